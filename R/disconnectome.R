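#' Per-subject disconnectome probability map
#'
#' For each normative control tractogram, the streamlines intersecting the
#' lesion are selected, their visitation map computed and binarised
#' (visited / not visited); the disconnectome value at a voxel is the mean
#' of those binary maps, i.e. the fraction of controls in which a fiber
#' running through the lesion also runs through that voxel. Values
#' therefore lie on the grid `{0, 1/N, ..., 1}` for N controls and read as
#' a probability of disconnection from 0 to 100%.
#'
#' @param lesion Binary 3-D lesion mask on `grid` (nonempty).
#' @param controls Nonempty list of [tractogram()]s in `grid` space.
#' @param grid A [template_grid()].
#' @param step Streamline sampling step (see [streamline_voxels()]).
#' @param control_voxels Optional output of [voxelize_controls()] for the
#'   same controls/grid/step; streamline voxelisation dominates the cost
#'   and is lesion-independent, so precomputing it once amortises it
#'   across a cohort of lesions.
#' @return A `disconnectome_map` object: list with `prob` (3-D array in
#'   `[0,1]`), `grid`, `n_controls`, `thresholded = FALSE`.
#' @export
disconnectome_map <- function(lesion, controls, grid, step = NULL,
                              control_voxels = NULL) {
  if (length(controls) == 0L) stop("`controls` must be a nonempty list")
  if (!any(lesion != 0)) stop("`lesion` mask is empty")
  stopifnot(all(dim(lesion) == grid$shape))
  if (is.null(control_voxels))
    control_voxels <- voxelize_controls(controls, grid, step)
  lesioned <- as.logical(lesion != 0)
  acc <- empty_volume(grid)
  for (cv in control_voxels) {
    hit <- vapply(cv, function(idx) length(idx) > 0L && any(lesioned[idx]),
                  logical(1))
    if (any(hit)) {
      visited <- logical(length(acc))
      visited[unlist(cv[hit], use.names = FALSE)] <- TRUE
      acc <- acc + visited
    }
  }
  structure(list(prob = acc / length(controls), grid = grid,
                 n_controls = length(controls), thresholded = FALSE),
            class = "disconnectome_map")
}

#' Precompute per-streamline voxel sets for a list of controls
#'
#' @param controls List of [tractogram()]s.
#' @param grid A [template_grid()].
#' @param step Sampling step (see [streamline_voxels()]).
#' @return A list (per control) of lists (per streamline) of linear voxel
#'   indices into the grid array.
#' @export
voxelize_controls <- function(controls, grid, step = NULL) {
  lapply(controls, function(t)
    lapply(t$streamlines, function(s) {
      ijk <- streamline_voxels(s, grid, step)
      if (nrow(ijk)) grid_linear_index(grid, ijk) else integer(0)
    }))
}

#' @export
print.disconnectome_map <- function(x, ...) {
  cat(sprintf("<disconnectome_map: %d controls, %d nonzero voxels%s>\n",
              x$n_controls, sum(x$prob > 0),
              if (x$thresholded) ", thresholded" else ""))
  invisible(x)
}

#' Threshold a disconnectome map
#'
#' Retains voxels whose disconnection probability strictly exceeds
#' `cutoff` (default 0.5: more than half the controls' trajectories
#' intersect the lesion there); retained values are unchanged, all others
#' set to 0. A non-strict reading ("at least half") can be had with
#' `strict = FALSE`.
#'
#' @param d An unthresholded `disconnectome_map`.
#' @param cutoff Probability cutoff in `[0, 1)`.
#' @param strict Use strict `>` (default) or `>=`.
#' @return A thresholded `disconnectome_map`.
#' @export
threshold_map <- function(d, cutoff = 0.5, strict = TRUE) {
  stopifnot(inherits(d, "disconnectome_map"))
  if (d$thresholded) stop("map is already thresholded")
  if (cutoff < 0 || cutoff >= 1) stop("`cutoff` must be in [0, 1)")
  keep <- if (strict) d$prob > cutoff else d$prob >= cutoff
  d$prob <- d$prob * keep
  d$thresholded <- TRUE
  d
}

#' Build the white-matter analysis mask
#'
#' The union of the nonzero supports of the supplied per-subject
#' disconnectome maps; used as the denominator of the global disconnectome
#' and as the voxel-wise analysis mask.
#'
#' @param maps Nonempty list of `disconnectome_map`s on a common grid.
#' @return A binary 3-D array (`integer` 0/1).
#' @export
build_wm_mask <- function(maps) {
  if (length(maps) == 0L) stop("`maps` must be a nonempty list")
  shp <- maps[[1]]$grid$shape
  mask <- array(FALSE, dim = shp)
  for (m in maps) {
    if (!all(m$grid$shape == shp)) stop("grid mismatch across maps")
    mask <- mask | (m$prob > 0)
  }
  storage.mode(mask) <- "integer"
  mask
}

#' Global disconnectome (GD) score
#'
#' The mean disconnection probability across all white-matter-mask voxels.
#' Voxels inside the mask where the (thresholded) map is zero count in the
#' denominator, so GD reflects both the proportion and the severity of
#' affected white matter; 0.50 equals 50%.
#'
#' @param d A thresholded `disconnectome_map`.
#' @param wm Binary white-matter mask on the same grid (nonempty).
#' @return Scalar GD in `[0, 1]`.
#' @export
global_disconnectome <- function(d, wm) {
  stopifnot(inherits(d, "disconnectome_map"))
  if (!d$thresholded)
    stop("`d` must be thresholded before computing GD (see threshold_map)")
  if (!all(dim(wm) == d$grid$shape)) stop("grid mismatch between map and wm")
  nwm <- sum(wm != 0)
  if (nwm == 0L) stop("white-matter mask is empty")
  sum(d$prob[wm != 0]) / nwm
}

#' Lesion volume in millilitres
#'
#' @param lesion Binary lesion mask.
#' @param grid A [template_grid()].
#' @return Volume in ml (voxel count x voxel volume in mm^3 / 1000).
#' @export
lesion_volume_ml <- function(lesion, grid) {
  stopifnot(all(dim(lesion) == grid$shape))
  sum(lesion != 0) * voxel_volume_mm3(grid) / 1000
}
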