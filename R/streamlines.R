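#' Streamline constructor
#'
#' A streamline is an ordered polyline of world-coordinate points (mm).
#'
#' @param points Numeric n x 3 matrix, n >= 2, finite, consecutive rows
#'   distinct.
#' @return A `streamline` object (the validated matrix).
#' @export
streamline <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 2L) stop("a streamline needs >= 2 points")
  if (!all(is.finite(points))) stop("streamline coordinates must be finite")
  seg <- diff(points)
  if (any(rowSums(seg^2) == 0))
    stop("consecutive streamline points must be distinct")
  structure(points, class = c("streamline", "matrix"))
}

#' Tractogram constructor
#'
#' @param streamlines List of [streamline()] objects (may be empty).
#' @param space Identifier of the reference [template_grid()] (free-form
#'   string; all streamlines of one tractogram share it).
#' @return A `tractogram` object.
#' @export
tractogram <- function(streamlines = list(), space = "template") {
  streamlines <- lapply(streamlines, function(s)
    if (inherits(s, "streamline")) s else streamline(s))
  structure(list(streamlines = streamlines, space = space),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- sum(vapply(x$streamlines, nrow, 1L))
  cat(sprintf("<tractogram: %d streamlines, %d points, space '%s'>\n",
              length(x$streamlines), np, x$space))
  invisible(x)
}

#' Number of streamlines
#' @param t A [tractogram()].
#' @return Integer count.
#' @export
n_streamlines <- function(t) length(t$streamlines)

#' Resample a streamline to a maximum step length
#'
#' Inserts evenly spaced points along each segment so that consecutive
#' points are at most `step` mm apart. Endpoints and all original vertices
#' are preserved; every output point lies on the input polyline, so arc
#' length is unchanged.
#'
#' @param s A [streamline()].
#' @param step Maximum spacing in mm (> 0).
#' @return A resampled [streamline()].
#' @export
resample_streamline <- function(s, step) {
  if (step <= 0) stop("`step` must be > 0")
  pts <- unclass(s)
  out <- vector("list", nrow(pts) - 1L)
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step - 1e-12))
    f <- seq(0, 1, length.out = nseg + 1L)[-(nseg + 1L)]
    out[[i]] <- cbind(a[1] + f * (b[1] - a[1]),
                      a[2] + f * (b[2] - a[2]),
                      a[3] + f * (b[3] - a[3]))
  }
  streamline(rbind(do.call(rbind, out), pts[nrow(pts), ]))
}

#' Voxels visited by a streamline
#'
#' Resamples the streamline at `step` mm (enforced to be no larger than
#' half the smallest voxel dimension, so diagonal traversals cannot skip a
#' voxel) and returns the set of 0-based voxel indices containing at least
#' one sample point. Points outside the grid are dropped silently -- a
#' streamline may legitimately leave the template box.
#'
#' @param s A [streamline()].
#' @param grid A [template_grid()].
#' @param step Sampling step in mm; default `0.25 * min(voxel_size)`.
#' @return Integer m x 3 matrix of unique 0-based voxel indices, ordered by
#'   first visit (possibly 0 rows).
#' @export
streamline_voxels <- function(s, grid, step = NULL) {
  max_step <- min(grid$voxel_size) / 2
  if (is.null(step)) step <- 0.25 * min(grid$voxel_size)
  if (step > max_step + 1e-12)
    stop(sprintf("`step` must be <= half the smallest voxel dimension (%g mm)",
                 max_step))
  pts <- unclass(resample_streamline(s, step))
  ijk <- world_to_voxel(grid, pts)
  keep <- in_grid(grid, ijk)
  ijk <- ijk[keep, , drop = FALSE]
  if (nrow(ijk) == 0L) return(ijk)
  ijk[!duplicated(grid_linear_index(grid, ijk)), , drop = FALSE]
}

#' Visitation map of a tractogram
#'
#' Counts, per voxel, how many streamlines visit it (each streamline counts
#' once per voxel however many of its sample points fall there).
#'
#' @param t A [tractogram()].
#' @param grid A [template_grid()].
#' @param step Sampling step passed to [streamline_voxels()].
#' @return 3-D integer array of counts on `grid`.
#' @export
visitation_map <- function(t, grid, step = NULL) {
  counts <- empty_volume(grid)
  for (s in t$streamlines) {
    ijk <- streamline_voxels(s, grid, step)
    if (nrow(ijk)) {
      li <- grid_linear_index(grid, ijk)
      counts[li] <- counts[li] + 1
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Select streamlines passing through a mask
#'
#' Emulates lesion-seeded tracking with a normative whole-brain tractogram:
#' the selected set is exactly the streamlines whose visited-voxel set
#' intersects the (lesion) mask, in their original order.
#'
#' @param t A [tractogram()].
#' @param mask Binary 3-D array on `grid` (a lesion mask).
#' @param grid A [template_grid()].
#' @param step Sampling step passed to [streamline_voxels()].
#' @return A [tractogram()] containing the selected streamlines.
#' @export
select_through_mask <- function(t, mask, grid, step = NULL) {
  stopifnot(all(dim(mask) == grid$shape))
  hit <- vapply(t$streamlines, function(s) {
    ijk <- streamline_voxels(s, grid, step)
    nrow(ijk) > 0L && any(mask[grid_linear_index(grid, ijk)] != 0)
  }, logical(1))
  tractogram(t$streamlines[hit], space = t$space)
}
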