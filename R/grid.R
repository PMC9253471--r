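#' Template grid
#'
#' A small RAS+ reference grid standing in for a template space (e.g. a
#' downsampled MNI-like box). The affine maps 0-based voxel indices to world
#' coordinates in mm; by default voxel `(0,0,0)` is centred at `origin`.
#'
#' @param shape Integer triple, voxels per axis (each >= 1).
#' @param voxel_size Numeric triple (or scalar), mm per axis (each > 0).
#' @param origin World-mm position of the centre of voxel `(0,0,0)`.
#' @param affine Optional explicit 4x4 voxel-to-world matrix; overrides
#'   `voxel_size`/`origin`. Must be invertible.
#' @return An object of class `template_grid` with fields `shape`,
#'   `voxel_size`, `affine`.
#' @examples
#' g <- template_grid(c(32, 32, 32), 1)
#' g$affine
#' @export
template_grid <- function(shape, voxel_size = 1, origin = c(0, 0, 0),
                          affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be three integers >= 1")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("`voxel_size` entries must be > 0")
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(voxel_size, 3L)
    affine[1:3, 4] <- as.numeric(origin)
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
    if (abs(det(affine)) < .Machine$double.eps)
      stop("`affine` must be invertible")
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "template_grid")
}

#' @export
print.template_grid <- function(x, ...) {
  cat(sprintf("<template_grid %s at %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' Convert 0-based voxel indices to world mm
#'
#' @param grid A [template_grid()].
#' @param ijk Integer matrix (n x 3) of 0-based voxel indices.
#' @return Numeric n x 3 matrix of world coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk, 1)
  out <- h %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

#' Convert world mm to 0-based voxel indices
#'
#' A point maps to the voxel whose centre is nearest under the inverse
#' affine; rounding is half-away-from-zero so the map is tie-stable and
#' does not depend on the platform's banker's rounding.
#'
#' @param grid A [template_grid()].
#' @param xyz Numeric matrix (n x 3) of world coordinates in mm.
#' @return Integer n x 3 matrix of 0-based voxel indices (may fall outside
#'   the grid; see [in_grid()]).
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  h <- cbind(xyz, 1)
  v <- h %*% t(solve(grid$affine))
  matrix(as.integer(round_half_away(v[, 1:3, drop = FALSE])), ncol = 3L)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Which voxel indices fall inside a grid
#'
#' @param grid A [template_grid()].
#' @param ijk Integer n x 3 matrix of 0-based indices.
#' @return Logical vector of length n.
#' @export
in_grid <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  ijk[, 1] >= 0L & ijk[, 1] < grid$shape[1] &
    ijk[, 2] >= 0L & ijk[, 2] < grid$shape[2] &
    ijk[, 3] >= 0L & ijk[, 3] < grid$shape[3]
}

#' World-space bounding box of a grid
#'
#' The box containing every voxel (centres +/- half a voxel) for an
#' axis-aligned affine.
#'
#' @param grid A [template_grid()].
#' @return A 2 x 3 matrix; row 1 = lower corner, row 2 = upper corner (mm).
#' @export
grid_world_bounds <- function(grid) {
  corners <- as.matrix(expand.grid(
    c(-0.5, grid$shape[1] - 0.5),
    c(-0.5, grid$shape[2] - 0.5),
    c(-0.5, grid$shape[3] - 0.5)))
  w <- voxel_to_world(grid, corners)
  rbind(lower = apply(w, 2, min), upper = apply(w, 2, max))
}

#' Voxel volume in mm^3
#' @param grid A [template_grid()].
#' @return Scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(grid) abs(det(grid$affine[1:3, 1:3]))

# linear (1-based) index into the grid array from 0-based ijk rows
grid_linear_index <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  1L + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
}

empty_volume <- function(grid, value = 0) {
  array(value, dim = grid$shape)
}
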