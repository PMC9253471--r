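#' Read a 3-D volume with its affine
#'
#' Thin wrapper over `RNifti`. Only 3-D volumes are accepted: lesion masks,
#' disconnectome maps and statistic maps are all single volumes here.
#'
#' @param path Path to a NIfTI file (`.nii` or `.nii.gz`).
#' @return A list with `data` (3-D array), `affine` (4x4 voxel-to-world,
#'   0-based voxel indices) and `grid` (a [template_grid()]).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D volume, got %d dimensions", length(d)))
  affine <- structure(RNifti::xform(img), class = NULL)
  grid <- template_grid(d, affine = affine)
  list(data = array(as.numeric(img), dim = d), affine = grid$affine,
       grid = grid)
}

#' Write a 3-D volume
#'
#' @param volume 3-D numeric or logical array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel convention), or a
#'   [template_grid()] whose affine is used.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"uint8"` keeps binary masks compact,
#'   `"double"` preserves probabilities exactly.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, affine, path, datatype = "double") {
  if (inherits(affine, "template_grid")) affine <- affine$affine
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L)
    stop(sprintf("expected a 3-D volume, got %d dimensions",
                 max(1L, length(d))))
  storage.mode(volume) <- "double"
  img <- RNifti::asNifti(volume)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
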