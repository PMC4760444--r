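#' A 4D BOLD series with acquisition metadata
#'
#' Light container for a 4D array of BOLD intensities plus the repetition
#' time, voxel size and brain mask the analysis needs.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr Repetition time, seconds.
#' @param voxel_size Voxel size per spatial axis, mm.
#' @param mask Logical 3D array; voxels outside are ignored everywhere.
#' @param truth Optional ground-truth record (phantoms only).
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr, voxel_size, mask = NULL, truth = NULL) {
  stopifnot(length(dim(data)) == 4, tr > 0, length(voxel_size) == 3)
  dims <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(all(dim(mask) == dims))
  structure(
    list(data = data, tr = tr, voxel_size = as.numeric(voxel_size),
         mask = mask, truth = truth),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bold_series> %d x %d x %d voxels x %d volumes, TR %.3g s, voxel %s mm, %d in mask\n",
    d[1], d[2], d[3], d[4], x$tr,
    paste(signif(x$voxel_size, 3), collapse = "x"), sum(x$mask)
  ))
  invisible(x)
}

#' @rdname bold_series
#' @param x A `bold_series`.
#' @export
n_volumes <- function(x) dim(x$data)[4]

#' Whole-brain mean BOLD time course
#'
#' @param x A [bold_series()].
#' @return Numeric vector, one mean intensity per volume over the mask.
#' @export
global_signal <- function(x) {
  stopifnot(inherits(x, "bold_series"))
  flat <- matrix(x$data, prod(dim(x$data)[1:3]), dim(x$data)[4])
  colMeans(flat[as.vector(x$mask), , drop = FALSE])
}

# NIfTI I/O -------------------------------------------------------------------

#' Read and write volumes and series as NIfTI-1
#'
#' Thin wrappers around RNifti keeping voxel size in the header. `read_bold`
#' returns a [bold_series()]; masks are any volume read with `read_volume`
#' compared against 0.5.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param tr Repetition time in seconds; defaults to the header's.
#' @param mask Optional logical array.
#' @return `read_bold`: a `bold_series`; `read_volume`: a 3D array with a
#'   `voxel_size` attribute.
#' @export
read_bold <- function(path, tr = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  if (is.null(tr)) tr <- if (length(pix) >= 4) pix[4] else stop("TR not in header")
  bold_series(unclass(img)[, , , , drop = FALSE], tr = tr,
              voxel_size = pix[1:3], mask = mask)
}

#' @rdname read_bold
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1:3]
  out
}

#' @rdname read_bold
#' @param x Array (3D or 4D) or `bold_series` to write.
#' @param voxel_size Voxel size per axis, mm (taken from `x` when it is a
#'   `bold_series`).
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  if (inherits(x, "bold_series")) {
    voxel_size <- x$voxel_size
    tr <- x$tr
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- c(voxel_size, tr)
  } else {
    img <- RNifti::asNifti(x + 0)  # logical -> numeric
    RNifti::pixdim(img) <- voxel_size[seq_len(min(3, length(dim(x))))]
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
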