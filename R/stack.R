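#' Construct a hyperspectral SRS stack
#'
#' The lambda-x-y container: a 3D array of intensities indexed
#' `[frame, row, col]` with one frame per wavenumber, plus the wavenumber
#' axis and the pixel size. Frames are stored in ascending wavenumber
#' order.
#'
#' @param data 3D numeric array, dim = (n_wavenumbers, rows, cols).
#' @param axis Wavenumber axis, length `dim(data)[1]`.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @return An object of class `hs_stack`.
#' @export
hs_stack <- function(data, axis, pixel_size = NA_real_) {
  axis <- wn_axis(axis)
  if (length(dim(data)) != 3L)
    stop("stack data must be a 3D array (wavenumber x row x col)", call. = FALSE)
  if (dim(data)[1] != length(axis))
    stop("stack has ", dim(data)[1], " frames but axis has ", length(axis),
         " wavenumbers", call. = FALSE)
  if (!all(is.finite(data)))
    stop("stack contains non-finite values", call. = FALSE)
  structure(list(data = data, axis = axis, pixel_size = pixel_size),
            class = "hs_stack")
}

#' @export
print.hs_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hs_stack> %d frames (%g-%g cm-1), %d x %d px, pixel %g um\n",
              d[1], min(x$axis), max(x$axis), d[2], d[3], x$pixel_size))
  invisible(x)
}

#' @export
dim.hs_stack <- function(x) dim(x$data)

#' Crop a stack spatially
#'
#' @param stack An [hs_stack()].
#' @param rows,cols Integer index vectors of rows / columns to keep.
#' @return The cropped `hs_stack`.
#' @export
crop_stack <- function(stack, rows, cols) {
  stopifnot(inherits(stack, "hs_stack"))
  hs_stack(stack$data[, rows, cols, drop = FALSE], stack$axis, stack$pixel_size)
}
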