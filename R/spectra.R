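#' Validate a wavenumber axis
#'
#' A wavenumber axis is a strictly increasing finite numeric vector of
#' Raman shifts in cm^-1 with at least two points. Axes need not be
#' uniformly spaced; every operation in the package consults the axis
#' explicitly.
#'
#' @param values Numeric vector of wavenumbers (cm^-1).
#' @return The validated numeric vector.
#' @export
wn_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("wavenumber axis needs at least 2 points", call. = FALSE)
  if (!all(is.finite(values)))
    stop("wavenumber axis must be finite", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  values
}

#' Construct a spectrum
#'
#' @param axis Wavenumber axis (cm^-1), see [wn_axis()].
#' @param intensity Numeric intensities (arbitrary SRS units), same length
#'   as `axis`.
#' @param label Free-text label.
#' @return An object of class `spectrum`: a list with `axis`, `intensity`,
#'   `label`.
#' @export
spectrum <- function(axis, intensity, label = "") {
  axis <- wn_axis(axis)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(axis))
    stop("intensity and axis lengths differ (", length(intensity), " vs ",
         length(axis), ")", call. = FALSE)
  if (!all(is.finite(intensity)))
    stop("spectrum intensities must be finite", call. = FALSE)
  structure(list(axis = axis, intensity = intensity, label = as.character(label)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, %.0f-%.0f cm-1, max %.4g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$axis), min(x$axis), max(x$axis), max(x$intensity)))
  invisible(x)
}

# trapezoidal integral over the (possibly non-uniform) axis
trapz_integral <- function(axis, y) {
  sum(diff(axis) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Normalize a spectrum
#'
#' `mode = "max"` scales so the maximum intensity is 1; `mode = "area"`
#' scales so the trapezoidal integral over the axis is 1; `mode = "none"`
#' returns the spectrum unchanged.
#'
#' @param s A [spectrum()].
#' @param mode One of `"max"`, `"area"`, `"none"`.
#' @return A normalized `spectrum`.
#' @export
normalize_spectrum <- function(s, mode = c("max", "area", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "spectrum"))
  if (mode == "none") return(s)
  if (mode == "max") {
    m <- max(abs(s$intensity))
    if (m <= 0) stop("cannot max-normalize an all-zero spectrum", call. = FALSE)
    s$intensity <- s$intensity / m
  } else {
    a <- trapz_integral(s$axis, s$intensity)
    if (a == 0) stop("cannot area-normalize: zero integral", call. = FALSE)
    s$intensity <- s$intensity / a
  }
  s
}

#' Define a named spectral window
#'
#' @param lo,hi Window bounds in cm^-1, `lo < hi`. Both bounds are
#'   inclusive.
#' @param name Window name (e.g. `"fingerprint"`, `"ch"`).
#' @return An object of class `spectral_window`.
#' @export
spectral_window <- function(lo, hi, name = "") {
  if (!(is.finite(lo) && is.finite(hi) && lo < hi))
    stop("spectral window requires finite lo < hi", call. = FALSE)
  structure(list(lo = lo, hi = hi, name = as.character(name)),
            class = "spectral_window")
}

#' Default spectral windows
#'
#' The fingerprint window (670-900 cm^-1, where the 760 cm^-1 limonene
#' band lives) and the C-H stretching window (2800-3100 cm^-1).
#'
#' @return Named list of [spectral_window()] objects.
#' @export
default_windows <- function() {
  list(fingerprint = spectral_window(670, 900, "fingerprint"),
       ch = spectral_window(2800, 3100, "ch"))
}

#' Build a synthetic reference spectrum from line-shape parameters
#'
#' Evaluates a sum of Lorentzian (default) or Gaussian bands plus a flat
#' baseline on a wavenumber axis. Used to construct reference spectra for
#' simulation and testing; the Lorentzian profile is the usual model for
#' Raman bands.
#'
#' @param peaks A data.frame / matrix with columns `center` (cm^-1),
#'   `fwhm` (cm^-1, > 0) and `amplitude` (>= 0), one row per band; or
#'   `NULL` / zero rows for a flat spectrum.
#' @param axis Wavenumber axis.
#' @param baseline Constant offset added everywhere.
#' @param shape `"lorentzian"` or `"gaussian"`.
#' @param label Spectrum label.
#' @return A [spectrum()]. With no peaks and `baseline = 0` this is an
#'   all-zero spectrum (valid as a blank).
#' @export
synthetic_reference <- function(peaks, axis, baseline = 0,
                                shape = c("lorentzian", "gaussian"),
                                label = "") {
  shape <- match.arg(shape)
  axis <- wn_axis(axis)
  y <- rep(baseline, length(axis))
  if (!is.null(peaks) && NROW(peaks) > 0) {
    peaks <- as.data.frame(peaks)
    stopifnot(all(c("center", "fwhm", "amplitude") %in% names(peaks)))
    if (any(peaks$fwhm <= 0)) stop("fwhm must be > 0", call. = FALSE)
    if (any(peaks$amplitude < 0)) stop("amplitudes must be >= 0", call. = FALSE)
    for (i in seq_len(nrow(peaks))) {
      x0 <- peaks$center[i]; g <- peaks$fwhm[i]; a <- peaks$amplitude[i]
      y <- y + if (shape == "lorentzian") {
        a * (g / 2)^2 / ((axis - x0)^2 + (g / 2)^2)
      } else {
        a * exp(-4 * log(2) * (axis - x0)^2 / g^2)
      }
    }
  }
  spectrum(axis, y, label)
}

#' Spectrally summed image over a window
#'
#' Per-pixel sum of stack frames whose wavenumber lies inside the window
#' (bounds inclusive). This is the "spectrally summed" image used for
#' display and as segmentation input.
#'
#' @param stack An [hs_stack()].
#' @param w A [spectral_window()].
#' @return A 2D matrix with the stack's spatial shape.
#' @export
window_sum <- function(stack, w) {
  stopifnot(inherits(stack, "hs_stack"), inherits(w, "spectral_window"))
  sel <- stack$axis >= w$lo & stack$axis <= w$hi
  if (!any(sel))
    stop(sprintf("window [%g, %g] ('%s') contains no frames: stack axis spans %g-%g cm-1",
                 w$lo, w$hi, w$name, min(stack$axis), max(stack$axis)),
         call. = FALSE)
  colSums(stack$data[sel, , , drop = FALSE], dims = 1)
}

#' Intensity at a Raman peak
#'
#' Returns the intensity at the axis point nearest to `center`
#' (nearest-neighbor, no interpolation; ties break toward the lower
#' wavenumber). For a stack the result is the selected frame as a 2D
#' image; for a spectrum, a scalar.
#'
#' @param x An [hs_stack()] or [spectrum()].
#' @param center Peak position in cm^-1; must lie within the axis range.
#' @return Matrix (stack) or scalar (spectrum).
#' @export
peak_intensity <- function(x, center) {
  axis <- x$axis
  if (center < min(axis) || center > max(axis))
    stop(sprintf("peak center %g cm-1 outside axis range %g-%g",
                 center, min(axis), max(axis)), call. = FALSE)
  idx <- which.min(abs(axis - center))  # first (= lower wavenumber) on ties
  if (inherits(x, "hs_stack")) {
    x$data[idx, , ]
  } else if (inherits(x, "spectrum")) {
    x$intensity[idx]
  } else stop("peak_intensity expects an hs_stack or spectrum", call. = FALSE)
}

#' Read a spectrum from CSV
#'
#' Expects header `wavenumber_cm1,intensity` (UTF-8). Rows may be in any
#' order; they are sorted by wavenumber.
#'
#' @param path CSV file path.
#' @param label Label for the returned spectrum (defaults to the file name).
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavenumber_cm1", "intensity") %in% names(df)))
    stop("spectrum CSV must have columns wavenumber_cm1,intensity: ", path,
         call. = FALSE)
  o <- order(df$wavenumber_cm1)
  spectrum(df$wavenumber_cm1[o], df$intensity[o],
           label = if (is.null(label)) basename(path) else label)
}

#' Write a spectrum to CSV
#'
#' @param s A [spectrum()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  utils::write.csv(data.frame(wavenumber_cm1 = s$axis, intensity = s$intensity),
                   path, row.names = FALSE)
  invisible(path)
}
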