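#' Mander's colocalization coefficient
#'
#' MCC = sum_i Lim_i [LimSyn_i >= threshold] / sum_i Lim_i over the
#' evaluated region (the comparison is inclusive). The region defaults to
#' the whole image; passing a [cell_mask()] or logical matrix restricts
#' evaluation to intracellular pixels, which is the recommended mode
#' since colocalization of analyte and enzyme is an intracellular
#' question.
#'
#' @param lim_map 2D analyte (limonene) concentration map, nonnegative.
#' @param limsyn_map 2D enzyme-fluorescence map, same shape.
#' @param threshold Fluorescence threshold (see [auto_threshold()]).
#' @param restrict Optional [cell_mask()] or logical matrix.
#' @return An object of class `colocalization_result`: `mcc`,
#'   `threshold_used`, `n_colocal_pixels`, `restricted_to`.
#' @export
mcc <- function(lim_map, limsyn_map, threshold, restrict = NULL) {
  if (!all(dim(lim_map) == dim(limsyn_map)))
    stop("maps are not aligned", call. = FALSE)
  region <- if (is.null(restrict)) {
    matrix(TRUE, nrow(lim_map), ncol(lim_map))
  } else if (inherits(restrict, "cell_mask")) {
    restrict$labels > 0L
  } else {
    stopifnot(is.logical(restrict), all(dim(restrict) == dim(lim_map)))
    restrict
  }
  denom <- sum(lim_map[region])
  if (denom <= 0)
    stop("MCC undefined: total limonene intensity over the evaluated region ",
         "is zero (division by zero)", call. = FALSE)
  colocal <- region & (limsyn_map >= threshold)
  structure(list(mcc = sum(lim_map[colocal]) / denom,
                 threshold_used = threshold,
                 n_colocal_pixels = sum(colocal),
                 restricted_to = if (is.null(restrict)) "whole-image"
                                 else "cells-only"),
            class = "colocalization_result")
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat(sprintf("<colocalization> MCC %.3f (threshold %.4g, %d colocal px, %s)\n",
              x$mcc, x$threshold_used, x$n_colocal_pixels, x$restricted_to))
  invisible(x)
}

# Otsu threshold on a numeric vector (256-bin between-class variance)
otsu_vec <- function(v, levels = 256L) {
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant values: Otsu threshold is degenerate", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- hist(v, breaks = br, plot = FALSE)
  cnt <- as.numeric(h$counts); mids <- h$mids   # numeric: counts can overflow int products
  w1 <- cumsum(cnt); w2 <- sum(cnt) - w1
  s1 <- cumsum(cnt * mids)
  m1 <- s1 / w1; m2 <- (sum(cnt * mids) - s1) / w2
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  # the criterion is flat across empty gaps; take the plateau midpoint
  ks <- which(between >= max(between) * (1 - 1e-12))
  br[ks[ceiling(length(ks) / 2)] + 1L]
}

#' Automatic fluorescence threshold
#'
#' @param limsyn_map 2D fluorescence map.
#' @param method `"otsu"` (256-bin, requires a nonconstant map) or
#'   `"quantile"` with probability `q` (type-7 quantile definition).
#' @param q Quantile probability for `method = "quantile"`.
#' @param restrict Optional [cell_mask()] or logical matrix: threshold
#'   computed from the restricted pixels only.
#' @return Scalar threshold.
#' @export
auto_threshold <- function(limsyn_map, method = c("otsu", "quantile"),
                           q = 0.5, restrict = NULL) {
  method <- match.arg(method)
  v <- if (is.null(restrict)) as.vector(limsyn_map)
       else if (inherits(restrict, "cell_mask")) limsyn_map[restrict$labels > 0L]
       else limsyn_map[restrict]
  if (method == "otsu") otsu_vec(v)
  else unname(stats::quantile(v, q, type = 7))
}
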