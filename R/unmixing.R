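#' Construct a reference set (the S matrix)
#'
#' Bundles k reference spectra sharing one wavenumber axis into the
#' k x N_lambda matrix used for unmixing. The conventional three channels
#' are the analyte (limonene), the cell body (wild-type average) and the
#' non-cell background.
#'
#' @param spectra List of [spectrum()] objects on an identical axis.
#' @param names Channel names; default taken from spectrum labels, falling
#'   back to `limonene`, `cell_body`, `background` for k = 3.
#' @return An object of class `reference_set` with fields `S` (k x N
#'   matrix), `axis`, `names`.
#' @export
reference_set <- function(spectra, names = NULL) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  if (!all(vapply(spectra, inherits, TRUE, "spectrum")))
    stop("all references must be spectrum objects", call. = FALSE)
  axis <- spectra[[1L]]$axis
  for (s in spectra[-1L])
    if (length(s$axis) != length(axis) || any(s$axis != axis))
      stop("all reference spectra must share one wavenumber axis", call. = FALSE)
  S <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  if (any(rowSums(abs(S)) == 0))
    stop("a reference spectrum is all-zero", call. = FALSE)
  if (is.null(names)) {
    names <- vapply(spectra, `[[`, "", "label")
    if (any(!nzchar(names)))
      names <- if (length(spectra) == 3L) c("limonene", "cell_body", "background")
               else paste0("channel", seq_along(spectra))
  }
  rownames(S) <- names
  structure(list(S = S, axis = axis, names = names), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> k=%d [%s], %d wavenumbers %g-%g cm-1\n",
              nrow(x$S), paste(x$names, collapse = ", "),
              length(x$axis), min(x$axis), max(x$axis)))
  invisible(x)
}

#' Resample references onto a new wavenumber axis
#'
#' Linear interpolation of each reference onto `axis`; the target axis
#' must lie within the references' range.
#'
#' @param refs A [reference_set()].
#' @param axis Target wavenumber axis.
#' @return A `reference_set` on `axis`.
#' @export
resample_references <- function(refs, axis) {
  axis <- wn_axis(axis)
  if (min(axis) < min(refs$axis) || max(axis) > max(refs$axis))
    stop("target axis extends beyond reference axis; cannot extrapolate",
         call. = FALSE)
  sp <- lapply(seq_len(nrow(refs$S)), function(i)
    spectrum(axis, stats::approx(refs$axis, refs$S[i, ], xout = axis)$y,
             refs$names[i]))
  reference_set(sp, refs$names)
}

#' Unmixing configuration
#'
#' @param lam L1 penalty lambda >= 0. The same lambda is meant to be used
#'   for all stacks acquired under one imaging condition.
#' @param nonnegative Constrain coefficients to be >= 0 (default TRUE:
#'   concentrations are physical). `FALSE` gives the unconstrained LASSO.
#' @param max_iter Maximum full coordinate-descent cycles.
#' @param tol Per-pixel relative objective-change stopping tolerance.
#' @param normalize_refs `"max"` (default) max-normalizes each reference
#'   before fitting, so channel units are fractions of the pure-reference
#'   intensity; `"none"` fits in raw units.
#' @return An object of class `unmix_config`.
#' @export
unmix_config <- function(lam = 0.05, nonnegative = TRUE, max_iter = 1000L,
                         tol = 1e-8, normalize_refs = c("max", "none")) {
  normalize_refs <- match.arg(normalize_refs)
  stopifnot(is.finite(lam), lam >= 0, tol > 0, max_iter >= 1)
  structure(list(lam = lam, nonnegative = isTRUE(nonnegative),
                 max_iter = as.integer(max_iter), tol = tol,
                 normalize_refs = normalize_refs),
            class = "unmix_config")
}

#' LASSO unmixing objective
#'
#' The per-pixel objective 1/2 ||d - c S||_2^2 + lambda ||c||_1.
#'
#' @param d Numeric vector, one pixel's spectrum (length N_lambda).
#' @param coef Numeric coefficient vector (length k).
#' @param refs A [reference_set()].
#' @param lam Penalty lambda.
#' @return Scalar objective value.
#' @export
unmix_objective <- function(d, coef, refs, lam) {
  S <- refs$S
  if (length(d) != ncol(S) || length(coef) != nrow(S))
    stop("dimension mismatch: d has ", length(d), " points, coef has ",
         length(coef), ", S is ", nrow(S), "x", ncol(S), call. = FALSE)
  r <- d - as.vector(coef %*% S)
  0.5 * sum(r^2) + lam * sum(abs(coef))
}

# Vectorized cyclic coordinate descent with exact soft-threshold updates.
# D: n x N matrix of pixel spectra (rows), S: k x N reference matrix.
# Each pixel warm-starts at 0 and is frozen once, over one full cycle, its
# relative objective change drops below tol AND its relative coefficient
# change drops below sqrt(tol) (the objective is quadratically flat near
# the optimum, so the coefficient criterion guards accuracy on correlated
# references). A pixel's solution depends only on its own spectrum, so
# unmixing commutes with spatial cropping.
lasso_cd_core <- function(D, S, lam, nonnegative = TRUE,
                          max_iter = 1000L, tol = 1e-8) {
  if (!all(is.finite(D))) stop("non-finite values in input spectra", call. = FALSE)
  n <- nrow(D); k <- nrow(S)
  G <- S %*% t(S)                       # k x k Gram matrix
  B <- D %*% t(S)                       # n x k correlations
  C <- matrix(0, n, k)
  obj <- 0.5 * rowSums(D^2)             # objective at c = 0
  iters <- integer(n)
  active <- seq_len(n)
  ctol <- sqrt(tol)
  it <- 0L
  while (length(active) > 0L && it < max_iter) {
    it <- it + 1L
    Ca <- C[active, , drop = FALSE]
    Cold <- Ca
    for (j in seq_len(k)) {
      rho <- B[active, j] - Ca %*% G[, j] + Ca[, j] * G[j, j]
      Ca[, j] <- if (nonnegative) pmax(rho - lam, 0) / G[j, j]
                 else sign(rho) * pmax(abs(rho) - lam, 0) / G[j, j]
    }
    r <- D[active, , drop = FALSE] - Ca %*% S
    newobj <- 0.5 * rowSums(r^2) + lam * rowSums(abs(Ca))
    rel <- (obj[active] - newobj) / pmax(obj[active], .Machine$double.eps)
    dmat <- abs(Ca - Cold); amat <- abs(Ca)
    dc <- dmat[, 1L]; ac <- amat[, 1L]
    for (j in seq_len(k)[-1L]) { dc <- pmax(dc, dmat[, j]); ac <- pmax(ac, amat[, j]) }
    dc <- dc / pmax(1, ac)
    C[active, ] <- Ca
    obj[active] <- newobj
    iters[active] <- it
    done <- rel < tol & dc < ctol
    active <- active[!done]
  }
  if (length(active) > 0L)
    warning(length(active), " pixel(s) did not converge within ", max_iter,
            " cycles; best iterates returned", call. = FALSE)
  list(C = C, objective = obj, iterations = iters,
       converged = n - length(active), n = n)
}

# apply the configured reference normalization, returning the working S
working_S <- function(refs, cfg) {
  S <- refs$S
  if (cfg$normalize_refs == "max") S <- S / apply(abs(S), 1, max)
  S
}

#' Unmix a single pixel spectrum
#'
#' Cyclic coordinate descent with exact per-coordinate soft-threshold
#' updates, warm-started at zero, minimizing
#' 1/2 ||d - c S||_2^2 + lambda ||c||_1 (optionally subject to c >= 0).
#'
#' @param d Numeric spectrum of length N_lambda matching `refs`.
#' @param refs A [reference_set()].
#' @param cfg An [unmix_config()].
#' @return Named coefficient vector (length k) with attributes
#'   `objective` and `iterations`.
#' @export
lasso_unmix_pixel <- function(d, refs, cfg = unmix_config()) {
  if (length(d) != ncol(refs$S))
    stop("spectrum length ", length(d), " does not match reference N_lambda ",
         ncol(refs$S), call. = FALSE)
  fit <- lasso_cd_core(matrix(as.numeric(d), 1L), working_S(refs, cfg),
                       cfg$lam, cfg$nonnegative, cfg$max_iter, cfg$tol)
  coef <- drop(fit$C)
  names(coef) <- refs$names
  attr(coef, "objective") <- fit$objective
  attr(coef, "iterations") <- fit$iterations
  coef
}

#' Estimate the background reference spectrum from a stack
#'
#' Averages the spectrum over non-cell pixels. With a cell mask the
#' non-cell area is `labels == 0`; otherwise cells are located by Otsu
#' thresholding the spectrally summed image and pixels below the
#' threshold are taken as background.
#'
#' @param stack An [hs_stack()].
#' @param cell_mask Optional [cell_mask()]; `NULL` for automatic Otsu.
#' @return A [spectrum()] labelled `"background"`.
#' @export
estimate_background_spectrum <- function(stack, cell_mask = NULL) {
  if (is.null(cell_mask)) {
    summed <- colSums(stack$data, dims = 1)
    rng <- range(summed)
    if (diff(rng) == 0)
      stop("constant summed image: cannot Otsu-threshold for background",
           call. = FALSE)
    thr <- EBImage::otsu(EBImage::Image(summed), range = rng)
    out <- summed < thr
  } else {
    out <- cell_mask$labels == 0L
  }
  if (!any(out)) stop("non-cell area is empty", call. = FALSE)
  nl <- dim(stack$data)[1]
  D <- matrix(stack$data, nl)            # N_lambda x n_pixels
  spectrum(stack$axis, rowMeans(D[, as.vector(out), drop = FALSE]),
           label = "background")
}

#' Unmix a full stack into concentration maps
#'
#' Applies the per-pixel LASSO independently to every pixel (the pixels
#' share nothing but the references, so the result is deterministic and
#' commutes with spatial cropping).
#'
#' @param stack An [hs_stack()].
#' @param refs A [reference_set()]; its axis must equal the stack axis
#'   unless `resample = TRUE`, in which case references are linearly
#'   interpolated onto the stack axis.
#' @param cfg An [unmix_config()].
#' @param resample Allow resampling of references onto the stack axis.
#' @return An object of class `concentration_maps`: named list `maps` of
#'   k matrices, `residual_norm` matrix (per-pixel l2 residual), `names`,
#'   plus the `config` used and coordinate-descent diagnostics.
#' @export
unmix_stack <- function(stack, refs, cfg = unmix_config(), resample = FALSE) {
  stopifnot(inherits(stack, "hs_stack"), inherits(refs, "reference_set"))
  if (length(refs$axis) != length(stack$axis) || any(refs$axis != stack$axis)) {
    if (!resample)
      stop("reference axis does not match stack axis (set resample = TRUE ",
           "to interpolate references)", call. = FALSE)
    refs <- resample_references(refs, stack$axis)
  }
  dm <- dim(stack$data)
  nl <- dm[1]; nr <- dm[2]; nc <- dm[3]
  D <- t(matrix(stack$data, nl))         # n_pixels x N_lambda
  S <- working_S(refs, cfg)
  fit <- lasso_cd_core(D, S, cfg$lam, cfg$nonnegative, cfg$max_iter, cfg$tol)
  resid <- D - fit$C %*% S
  maps <- lapply(seq_len(nrow(S)), function(j) matrix(fit$C[, j], nr, nc))
  names(maps) <- refs$names
  structure(list(maps = maps,
                 residual_norm = matrix(sqrt(rowSums(resid^2)), nr, nc),
                 names = refs$names, config = cfg,
                 iterations = matrix(fit$iterations, nr, nc)),
            class = "concentration_maps")
}

#' @export
print.concentration_maps <- function(x, ...) {
  d <- dim(x$maps[[1]])
  cat(sprintf("<concentration_maps> %d channels [%s], %d x %d px, mean residual %.4g\n",
              length(x$maps), paste(x$names, collapse = ", "),
              d[1], d[2], mean(x$residual_norm)))
  invisible(x)
}

#' Select the penalty lambda from the non-cell residual
#'
#' Chooses the largest candidate lambda whose mean residual norm over
#' non-cell pixels stays within `factor` times the lambda = 0 residual,
#' so the penalty suppresses spurious coefficients without degrading the
#' fit where nothing but background is present. The chosen value is meant
#' to be reused for every stack from the same acquisition condition.
#'
#' @param stack An [hs_stack()].
#' @param refs A [reference_set()].
#' @param candidates Increasing vector of candidate lambdas.
#' @param cell_mask Optional [cell_mask()] (Otsu-auto otherwise).
#' @param factor Allowed residual inflation (default 1.1).
#' @param cfg Base [unmix_config()] whose lambda is swept.
#' @return The selected lambda (scalar).
#' @export
choose_lambda <- function(stack, refs, candidates = c(0.01, 0.02, 0.05, 0.1, 0.2),
                          cell_mask = NULL, factor = 1.1,
                          cfg = unmix_config()) {
  stopifnot(all(diff(candidates) > 0), all(candidates >= 0))
  if (is.null(cell_mask)) {
    summed <- colSums(stack$data, dims = 1)
    thr <- EBImage::otsu(EBImage::Image(summed), range = range(summed))
    out <- summed < thr
  } else out <- cell_mask$labels == 0L
  if (!any(out)) stop("non-cell area is empty", call. = FALSE)
  # evaluate on a subsample of background pixels for speed
  idx <- which(as.vector(out))
  if (length(idx) > 5000L) idx <- idx[round(seq(1, length(idx), length.out = 5000L))]
  nl <- dim(stack$data)[1]
  D <- t(matrix(stack$data, nl))[idx, , drop = FALSE]
  S <- working_S(refs, cfg)
  mean_resid <- function(lam) {
    fit <- lasso_cd_core(D, S, lam, cfg$nonnegative, cfg$max_iter, cfg$tol)
    mean(sqrt(rowSums((D - fit$C %*% S)^2)))
  }
  base <- mean_resid(0)
  ok <- candidates[vapply(candidates, function(l) mean_resid(l) <= factor * base,
                          TRUE)]
  if (length(ok) == 0L) return(0)
  max(ok)
}
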