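#' Synthetic scene parameters
#'
#' Defaults describe the population structure the analysis targets:
#' non-overlapping rod-shaped cells (2D spherocylinders, length 2-4 um,
#' width 0.8 um at 0.1 um/px), a minority of cells (probability 0.19)
#' carrying 1-2 bright intracellular aggregates whose axial position d/L
#' is drawn from a truncated normal centred at 0.8 (sd 0.08, clipped to
#' [0.5, 1]) so most aggregates sit in the 70-90% stretch of the cell,
#' aggregate limonene levels spanning a broad range, and additive
#' Gaussian noise on every pixel spectrum.
#'
#' @param image_shape Integer (rows, cols) in pixels.
#' @param pixel_size um per pixel.
#' @param n_cells Number of cells to place.
#' @param cell_length_range Tip-to-tip cell length range (um).
#' @param cell_width Cell width (um).
#' @param aggregate_probability Fraction of cells bearing >= 1 aggregate.
#' @param aggregate_count_weights Named weights over counts given any
#'   aggregate, e.g. `c("1" = 0.8, "2" = 0.2)`.
#' @param aggregate_radius Aggregate radius (um).
#' @param polar_bias Named vector `c(mean = , sd = )` of the truncated
#'   normal on d/L (clipped to [0.5, 1]).
#' @param limonene_conc_range Range of true limonene coefficients inside
#'   aggregates (arbitrary concentration units, on the unmixing scale).
#' @param cell_body_level Mean cell-body coefficient (per-cell levels are
#'   drawn around this with 10% cell-to-cell variation).
#' @param background_level Background coefficient (everywhere).
#' @param noise_sigma Additive Gaussian noise sd per pixel and frame.
#' @param noise_model `"gaussian"` (default) or `"poisson"` (intensities
#'   scaled by `1/noise_sigma^2` and Poisson-resampled).
#' @param seed Integer seed; a fixed seed reproduces the scene exactly.
#' @param max_retries Placement attempts per cell before failing.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(512L, 512L), pixel_size = 0.1,
                         n_cells = 60L, cell_length_range = c(2, 4),
                         cell_width = 0.8, aggregate_probability = 0.19,
                         aggregate_count_weights = c("1" = 0.8, "2" = 0.2),
                         aggregate_radius = 0.2,
                         polar_bias = c(mean = 0.8, sd = 0.08),
                         limonene_conc_range = c(0.3, 1.0),
                         cell_body_level = 1.0, background_level = 1.0,
                         noise_sigma = 0.02,
                         noise_model = c("gaussian", "poisson"),
                         seed = 1L, max_retries = 200L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16),
            pixel_size > 0, n_cells >= 0,
            length(cell_length_range) == 2L, all(cell_length_range > 0),
            diff(cell_length_range) >= 0, cell_width > 0,
            aggregate_probability >= 0, aggregate_probability <= 1,
            all(aggregate_count_weights >= 0), sum(aggregate_count_weights) > 0,
            aggregate_radius > 0, polar_bias[["sd"]] > 0,
            length(limonene_conc_range) == 2L, all(limonene_conc_range >= 0),
            noise_sigma >= 0, max_retries >= 1)
  if (max(cell_length_range) / pixel_size + 8 > min(image_shape))
    stop("cells do not fit in the image at this pixel size", call. = FALSE)
  structure(list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
                 n_cells = as.integer(n_cells),
                 cell_length_range = cell_length_range, cell_width = cell_width,
                 aggregate_probability = aggregate_probability,
                 aggregate_count_weights = aggregate_count_weights,
                 aggregate_radius = aggregate_radius, polar_bias = polar_bias,
                 limonene_conc_range = limonene_conc_range,
                 cell_body_level = cell_body_level,
                 background_level = background_level,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 seed = as.integer(seed), max_retries = as.integer(max_retries)),
            class = "scene_params")
}

# Euclidean distance from pixel centres (pr, pc) to segment a-b (row, col)
dist_to_segment <- function(pr, pc, a, b) {
  vr <- b[1] - a[1]; vc <- b[2] - a[2]
  l2 <- vr^2 + vc^2
  t <- if (l2 == 0) rep(0, length(pr))
       else pmin(1, pmax(0, ((pr - a[1]) * vr + (pc - a[2]) * vc) / l2))
  sqrt((pr - (a[1] + t * vr))^2 + (pc - (a[2] + t * vc))^2)
}

#' Default reference spectra for simulation
#'
#' Three max-normalized references on the fingerprint axis: limonene (a
#' sharp Lorentzian band at 760 cm^-1), a cell body spectrum (broad bands
#' around 720/785/850 cm^-1 typical of nucleic-acid/protein-rich
#' cytoplasm), and a flat solvent background.
#'
#' @param axis Wavenumber axis (default 670-900 cm^-1 in 10 cm^-1 steps,
#'   24 frames).
#' @return A [reference_set()] whose rows each have maximum 1.
#' @export
default_reference_set <- function(axis = seq(670, 900, by = 10)) {
  lim <- synthetic_reference(
    data.frame(center = 760, fwhm = 12, amplitude = 1), axis, label = "limonene")
  body <- synthetic_reference(
    data.frame(center = c(720, 785, 850), fwhm = c(30, 25, 35),
               amplitude = c(0.6, 0.5, 0.3)),
    axis, baseline = 0.05, label = "cell_body")
  bg <- synthetic_reference(NULL, axis, baseline = 1, label = "background")
  reference_set(list(normalize_spectrum(lim, "max"),
                     normalize_spectrum(body, "max"),
                     normalize_spectrum(bg, "max")))
}

#' Generate a ground-truthed synthetic scene
#'
#' Places non-overlapping spherocylindrical cells by rejection sampling,
#' assigns aggregates (Bernoulli bearing, weighted count, truncated-normal
#' axial position toward a randomly chosen pole), rasterizes truth label
#' masks and the three true concentration maps (limonene is zero outside
#' aggregates).
#'
#' @param p A [scene_params()].
#' @return An object of class `scene_truth`: `params`, `cells`
#'   (data.frame: id, centroid, orientation, length/width in px, pole
#'   coordinates, body level), `aggregates` (data.frame: id, cell id,
#'   centroid, true d/L, true concentration), `cell_mask`,
#'   `aggregate_mask`, and `maps` (named list limonene / cell_body /
#'   background).
#' @export
generate_scene <- function(p) {
  stopifnot(inherits(p, "scene_params"))
  set.seed(p$seed)
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  occ <- matrix(FALSE, nr, nc)
  gap_px <- 2
  w_px <- p$cell_width / p$pixel_size
  cells <- list(); cell_pix <- list()
  for (i in seq_len(p$n_cells)) {
    placed <- FALSE
    for (try in seq_len(p$max_retries)) {
      len_um <- stats::runif(1, p$cell_length_range[1], p$cell_length_range[2])
      len_px <- len_um / p$pixel_size
      theta <- stats::runif(1, 0, pi)
      u <- c(sin(theta), cos(theta))
      half <- len_px / 2
      m <- half + gap_px + 2
      ctr <- c(stats::runif(1, 1 + m, nr - m), stats::runif(1, 1 + m, nc - m))
      tipA <- ctr - half * u; tipB <- ctr + half * u
      segA <- ctr - (half - w_px / 2) * u; segB <- ctr + (half - w_px / 2) * u
      r1 <- max(1L, floor(min(tipA[1], tipB[1]) - w_px / 2 - gap_px))
      r2 <- min(nr, ceiling(max(tipA[1], tipB[1]) + w_px / 2 + gap_px))
      c1 <- max(1L, floor(min(tipA[2], tipB[2]) - w_px / 2 - gap_px))
      c2 <- min(nc, ceiling(max(tipA[2], tipB[2]) + w_px / 2 + gap_px))
      gr <- as.matrix(expand.grid(r = r1:r2, c = c1:c2))
      d <- dist_to_segment(gr[, 1], gr[, 2], segA, segB)
      outer_idx <- (gr[d <= w_px / 2 + gap_px, 2] - 1L) * nr +
                    gr[d <= w_px / 2 + gap_px, 1]
      if (any(occ[outer_idx])) next
      inner <- d <= w_px / 2
      pix <- (gr[inner, 2] - 1L) * nr + gr[inner, 1]
      occ[pix] <- TRUE
      cell_pix[[i]] <- pix
      cells[[i]] <- data.frame(
        cell_id = i, ctr_row = ctr[1], ctr_col = ctr[2], theta = theta,
        length_px = len_px, width_px = w_px,
        poleA_row = tipA[1], poleA_col = tipA[2],
        poleB_row = tipB[1], poleB_col = tipB[2],
        body_level = max(0.5, stats::rnorm(1, p$cell_body_level,
                                           0.1 * p$cell_body_level)))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place cell ", i, " without overlap after ",
           p$max_retries, " retries; reduce n_cells or enlarge the image",
           call. = FALSE)
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(cell_id = integer(), ctr_row = numeric(), ctr_col = numeric(),
               theta = numeric(), length_px = numeric(), width_px = numeric(),
               poleA_row = numeric(), poleA_col = numeric(),
               poleB_row = numeric(), poleB_col = numeric(),
               body_level = numeric())

  cell_labels <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(cells))) cell_labels[cell_pix[[i]]] <- i

  # aggregates
  r_px <- p$aggregate_radius / p$pixel_size
  cw <- p$aggregate_count_weights / sum(p$aggregate_count_weights)
  counts_avail <- as.integer(names(cw))
  agg_labels <- matrix(0L, nr, nc)
  aggs <- list(); parent <- integer()
  next_id <- 0L
  for (i in seq_len(nrow(cells))) {
    if (stats::runif(1) >= p$aggregate_probability) next
    cnt <- if (length(counts_avail) == 1L) counts_avail else
      sample(counts_avail, 1L, prob = cw)
    A <- c(cells$poleA_row[i], cells$poleA_col[i])
    B <- c(cells$poleB_row[i], cells$poleB_col[i])
    L <- cells$length_px[i]
    gmax <- max(0.55, 1 - (r_px + 1) / L)
    placed_pix <- integer()
    for (a in seq_len(cnt)) {
      ok <- FALSE
      for (try in 1:50) {
        g <- stats::rnorm(1, p$polar_bias[["mean"]], p$polar_bias[["sd"]])
        if (g < 0.5 || g > gmax) next
        t <- if (stats::runif(1) < 0.5) g else 1 - g
        ctr <- A + t * (B - A)
        rr <- max(1L, floor(ctr[1] - r_px)):min(nr, ceiling(ctr[1] + r_px))
        cc <- max(1L, floor(ctr[2] - r_px)):min(nc, ceiling(ctr[2] + r_px))
        gr <- as.matrix(expand.grid(r = rr, c = cc))
        dd <- sqrt((gr[, 1] - ctr[1])^2 + (gr[, 2] - ctr[2])^2)
        pix <- (gr[dd <= r_px, 2] - 1L) * nr + gr[dd <= r_px, 1]
        pix <- pix[cell_labels[pix] == i]          # clip to the parent cell
        if (length(pix) == 0L || any(pix %in% placed_pix)) next
        next_id <- next_id + 1L
        agg_labels[pix] <- next_id
        placed_pix <- c(placed_pix, pix)
        parent[next_id] <- i
        conc <- stats::runif(1, p$limonene_conc_range[1], p$limonene_conc_range[2])
        aggs[[next_id]] <- data.frame(
          aggregate_id = next_id, cell_id = i,
          ctr_row = mean((pix - 1L) %% nr + 1L),
          ctr_col = mean((pix - 1L) %/% nr + 1L),
          dl_true = g, conc_true = conc, radius_px = r_px)
        ok <- TRUE
        break
      }
      if (!ok) break  # could not fit another disjoint aggregate in this cell
    }
  }
  aggs <- if (length(aggs)) do.call(rbind, aggs) else
    data.frame(aggregate_id = integer(), cell_id = integer(),
               ctr_row = numeric(), ctr_col = numeric(), dl_true = numeric(),
               conc_true = numeric(), radius_px = numeric())

  lim <- matrix(0, nr, nc)
  if (nrow(aggs)) for (j in seq_len(nrow(aggs)))
    lim[agg_labels == j] <- aggs$conc_true[j]
  body <- matrix(0, nr, nc)
  for (i in seq_len(nrow(cells))) body[cell_pix[[i]]] <- cells$body_level[i]
  bg <- matrix(p$background_level, nr, nc)

  structure(list(params = p, cells = cells, aggregates = aggs,
                 cell_mask = cell_mask(cell_labels, p$pixel_size),
                 aggregate_mask = aggregate_mask(agg_labels, parent),
                 maps = list(limonene = lim, cell_body = body, background = bg)),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d cells, %d aggregates, %d x %d px (seed %d)\n",
              nrow(x$cells), nrow(x$aggregates), x$params$image_shape[1],
              x$params$image_shape[2], x$params$seed))
  invisible(x)
}

#' Render a hyperspectral stack from scene truth
#'
#' Forward model D = C S + E: each pixel's spectrum is the nonnegative
#' mixture of the three references weighted by the true concentration
#' maps, optionally blurred by a Gaussian PSF, plus additive noise. The
#' returned truth maps are the pre-noise coefficients.
#'
#' @param truth A [generate_scene()] result.
#' @param refs A [reference_set()] with the 3 channels
#'   limonene / cell_body / background.
#' @param noise_sigma Noise sd (default from `truth$params`).
#' @param seed RNG seed for the noise.
#' @param blur_sigma Gaussian optical blur sd in px applied to each frame
#'   before noise (0 disables).
#' @return List with elements `stack` ([hs_stack()]) and `maps` (the true
#'   concentration maps actually rendered, post-blur if any).
#' @export
render_stack <- function(truth, refs = default_reference_set(),
                         noise_sigma = NULL, seed = truth$params$seed + 1L,
                         blur_sigma = 0) {
  stopifnot(inherits(truth, "scene_truth"), inherits(refs, "reference_set"))
  if (nrow(refs$S) != 3L)
    stop("render_stack needs exactly 3 reference channels", call. = FALSE)
  if (is.null(noise_sigma)) noise_sigma <- truth$params$noise_sigma
  nr <- truth$params$image_shape[1]; nc <- truth$params$image_shape[2]
  maps <- truth$maps
  if (blur_sigma > 0)
    maps <- lapply(maps, function(m)
      EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = blur_sigma)))
  M <- cbind(as.vector(maps$limonene), as.vector(maps$cell_body),
             as.vector(maps$background))
  D <- M %*% refs$S                       # n_pixels x N_lambda
  set.seed(seed)
  if (noise_sigma > 0) {
    if (truth$params$noise_model == "poisson") {
      gain <- 1 / noise_sigma^2           # counts per intensity unit
      D <- matrix(stats::rpois(length(D), pmax(D, 0) * gain) / gain, nrow(D))
    } else {
      D <- D + matrix(stats::rnorm(length(D), 0, noise_sigma), nrow(D))
    }
  }
  arr <- aperm(array(D, dim = c(nr, nc, length(refs$axis))), c(3, 1, 2))
  list(stack = hs_stack(arr, refs$axis, truth$params$pixel_size), maps = maps)
}

#' Render a matched fluorescence channel
#'
#' Aggregate pixels emit fluorescence in proportion to their limonene
#' content; a `(1 - colocal_fraction)` share of the total emission is
#' relocated to random in-cell non-aggregate sites (emulating enzyme not
#' bound in aggregates), then a Gaussian PSF blur and additive noise are
#' applied. Relocation sites are drawn before the split so the result is
#' monotone in `colocal_fraction` at a fixed seed.
#'
#' @param truth A [generate_scene()] result.
#' @param psf_sigma PSF sd in px.
#' @param colocal_fraction Fraction of emission left on aggregates, in
#'   [0, 1].
#' @param noise_sigma Additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return 2D fluorescence image (matrix).
#' @export
render_fluorescence <- function(truth, psf_sigma = 1, colocal_fraction = 0.85,
                                noise_sigma = 0.005,
                                seed = truth$params$seed + 2L) {
  stopifnot(inherits(truth, "scene_truth"),
            colocal_fraction >= 0, colocal_fraction <= 1)
  nr <- truth$params$image_shape[1]; nc <- truth$params$image_shape[2]
  set.seed(seed)
  base <- truth$maps$limonene
  total <- sum(base)
  f <- colocal_fraction * base
  if (total > 0) {
    host <- which(truth$cell_mask$labels > 0 & truth$aggregate_mask$labels == 0)
    n_sites <- min(length(host), max(1L, sum(base > 0)))
    sites <- sample(host, n_sites)
    f[sites] <- f[sites] + (1 - colocal_fraction) * total / n_sites
  }
  if (psf_sigma > 0)
    f <- EBImage::imageData(EBImage::gblur(EBImage::Image(f), sigma = psf_sigma))
  if (noise_sigma > 0) f <- f + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc)
  f
}

#' Generate a calibration dilution series
#'
#' Per replicate, measured intensity = slope * concentration +
#' Gaussian(0, blank_sigma).
#'
#' @param concentrations Concentrations (mM), >= 0; include 0 for blanks.
#' @param slope Sensitivity (a.u. per mM), > 0.
#' @param blank_sigma Noise sd (a.u.).
#' @param n_replicates Replicates per level.
#' @param seed RNG seed.
#' @return data.frame with columns `conc_mm`, `intensity`.
#' @export
generate_calibration_series <- function(concentrations, slope, blank_sigma,
                                        n_replicates = 3L, seed = 1L) {
  stopifnot(all(concentrations >= 0), slope > 0, blank_sigma >= 0,
            n_replicates >= 1)
  set.seed(seed)
  conc <- rep(concentrations, each = n_replicates)
  data.frame(conc_mm = conc,
             intensity = slope * conc +
               stats::rnorm(length(conc), 0, blank_sigma))
}
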