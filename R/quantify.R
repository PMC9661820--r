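# --- central-line geodesics ------------------------------------------------

# Build an igraph over a set of mask pixels: 8-connected, unit weight for
# axial neighbours and sqrt(2) for diagonals.
pixel_graph <- function(coords) {
  n <- nrow(coords)
  r0 <- min(coords[, 1]) - 1L; c0 <- min(coords[, 2]) - 1L
  nr <- max(coords[, 1]) - r0; nc <- max(coords[, 2]) - c0
  lut <- matrix(0L, nr, nc)
  lut[cbind(coords[, 1] - r0, coords[, 2] - c0)] <- seq_len(n)
  from <- integer(); to <- integer(); w <- numeric()
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    rr <- coords[, 1] - r0 + o[1]; cc <- coords[, 2] - c0 + o[2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nid <- integer(n)
    nid[ok] <- lut[cbind(rr[ok], cc[ok])]
    has <- nid > 0L
    from <- c(from, which(has)); to <- c(to, nid[has])
    w <- c(w, rep(if (o[1] != 0L && o[2] != 0L) sqrt(2) else 1, sum(has)))
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

# Longest geodesic path through a pixel set (two farthest-point sweeps,
# exact for elongated shapes): returns the path pixels, cumulative arc
# length, total length L, and the two pole pixels (path endpoints).
central_line <- function(coords) {
  if (nrow(coords) < 2L)
    stop("cell has fewer than 2 pixels; central line undefined", call. = FALSE)
  g <- pixel_graph(coords)
  d0 <- igraph::distances(g, v = 1L)[1L, ]
  d0[!is.finite(d0)] <- -1
  a <- which.max(d0)
  d1 <- igraph::distances(g, v = a)[1L, ]
  d1[!is.finite(d1)] <- -1
  b <- which.max(d1)
  if (d1[b] <= 0)
    stop("degenerate cell: geodesic length is zero", call. = FALSE)
  vp <- igraph::shortest_paths(g, from = a, to = b, output = "vpath")$vpath[[1L]]
  vids <- as.integer(vp)
  pc <- coords[vids, , drop = FALSE]
  steps <- sqrt(rowSums((pc[-1L, , drop = FALSE] -
                         pc[-nrow(pc), , drop = FALSE])^2))
  list(coords = pc, arc = c(0, cumsum(steps)), L = sum(steps),
       poleA = pc[1L, ], poleB = pc[nrow(pc), ])
}

#' Aggregate location along the cell axis (d, L, d/L)
#'
#' The central line is the longest geodesic path through the cell mask
#' (8-connected pixels; its endpoints are the cell poles), so it is well
#' defined for straight and bent rods alike. `L` is the geodesic length
#' of that line. In `centroid` mode the aggregate position is the line
#' pixel nearest the aggregate centroid; in `maxline` mode it is the
#' pixel of maximal intensity along the line. `d` is the arc distance
#' from that position to the farther pole, so d/L is always in
#' [0.5, 1].
#'
#' @param cells A [cell_mask()].
#' @param cell_id Label of the cell to analyse.
#' @param aggregate_centroid Numeric (row, col), required for
#'   `mode = "centroid"`.
#' @param intensity_map 2D matrix, required for `mode = "maxline"`.
#' @param mode `"centroid"` (default) or `"maxline"`.
#' @return List with `d`, `L`, `dl` (all in px except the dimensionless
#'   `dl`) and the pole coordinates.
#' @export
aggregate_location <- function(cells, cell_id, aggregate_centroid = NULL,
                               intensity_map = NULL,
                               mode = c("centroid", "maxline")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cells, "cell_mask"))
  coords <- which(cells$labels == cell_id, arr.ind = TRUE)
  cl <- central_line(coords)
  pos <- if (mode == "centroid") {
    if (is.null(aggregate_centroid))
      stop("centroid mode needs aggregate_centroid", call. = FALSE)
    dd <- (cl$coords[, 1] - aggregate_centroid[1])^2 +
          (cl$coords[, 2] - aggregate_centroid[2])^2
    cl$arc[which.min(dd)]
  } else {
    if (is.null(intensity_map))
      stop("maxline mode needs an intensity map", call. = FALSE)
    v <- intensity_map[cl$coords]
    cl$arc[which.max(v)]
  }
  d <- max(pos, cl$L - pos)
  list(d = d, L = cl$L, dl = d / cl$L, poleA = cl$poleA, poleB = cl$poleB,
       mode = mode)
}

# moment-based major axis length (4 sigma of the leading principal axis)
moment_major_axis <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  cv <- stats::cov(coords) * (nrow(coords) - 1) / nrow(coords)
  4 * sqrt(max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0))
}

# --- feature extraction ----------------------------------------------------

#' Extract per-cell and per-aggregate feature tables
#'
#' Computes the five feature categories per cell (morphometry, aggregate
#' count, SRS window sums, 760 cm^-1 peak intensity, chemical-channel
#' means) and per aggregate (morphometry, location d/L, limonene and cell
#' body intensities, optional fluorescence). Rest-of-cell means exclude
#' the cell's aggregate pixels.
#'
#' @param stack An [hs_stack()] (may be `NULL` to skip window/peak
#'   features).
#' @param maps A `concentration_maps` from [unmix_stack()] or a named list
#'   of matrices containing at least `limonene` and `cell_body`.
#' @param cells A [cell_mask()].
#' @param aggs An [aggregate_mask()].
#' @param windows Named list of [spectral_window()]s (default
#'   [default_windows()]); windows not covered by the stack axis yield NA.
#' @param fluorescence Optional 2D matrix for per-aggregate mean
#'   fluorescence.
#' @param location_mode `"centroid"` or `"maxline"` for d/L.
#' @param rich_threshold Optional threshold: aggregates with
#'   `mean_limonene / rich_norm >= rich_threshold` are flagged
#'   limonene-rich (NA flag when no threshold is given).
#' @param rich_norm Normalization constant for the rich flag (typically
#'   the control-strain cell-body mean, making the threshold a unitless
#'   ratio).
#' @return List of data.frames `cells` and `aggregates`.
#' @export
extract_cell_features <- function(stack, maps, cells, aggs,
                                  windows = default_windows(),
                                  fluorescence = NULL,
                                  location_mode = c("centroid", "maxline"),
                                  rich_threshold = NULL, rich_norm = 1) {
  location_mode <- match.arg(location_mode)
  stopifnot(inherits(cells, "cell_mask"), inherits(aggs, "aggregate_mask"))
  if (inherits(maps, "concentration_maps")) maps <- maps$maps
  lim <- maps$limonene; body <- maps$cell_body
  if (!all(dim(lim) == dim(cells$labels)) ||
      !all(dim(cells$labels) == dim(aggs$labels)))
    stop("maps and masks are not spatially aligned", call. = FALSE)
  if (!is.null(stack) && !all(dim(stack$data)[2:3] == dim(cells$labels)))
    stop("stack and masks are not spatially aligned", call. = FALSE)
  px <- cells$pixel_size
  lab <- cells$labels
  ncell <- max(lab, 0L)
  win_imgs <- list()
  if (!is.null(stack))
    for (wn in names(windows))
      win_imgs[[wn]] <- tryCatch(window_sum(stack, windows[[wn]]),
                                 error = function(e) NULL)
  peak_img <- if (!is.null(stack))
    tryCatch(peak_intensity(stack, 760), error = function(e) NULL) else NULL

  n_agg_per_cell <- tabulate(aggs$parent[seq_len(max(aggs$labels, 0L))],
                             nbins = max(ncell, 1L))
  cell_rows <- vector("list", ncell)
  line_cache <- list()
  for (i in seq_len(ncell)) {
    pix <- which(lab == i)
    coords <- which(lab == i, arr.ind = TRUE)
    rest <- pix[aggs$labels[pix] == 0L]
    cell_rows[[i]] <- data.frame(
      cell_id = i,
      area_px = length(pix),
      area_um2 = if (is.na(px)) NA_real_ else length(pix) * px^2,
      major_axis_len_px = moment_major_axis(coords),
      n_aggregates = n_agg_per_cell[i],
      mean_limonene = mean(lim[pix]),
      mean_limonene_rest = if (length(rest)) mean(lim[rest]) else NA_real_,
      mean_cellbody = mean(body[pix]),
      sum_fingerprint = if (!is.null(win_imgs$fingerprint))
        sum(win_imgs$fingerprint[pix]) else NA_real_,
      sum_ch = if (!is.null(win_imgs$ch)) sum(win_imgs$ch[pix]) else NA_real_,
      peak760 = if (!is.null(peak_img)) mean(peak_img[pix]) else NA_real_)
  }
  cell_tbl <- if (ncell) do.call(rbind, cell_rows) else data.frame(
    cell_id = integer(), area_px = integer(), area_um2 = numeric(),
    major_axis_len_px = numeric(), n_aggregates = integer(),
    mean_limonene = numeric(), mean_limonene_rest = numeric(),
    mean_cellbody = numeric(), sum_fingerprint = numeric(),
    sum_ch = numeric(), peak760 = numeric())

  magg <- max(aggs$labels, 0L)
  agg_rows <- vector("list", magg)
  for (j in seq_len(magg)) {
    pix <- which(aggs$labels == j)
    coords <- which(aggs$labels == j, arr.ind = TRUE)
    ctr <- colMeans(coords)
    ci <- aggs$parent[j]
    loc <- aggregate_location(cells, ci,
                              aggregate_centroid = ctr,
                              intensity_map = lim, mode = location_mode)
    ml <- mean(lim[pix])
    agg_rows[[j]] <- data.frame(
      aggregate_id = j, cell_id = ci,
      area_px = length(pix),
      major_axis_len_px = moment_major_axis(coords),
      d_px = loc$d, L_px = loc$L, dl_ratio = loc$dl,
      mean_limonene = ml, total_limonene = sum(lim[pix]),
      mean_cellbody = mean(body[pix]),
      mean_fluorescence = if (is.null(fluorescence)) NA_real_
                          else mean(fluorescence[pix]),
      limonene_rich = if (is.null(rich_threshold)) NA
                      else ml / rich_norm >= rich_threshold)
  }
  agg_tbl <- if (magg) do.call(rbind, agg_rows) else data.frame(
    aggregate_id = integer(), cell_id = integer(), area_px = integer(),
    major_axis_len_px = numeric(), d_px = numeric(), L_px = numeric(),
    dl_ratio = numeric(), mean_limonene = numeric(),
    total_limonene = numeric(), mean_cellbody = numeric(),
    mean_fluorescence = numeric(), limonene_rich = logical())
  list(cells = cell_tbl, aggregates = agg_tbl)
}

# --- threshold sweep & population summaries --------------------------------

#' Threshold sweep against control populations
#'
#' For every grid threshold, the fraction of each population classified
#' positive (value >= threshold) is computed; the chosen threshold is the
#' smallest grid value at which the control fraction drops to `alpha` or
#' below (default 0: zero control positives). The full curve is returned
#' for plotting.
#'
#' @param values_positive Per-aggregate intensities from the
#'   full-pathway strain.
#' @param values_control Same feature from control strains.
#' @param grid Increasing vector of candidate thresholds.
#' @param alpha Tolerated control positive fraction (default 0).
#' @return List with `chosen` (threshold or NA with a warning when no
#'   grid value qualifies) and `curve` (data.frame threshold /
#'   frac_positive / frac_control).
#' @export
sweep_threshold <- function(values_positive, values_control, grid,
                            alpha = 0) {
  stopifnot(length(values_positive) > 0, length(values_control) > 0,
            all(diff(grid) > 0))
  fp <- vapply(grid, function(t) mean(values_positive >= t), 0)
  fc <- vapply(grid, function(t) mean(values_control >= t), 0)
  ok <- which(fc <= alpha)
  chosen <- if (length(ok)) grid[min(ok)] else {
    warning("no grid threshold brings the control fraction to <= ", alpha,
            call. = FALSE)
    NA_real_
  }
  list(chosen = chosen,
       curve = data.frame(threshold = grid, frac_positive = fp,
                          frac_control = fc))
}

#' Population-level summaries
#'
#' @param cell_tbl,agg_tbl Tables from [extract_cell_features()].
#' @return List: `frac_cells_with_aggregates`,
#'   `frac_cells_limonene_rich` (NA when no aggregate was classified),
#'   `aggregate_count_hist` (named counts over 0..max aggregates per
#'   cell), and `size_intensity` (data.frame of per-aggregate area vs
#'   mean limonene).
#' @export
population_summaries <- function(cell_tbl, agg_tbl) {
  if (nrow(cell_tbl) == 0L) stop("empty cell table", call. = FALSE)
  frac_agg <- mean(cell_tbl$n_aggregates >= 1L)
  frac_rich <- if (nrow(agg_tbl) == 0L || all(is.na(agg_tbl$limonene_rich)))
    NA_real_
  else {
    rich_cells <- unique(agg_tbl$cell_id[agg_tbl$limonene_rich %in% TRUE])
    length(rich_cells) / nrow(cell_tbl)
  }
  counts <- table(factor(cell_tbl$n_aggregates,
                         levels = 0:max(cell_tbl$n_aggregates, 0L)))
  list(frac_cells_with_aggregates = frac_agg,
       frac_cells_limonene_rich = frac_rich,
       aggregate_count_hist = as.integer(counts),
       aggregate_count_levels = as.integer(names(counts)),
       size_intensity = data.frame(area_px = agg_tbl$area_px,
                                   mean_limonene = agg_tbl$mean_limonene))
}

# --- calibration -----------------------------------------------------------

#' Fit a calibration line and limit of detection
#'
#' Ordinary least squares of intensity on concentration; the blank sd is
#' the standard deviation of the conc = 0 replicates and the limit of
#' detection is 3 sigma_blank / slope (3-sigma convention).
#'
#' @param table data.frame with columns `conc_mm` and `intensity`; at
#'   least 3 distinct concentrations including >= 2 blank replicates.
#' @return An object of class `calibration_fit` with `slope`,
#'   `intercept`, `blank_sigma`, `lod_mm`, `r2`.
#' @export
fit_calibration <- function(table) {
  stopifnot(all(c("conc_mm", "intensity") %in% names(table)))
  if (length(unique(table$conc_mm)) < 3L)
    stop("need >= 3 distinct concentrations", call. = FALSE)
  blanks <- table$intensity[table$conc_mm == 0]
  if (length(blanks) < 2L)
    stop("need >= 2 blank (conc = 0) replicates for the blank sd",
         call. = FALSE)
  fit <- stats::lm(intensity ~ conc_mm, data = table)
  sm <- suppressWarnings(summary(fit))   # exact fits warn harmlessly
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop("invalid calibration: slope must be > 0 (got ", signif(slope, 4), ")",
         call. = FALSE)
  bs <- stats::sd(blanks)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 blank_sigma = bs, lod_mm = 3 * bs / slope,
                 r2 = sm$r.squared,
                 slope_se = sm$coefficients[2L, 2L]),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> slope %.4g a.u./mM, blank sd %.4g, LOD %.4g mM, R2 %.4f\n",
              x$slope, x$blank_sigma, x$lod_mm, x$r2))
  invisible(x)
}

#' Estimate concentration from a calibration fit
#'
#' Inverts the calibration line: (intensity - blank) / slope, floored at
#' zero.
#'
#' @param intensity Measured intensity (a.u.), vectorized.
#' @param blank Blank intensity (a.u.).
#' @param fit A [fit_calibration()] result.
#' @return Concentration(s) in mM.
#' @export
estimate_concentration <- function(intensity, blank, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  pmax(0, (intensity - blank) / fit$slope)
}

#' Compare two populations (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test with normal
#' approximation, tie correction and continuity correction.
#'
#' @param values_a,values_b Numeric samples (n >= 1 each).
#' @return List with `statistic` (the U statistic for a over b) and
#'   `p_value`.
#' @export
compare_populations <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("empty sample", call. = FALSE)
  wt <- stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
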