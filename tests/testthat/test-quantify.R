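test_that("aggregate_location recovers symmetric and polar positions", {
  cm <- paint_rod()   # horizontal rod, row 20, cols ~10..70
  coords <- which(cm$labels == 1L, arr.ind = TRUE)
  L_approx <- diff(range(coords[, 2]))
  mid <- c(20, mean(range(coords[, 2])))
  loc_mid <- aggregate_location(cm, 1L, aggregate_centroid = mid)
  expect_lt(abs(loc_mid$dl - 0.5), 1 / L_approx + 0.01)
  pole <- c(20, max(coords[, 2]))
  loc_pole <- aggregate_location(cm, 1L, aggregate_centroid = pole)
  expect_gt(loc_pole$dl, 1 - 1.5 / L_approx)
  expect_lte(loc_pole$dl, 1 + 1e-12)
  # maxline mode finds the brightest pixel along the line
  img <- matrix(0, 40, 80)
  img[20, 55] <- 10
  loc_max <- aggregate_location(cm, 1L, intensity_map = img, mode = "maxline")
  want <- (55 - min(coords[, 2])) / L_approx
  want <- max(want, 1 - want)
  expect_lt(abs(loc_max$dl - want), 1.5 / L_approx)
  expect_error(aggregate_location(cm, 1L), "needs aggregate_centroid")
  # a 1-pixel "cell" is degenerate
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_error(aggregate_location(cell_mask(one), 1L,
                                  aggregate_centroid = c(3, 3)),
               "fewer than 2 pixels")
})

test_that("both location modes agree for fractional positions on rods", {
  for (g in c(0.6, 0.75, 0.9)) {
    cm <- paint_rod(nr = 30L, nc = 100L, ctr_row = 15, col_from = 10,
                    col_to = 90, half_width = 4)
    coords <- which(cm$labels == 1L, arr.ind = TRUE)
    c_lo <- min(coords[, 2]); c_hi <- max(coords[, 2])
    L <- c_hi - c_lo
    target_col <- c_lo + (1 - g) * L   # distance g*L from the far (high) pole
    ctr <- c(15, target_col)
    img <- matrix(0, 30, 100); img[15, round(target_col)] <- 5
    lc <- aggregate_location(cm, 1L, aggregate_centroid = ctr)
    lm <- aggregate_location(cm, 1L, intensity_map = img, mode = "maxline")
    expect_lt(abs(lc$dl - g), 1.5 / L)
    expect_lt(abs(lm$dl - g), 1.5 / L)
    expect_lt(abs(lc$dl - lm$dl), 2 / L)
  }
})

test_that("feature extraction matches hand-computed region statistics", {
  labels <- matrix(0L, 20, 20)
  labels[6:15, 4:7] <- 1L            # 10 x 4 rectangle, area 40
  cm <- cell_mask(labels, pixel_size = 0.1)
  agg0 <- aggregate_mask(matrix(0L, 20, 20), integer(0))
  lim <- matrix(0, 20, 20); lim[labels == 1L] <- 2.0
  maps <- list(limonene = lim, cell_body = matrix(1, 20, 20))
  f <- extract_cell_features(NULL, maps, cm, agg0)
  expect_equal(f$cells$area_px, 40L)
  expect_equal(f$cells$area_um2, 40 * 0.01)
  expect_equal(f$cells$mean_limonene, 2.0)
  expect_equal(f$cells$n_aggregates, 0L)
  expect_equal(nrow(f$aggregates), 0L)
  # rest-of-cell mean excludes aggregate pixels
  agglab <- matrix(0L, 20, 20); agglab[8:9, 5:6] <- 1L
  am <- aggregate_mask(agglab, 1L, cells = cm)
  lim2 <- lim; lim2[agglab == 1L] <- 10
  f2 <- extract_cell_features(NULL, list(limonene = lim2,
                                         cell_body = matrix(1, 20, 20)),
                              cm, am)
  expect_equal(f2$cells$mean_limonene_rest, 2.0)
  expect_equal(f2$cells$mean_limonene, (36 * 2 + 4 * 10) / 40)
  expect_equal(f2$aggregates$mean_limonene, 10)
  expect_equal(f2$aggregates$total_limonene, 40)
  expect_equal(f2$cells$n_aggregates, 1L)
  expect_error(extract_cell_features(NULL, maps, cm,
    aggregate_mask(matrix(0L, 5, 5), integer(0))), "aligned")
})

test_that("per-aggregate limonene means track the generating concentrations", {
  fx <- fixture_scene()
  rend <- render_stack(fx$truth, fx$refs, seed = 71L)
  maps <- unmix_stack(rend$stack, fx$refs)
  f <- extract_cell_features(rend$stack, maps, fx$truth$cell_mask,
                             fx$truth$aggregate_mask)
  m <- merge(f$aggregates, fx$truth$aggregates, by = "aggregate_id")
  # LASSO shrinks by ~lambda and noise adds scatter; demand close tracking
  expect_gt(cor(m$mean_limonene, m$conc_true), 0.95)
  expect_lt(max(abs(m$mean_limonene - m$conc_true)), 0.15)
})

test_that("threshold sweep selects the smallest clean grid value", {
  sep <- sweep_threshold(values_positive = c(1.3, 1.5, 2.0),
                         values_control = c(0.2, 0.5, 0.9),
                         grid = seq(0.5, 2, by = 0.1))
  expect_equal(sep$chosen, 1.0)
  expect_warning(
    same <- sweep_threshold(1:10, 1:10, grid = c(1, 5)),
    "no grid threshold")
  expect_true(is.na(same$chosen))
  # counting oracle on overlapping Gaussian populations
  set.seed(10)
  pos <- rnorm(500, 1.5, 0.4); ctl <- rnorm(500, 0.8, 0.3)
  grid <- seq(0, 3, by = 0.05)
  sw <- sweep_threshold(pos, ctl, grid)
  for (ti in c(1, 20, 40, 61)) {
    expect_equal(sw$curve$frac_positive[ti],
                 sum(pos >= grid[ti]) / length(pos))
    expect_equal(sw$curve$frac_control[ti],
                 sum(ctl >= grid[ti]) / length(ctl))
  }
  # monotone non-increasing curves
  expect_true(all(diff(sw$curve$frac_positive) <= 0))
  expect_true(all(diff(sw$curve$frac_control) <= 0))
})

test_that("population summaries count aggregate-bearing and rich cells", {
  cells <- data.frame(cell_id = 1:10,
                      n_aggregates = c(1, 2, rep(0, 8)))
  aggs <- data.frame(aggregate_id = 1:3, cell_id = c(1, 2, 2),
                     area_px = c(10, 12, 9),
                     mean_limonene = c(0.5, 0.8, 0.2),
                     limonene_rich = c(FALSE, FALSE, FALSE))
  s <- population_summaries(cells, aggs)
  expect_equal(s$frac_cells_with_aggregates, 0.2)
  expect_equal(s$frac_cells_limonene_rich, 0)
  expect_equal(s$aggregate_count_hist, c(8L, 1L, 1L))
  # invariant under cell label permutation
  perm <- sample(10)
  cells2 <- cells; cells2$cell_id <- perm[cells$cell_id]
  aggs2 <- aggs; aggs2$cell_id <- perm[aggs$cell_id]
  s2 <- population_summaries(cells2, aggs2)
  expect_equal(s2$frac_cells_with_aggregates, s$frac_cells_with_aggregates)
  expect_equal(s2$frac_cells_limonene_rich, s$frac_cells_limonene_rich)
  expect_error(population_summaries(cells[0, ], aggs), "empty")
  # rich flag of NA propagates as NA fraction
  aggs$limonene_rich <- NA
  expect_true(is.na(population_summaries(cells, aggs)$frac_cells_limonene_rich))
})

test_that("calibration fits reproduce exact lines and the 3-sigma LOD", {
  exact <- data.frame(conc_mm = c(0, 0, 25, 50, 100),
                      intensity = c(0, 0, 50, 100, 200))
  fit <- fit_calibration(exact)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$lod_mm, 0)
  expect_equal(fit$r2, 1)
  # symmetric blanks with sd exactly 14 around the exact line:
  a <- 14 / sqrt(2)
  tbl <- data.frame(conc_mm = c(0, 0, 25, 50, 100),
                    intensity = c(-a, a, 50, 100, 200))
  fit14 <- fit_calibration(tbl)
  expect_equal(fit14$slope, 2, tolerance = 1e-12)
  expect_equal(fit14$blank_sigma, 14, tolerance = 1e-12)
  expect_equal(fit14$lod_mm, 21, tolerance = 1e-12)
  # validation
  expect_error(fit_calibration(data.frame(conc_mm = c(0, 0, 1),
                                          intensity = c(0, 0, 1))),
               "3 distinct")
  expect_error(fit_calibration(data.frame(conc_mm = c(1, 2, 3),
                                          intensity = 1:3)),
               "blank")
  expect_error(fit_calibration(data.frame(conc_mm = c(0, 0, 1, 2),
                                          intensity = c(1, 1, 0.5, 0))),
               "slope")
})

test_that("noisy calibration recovers the injected slope within 2 SEs", {
  tbl <- generate_calibration_series(c(0, 25, 50, 75, 100), slope = 2,
                                     blank_sigma = 14, n_replicates = 1000,
                                     seed = 12L)
  fit <- fit_calibration(tbl)
  expect_lt(abs(fit$slope - 2), 2 * fit$slope_se)
  expect_gt(fit$r2, 0.9)
})

test_that("concentration estimates invert the calibration line", {
  fit <- fit_calibration(data.frame(conc_mm = c(0, 0, 25, 50),
                                    intensity = c(0, 0, 50, 100)))
  expect_equal(estimate_concentration(10, 10, fit), 0)
  expect_equal(estimate_concentration(10 + 2 * 50, 10, fit), 50)
  expect_equal(estimate_concentration(5, 10, fit), 0)  # floored
})

test_that("rank-sum comparison behaves at the extremes", {
  same <- compare_populations(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.95)
  apart <- compare_populations(c(1, 2, 3), c(10, 20, 30))
  expect_equal(apart$statistic, 0)
  expect_error(compare_populations(numeric(0), 1:3), "empty")
})
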