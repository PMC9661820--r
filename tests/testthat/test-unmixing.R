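ref_from_matrix <- function(S, axis = seq_len(ncol(S))) {
  reference_set(lapply(seq_len(nrow(S)), function(j)
    spectrum(axis, S[j, ], paste0("r", j))))
}

raw_cfg <- function(...) unmix_config(..., normalize_refs = "none")

test_that("the unmixing objective matches its definition", {
  set.seed(1)
  S <- matrix(rnorm(2 * 5), 2, 5)
  refs <- ref_from_matrix(S)
  cc <- c(1, 2)
  d <- as.vector(cc %*% S)
  expect_equal(unmix_objective(d, cc, refs, lam = 0), 0)
  expect_equal(unmix_objective(d, c(0, 0), refs, lam = 0), 0.5 * sum(d^2))
  # hand-expanded arithmetic oracle
  d2 <- rnorm(5)
  hand <- 0
  for (i in 1:5) hand <- hand + (d2[i] - (1 * S[1, i] + 2 * S[2, i]))^2
  hand <- hand / 2 + 0.3 * (abs(1) + abs(2))
  expect_equal(unmix_objective(d2, cc, refs, lam = 0.3), hand)
  expect_error(unmix_objective(d2[1:3], cc, refs, 0), "dimension mismatch")
})

test_that("single-reference pixels follow the analytic soft threshold", {
  set.seed(2)
  for (i in 1:20) {
    s <- rnorm(8); d <- rnorm(8); lam <- runif(1, 0, 3)
    refs <- ref_from_matrix(matrix(s, 1))
    cc <- as.numeric(lasso_unmix_pixel(d, refs,
      raw_cfg(lam = lam, nonnegative = FALSE, tol = 1e-16)))
    rho <- sum(s * d)
    closed <- sign(rho) * max(abs(rho) - lam, 0) / sum(s^2)
    expect_equal(cc, closed, tolerance = 1e-10)
  }
  # lam = 0 is the least-squares projection: d = 3 s -> c = 3
  s <- rnorm(8)
  refs <- ref_from_matrix(matrix(s, 1))
  expect_equal(as.numeric(lasso_unmix_pixel(3 * s, refs,
    raw_cfg(lam = 0, nonnegative = FALSE))), 3, tolerance = 1e-8)
  # an all-zero spectrum maps to zero coefficients for any lam
  expect_equal(as.numeric(lasso_unmix_pixel(rep(0, 8), refs,
    raw_cfg(lam = 0.5))), 0)
  expect_error(lasso_unmix_pixel(c(1, NA, rep(0, 6)), refs, raw_cfg()),
               "non-finite")
  expect_error(lasso_unmix_pixel(1:4, refs, raw_cfg()), "does not match")
})

test_that("lambda = 0 solutions agree with the normal equations", {
  set.seed(3)
  for (i in 1:10) {
    S <- matrix(rnorm(3 * 8), 3, 8)
    d <- rnorm(8)
    refs <- ref_from_matrix(S)
    cc <- suppressWarnings(as.numeric(lasso_unmix_pixel(d, refs,
      raw_cfg(lam = 0, nonnegative = FALSE, tol = 1e-20, max_iter = 2e5))))
    ls <- as.numeric(solve(S %*% t(S), S %*% d))
    expect_lt(sqrt(sum((cc - ls)^2)) / sqrt(sum(ls^2)), 1e-8)
  }
})

test_that("solutions satisfy descent, shrinkage and sparsity properties", {
  set.seed(4)
  for (i in 1:10) {
    S <- matrix(rnorm(3 * 10), 3, 10)
    refs <- ref_from_matrix(S)
    d <- rnorm(10)
    lam1 <- runif(1, 0, 1); lam2 <- lam1 + runif(1, 0.1, 2)
    c1 <- as.numeric(lasso_unmix_pixel(d, refs,
      raw_cfg(lam = lam1, nonnegative = FALSE, tol = 1e-12)))
    c2 <- as.numeric(lasso_unmix_pixel(d, refs,
      raw_cfg(lam = lam2, nonnegative = FALSE, tol = 1e-12)))
    # objective no worse than the zero start
    expect_lte(unmix_objective(d, c1, refs, lam1),
               unmix_objective(d, rep(0, 3), refs, lam1) + 1e-12)
    # solution path shrinks in l1 norm as lambda grows
    expect_lte(sum(abs(c2)), sum(abs(c1)) + 1e-9)
    # above the activation threshold the solution is exactly zero
    lam_max <- max(abs(S %*% d))
    c0 <- as.numeric(lasso_unmix_pixel(d, refs,
      raw_cfg(lam = lam_max * 1.001, nonnegative = FALSE)))
    expect_equal(c0, rep(0, 3))
  }
})

test_that("nonnegative fitting clips coordinates at zero", {
  set.seed(5)
  S <- matrix(abs(rnorm(2 * 8)), 2, 8)
  refs <- ref_from_matrix(S)
  d <- -as.vector(c(1, 1) %*% S)   # anti-correlated signal
  cc <- as.numeric(lasso_unmix_pixel(d, refs, raw_cfg(lam = 0)))
  expect_equal(cc, c(0, 0))
})

test_that("glmnet agrees with the coordinate-descent LASSO", {
  skip_if_not_installed("glmnet")
  set.seed(6)
  S <- matrix(rnorm(3 * 30), 3, 30)
  refs <- ref_from_matrix(S)
  truth <- c(1.2, 0, 0.4)
  d <- as.vector(truth %*% S) + rnorm(30, 0, 0.05)
  lam <- 0.4
  ours <- as.numeric(lasso_unmix_pixel(d, refs,
    raw_cfg(lam = lam, nonnegative = FALSE, tol = 1e-16, max_iter = 1e5)))
  gfit <- glmnet::glmnet(t(S), d, lambda = lam / length(d),
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-14)
  theirs <- as.numeric(gfit$beta)
  expect_equal(ours, theirs, tolerance = 1e-4)
})

test_that("background spectrum estimation recovers the outside spectrum", {
  axis <- seq(670, 900, 10)
  # uniform stack: every pixel shares one spectrum
  sp <- sin(seq_along(axis)) + 2
  st <- hs_stack(array(rep(sp, 25), dim = c(24, 5, 5)), axis)
  labels <- matrix(0L, 5, 5); labels[2:3, 2:3] <- 1L
  est <- estimate_background_spectrum(st, cell_mask(labels))
  expect_equal(est$intensity, sp)
  # two-region stack: exact recovery of the outside spectrum
  inside <- rep(5, 24)
  dat <- array(rep(sp, 25), dim = c(24, 5, 5))
  for (rc in which(labels == 1L)) dat[, (rc - 1) %% 5 + 1, (rc - 1) %/% 5 + 1] <- inside
  st2 <- hs_stack(dat, axis)
  expect_equal(estimate_background_spectrum(st2, cell_mask(labels))$intensity, sp)
  # auto (Otsu) mask on a rendered scene approaches the generator background
  fx <- fixture_scene()
  rend <- render_stack(fx$truth, fx$refs, seed = 55L)
  est3 <- estimate_background_spectrum(rend$stack)
  n_bg <- sum(fx$truth$cell_mask$labels == 0L)
  tol <- 5 * fx$params$noise_sigma / sqrt(n_bg) +
    1e-9  # frames are means over >= n_bg background pixels
  truth_bg <- fx$refs$S[3, ] * fx$params$background_level
  expect_true(all(abs(est3$intensity - truth_bg) < pmax(tol, 0.002)))
  expect_error(estimate_background_spectrum(st,
    cell_mask(matrix(1L, 5, 5))), "empty")
})

test_that("noiseless stacks unmix back to the exact truth maps", {
  fx <- fixture_scene()
  rend <- render_stack(fx$truth, fx$refs, noise_sigma = 0, seed = 1L)
  maps <- unmix_stack(rend$stack, fx$refs,
                      unmix_config(lam = 0, tol = 1e-14, max_iter = 5000L))
  expect_lt(max(abs(maps$maps$limonene - fx$truth$maps$limonene)), 1e-6)
  expect_lt(max(abs(maps$maps$cell_body - fx$truth$maps$cell_body)), 1e-6)
  expect_lt(max(abs(maps$maps$background - fx$truth$maps$background)), 1e-6)
  expect_lt(max(maps$residual_norm), 1e-6)
})

test_that("pure background stacks yield a clean limonene channel", {
  p <- scene_params(image_shape = c(64L, 64L), n_cells = 0L, seed = 2L)
  tr <- generate_scene(p)
  rend <- render_stack(tr, seed = 3L)
  maps <- unmix_stack(rend$stack, default_reference_set())
  expect_lt(max(maps$maps$limonene), 0.05)
  expect_lt(mean(maps$maps$limonene), 0.005)
})

test_that("unmixing commutes with spatial cropping", {
  fx <- fixture_scene()
  rend <- render_stack(fx$truth, fx$refs, seed = 77L)
  cfg <- unmix_config(lam = 0.05)
  whole <- unmix_stack(rend$stack, fx$refs, cfg)
  rows <- 40:90; cols <- 100:160
  part <- unmix_stack(crop_stack(rend$stack, rows, cols), fx$refs, cfg)
  expect_equal(part$maps$limonene, whole$maps$limonene[rows, cols],
               tolerance = 1e-10)
  expect_equal(part$residual_norm, whole$residual_norm[rows, cols],
               tolerance = 1e-10)
})

test_that("axis mismatches are rejected unless resampling is enabled", {
  fx <- fixture_scene()
  rend <- render_stack(fx$truth, fx$refs, noise_sigma = 0, seed = 1L)
  fine <- default_reference_set(axis = seq(670, 900, by = 5))
  expect_error(unmix_stack(rend$stack, fine, unmix_config()), "resample")
  maps <- unmix_stack(rend$stack, fine, unmix_config(lam = 0, tol = 1e-12),
                      resample = TRUE)
  # linear resampling of smooth references keeps recovery close to truth
  expect_gt(cor(as.vector(maps$maps$limonene),
                as.vector(fx$truth$maps$limonene)), 0.99)
})

test_that("choose_lambda keeps the background residual within its budget", {
  fx <- fixture_scene()
  rend <- render_stack(fx$truth, fx$refs, seed = 91L)
  lam <- choose_lambda(rend$stack, fx$refs, candidates = c(0.01, 0.05, 0.2, 1),
                       cell_mask = fx$truth$cell_mask)
  expect_true(lam %in% c(0, 0.01, 0.05, 0.2, 1))
  # an absurdly large penalty must be rejected (residual would blow up)
  expect_lt(lam, 1)
})
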