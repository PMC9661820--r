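# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# moderate seeded scene with its rendered stack, reused across test files
fixture_scene <- function() {
  if (is.null(.fixtures$scene)) {
    p <- scene_params(image_shape = c(256L, 256L), n_cells = 20L, seed = 42L)
    truth <- generate_scene(p)
    refs <- default_reference_set()
    rend <- render_stack(truth, refs)
    .fixtures$scene <- list(params = p, truth = truth, refs = refs,
                            stack = rend$stack)
  }
  .fixtures$scene
}

# paint a horizontal spherocylinder mask: returns a cell_mask with one cell
paint_rod <- function(nr = 40L, nc = 80L, ctr_row = 20, col_from = 10,
                      col_to = 70, half_width = 4) {
  m <- matrix(0L, nr, nc)
  a <- c(ctr_row, col_from + half_width)
  b <- c(ctr_row, col_to - half_width)
  gr <- as.matrix(expand.grid(r = 1:nr, c = 1:nc))
  vr <- b[1] - a[1]; vc <- b[2] - a[2]; l2 <- vr^2 + vc^2
  t <- pmin(1, pmax(0, ((gr[, 1] - a[1]) * vr + (gr[, 2] - a[2]) * vc) / l2))
  d <- sqrt((gr[, 1] - (a[1] + t * vr))^2 + (gr[, 2] - (a[2] + t * vc))^2)
  m[gr[d <= half_width, , drop = FALSE]] <- 1L
  cell_mask(m, pixel_size = 0.1)
}
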