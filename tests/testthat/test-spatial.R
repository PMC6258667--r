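test_that("lattice construction validates stability and source placement", {
  expect_error(lattice_config(n_rows = 2), "3 x 3")
  expect_error(lattice_config(D = 10, dt = 0.1), "stability")
  cfg <- lattice_config(n_rows = 10, n_cols = 10, source_fraction = 0,
                        seed = 4)
  f <- init_field(cfg, wt_params())
  expect_equal(sum(f$sources), 0)
  cfg1 <- lattice_config(n_rows = 10, n_cols = 10, source_fraction = 1)
  expect_equal(sum(init_field(cfg1, wt_params())$sources), 100)
  cfg2 <- lattice_config(n_rows = 10, n_cols = 10, source_fraction = 0.1,
                         seed = 4)
  a <- init_field(cfg2, wt_params())
  b <- init_field(cfg2, wt_params())
  expect_identical(a$sources, b$sources)
  expect_equal(sum(a$sources), 10)
})

test_that("epithelial field without sources is a fixed point", {
  f <- init_field(small_config(), wt_params())
  g <- f
  for (i in 1:50) g <- field_step(g)
  expect_lt(max(abs(g$E - f$E)), 1e-4)
  expect_lt(max(abs(g$T - f$T)), 1e-4)
})

test_that("diffusion alone conserves total TGF-beta on the torus", {
  cfg <- small_config()
  f <- init_field(cfg, wt_params())
  set.seed(8)
  f$T <- matrix(runif(64, 0, 10), 8, 8)
  total0 <- sum(f$T)
  # pure diffusion update, bypassing reaction
  for (i in 1:1000)
    f$T <- f$T + cfg$dt * cfg$D * emtswitch:::.laplacian5(f$T, cfg$dx)
  expect_equal(sum(f$T), total0, tolerance = 1e-10 * total0)
  expect_true(all(f$T >= 0))
})

test_that("uniform lattice reproduces the single-cell trajectory", {
  p <- wt_params()
  cfg <- small_config()
  f <- init_field(cfg, p)
  snaps <- run_field(f, 3, record_times = 3, exogenous = 15)
  s <- snaps[[1]]
  # all sites identical (uniform field, Laplacian vanishes)
  expect_lt(diff(range(s$E)), 1e-12)
  tr <- integrate_protocol(p, protocol_constant(15, 3),
                           output_grid = c(0, 3))
  for (v in c("T", "M", "Z", "E"))
    expect_equal(s[[v]][1, 1], tr$states[2, v], tolerance = 0.02,
                 ignore_attr = TRUE)
})

test_that("cyclically shifting sources shifts the whole solution", {
  p <- wt_params()
  base <- lattice_config(n_rows = 12, n_cols = 12, source_fraction = 0,
                         source_dose = 300, source_duration = 5)
  src <- c(14, 40, 77)
  cfg1 <- base; cfg1$source_index <- src
  # shift by one row (cyclic): index + 1 within each column of 12
  shift1 <- function(i) {
    r <- (i - 1) %% 12; c <- (i - 1) %/% 12
    ((r + 1) %% 12) + c * 12 + 1
  }
  cfg2 <- base; cfg2$source_index <- shift1(src)
  s1 <- run_field(init_field(cfg1, p), 4, record_times = 4)[[1]]
  s2 <- run_field(init_field(cfg2, p), 4, record_times = 4)[[1]]
  shifted <- rbind(s1$E[12, , drop = FALSE], s1$E[-12, , drop = FALSE])
  expect_equal(s2$E, shifted, tolerance = 1e-12)
})

test_that("mesenchymal fraction and patch size summarise the E field", {
  p <- wt_params()
  f <- init_field(small_config(), p)
  thr <- wt_threshold()
  expect_equal(mesenchymal_fraction(f, thr), 0)
  expect_equal(largest_patch(f, thr), 0L)
  # force a checkerboard of mesenchymal sites
  f$E <- matrix(ifelse((row(f$E) + col(f$E)) %% 2 == 0, thr / 10, 2 * thr),
                8, 8)
  expect_equal(mesenchymal_fraction(f, thr), 0.5)
  expect_equal(largest_patch(f, thr), 1L)   # diagonal sites are not adjacent
  # full mesenchymal field: one torus-spanning patch
  f$E <- matrix(thr / 10, 8, 8)
  expect_equal(mesenchymal_fraction(f, thr), 1)
  expect_equal(largest_patch(f, thr), 64L)
})

test_that("halving dt changes the final mesenchymal fraction marginally", {
  p <- wt_params()
  mk <- function(dt) {
    cfg <- lattice_config(dt = dt, seed = 6)
    run_field(init_field(cfg, p), 20, record_times = 20)[[1]]
  }
  f1 <- mesenchymal_fraction(mk(0.02))
  f2 <- mesenchymal_fraction(mk(0.01))
  expect_lt(abs(f1 - f2), 0.01 + 1e-9)
})

test_that("spatial reversion matches the single cell when autocrine is off", {
  noauto <- emt_params(k_T = 1e-6)
  cfg <- lattice_config(n_rows = 6, n_cols = 6, source_fraction = 0)
  r <- reversion_field_experiment(noauto, cfg, pre_dose = 20,
                                  pre_duration = 15, post_duration = 10,
                                  record_times = seq(0, 10, 0.5))
  tr <- integrate_protocol(noauto, protocol_withdrawal(20, 15, 10),
                           output_grid = 15 + seq(0, 10, 0.5))
  det_frac <- as.numeric(tr$states[, "E"] < r$threshold)
  # uniform field: the lattice flips epithelial when the single cell does
  flip_lattice <- r$times[which(r$fractions < 0.5)[1]]
  flip_cell <- seq(0, 10, 0.5)[which(det_frac < 0.5)[1]]
  expect_equal(flip_lattice, flip_cell, tolerance = 1)

  # zero post-duration keeps the pre-withdrawal state
  r0 <- reversion_field_experiment(wt_params(), cfg, pre_dose = 20,
                                   pre_duration = 15, post_duration = 0,
                                   record_times = 0)
  expect_equal(r0$fractions, 1)
})
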