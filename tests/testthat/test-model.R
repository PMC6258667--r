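test_that("derivatives match the closed forms at limiting states", {
  p <- wt_params()
  # all-zero state: repression terms vanish, production is maximal
  d0 <- emt_derivatives(c(T = 0, M = 0, Z = 0, E = 0), p, dose = 0)
  expect_equal(unname(d0), c(p$k_T, p$b_M + p$k_M, p$b_Z, p$b_E + p$k_E))

  # saturating ZEB silences both repressed promoters
  dz <- emt_derivatives(c(T = 1, M = 2, Z = 1e9, E = 3), p, dose = 0)
  expect_equal(dz[["M"]], p$b_M - p$d_M * 2, tolerance = 1e-6)
  expect_equal(dz[["E"]], p$b_E - p$d_E * 3, tolerance = 1e-6)

  expect_error(emt_derivatives(c(T = -1, M = 0, Z = 0, E = 0), p),
               "non-negative")
  expect_error(emt_derivatives(c(T = 1, M = 0, Z = 0, E = 0), p, dose = -2),
               "dose")
})

test_that("steady states are fixed points with near-zero residual rates", {
  p <- wt_params()
  for (dose in c(0, 7, 20)) {
    s <- steady_state(p, dose)
    expect_true(attr(s, "converged"))
    rates <- emt_derivatives(.subset(s, 1:4), p, dose)
    expect_lt(max(abs(rates) / (abs(s) + 1e-10)), 1e-6)
  }
})

test_that("memory: distinct attractors inside the window, one outside", {
  p <- wt_params()
  mid <- 7
  epi <- steady_state(p, mid, init = epithelial_state(p))
  mes <- steady_state(p, mid, init = c(T = 30, M = 0.01, Z = 2, E = 0.05))
  expect_gt(abs(epi[["E"]] - mes[["E"]]), 10 * 1e-7)
  expect_gt(epi[["E"]], 0.5)   # epithelial: E high, miR-200 high, ZEB low
  expect_gt(epi[["M"]], 0.5)
  expect_lt(epi[["Z"]], 0.2)
  expect_lt(mes[["E"]], 0.1)

  # far above the window every history converges to the mesenchymal state
  hi_a <- steady_state(p, 25, init = epithelial_state(p))
  hi_b <- steady_state(p, 25, init = c(T = 40, M = 0.01, Z = 3, E = 0.01))
  expect_equal(hi_a[["E"]], hi_b[["E"]], tolerance = 1e-4)
  expect_lt(hi_a[["E"]], 0.1)
})

test_that("integration handles protocols exactly and conserves non-negativity", {
  p <- wt_params()
  # zero-duration protocol returns only the initial state
  tr0 <- integrate_protocol(p, protocol_constant(5, 0),
                            init = c(T = 1, M = 1, Z = 1, E = 1))
  expect_equal(tr0$times, 0)
  expect_equal(unname(tr0$states[1, ]), c(1, 1, 1, 1))

  # starting at a steady state stays there under the matching dose
  s <- steady_state(p, 4)
  tr <- integrate_protocol(p, protocol_constant(4, 20), init = s,
                           output_grid = seq(0, 20, 2))
  expect_lt(max(abs(sweep(tr$states, 2, as.numeric(s)))), 1e-5)

  # pulse protocols: non-negative states throughout
  tr2 <- integrate_protocol(p, protocol_pulse(20, 3, 30),
                            output_grid = seq(0, 30, 0.5))
  expect_true(all(tr2$states >= 0))
})

test_that("tolerance refinement converges (self-consistency)", {
  p <- wt_params()
  proto <- protocol_pulse(15, 5, 12)
  g <- seq(0, 12, 1)
  a <- integrate_protocol(p, proto, output_grid = g, rel_tol = 1e-6)
  b <- integrate_protocol(p, proto, output_grid = g, rel_tol = 5e-7)
  final_a <- a$states[nrow(a$states), ]
  final_b <- b$states[nrow(b$states), ]
  expect_lt(max(abs(final_a - final_b) / (abs(final_b) + 1e-10)), 10 * 1e-6)
})

test_that("autonomy: delaying a pulse delays the response identically", {
  p <- wt_params()
  shift <- 4
  g <- seq(0, 10, 0.5)
  tr1 <- integrate_protocol(p, protocol_pulse(20, 3, 10), output_grid = g)
  pr2 <- dose_protocol(data.frame(start = c(0, shift, shift + 3),
                                  end = c(shift, shift + 3, shift + 10),
                                  dose = c(0, 20, 0)))
  tr2 <- integrate_protocol(p, pr2, output_grid = shift + g)
  expect_equal(tr2$states, tr1$states, tolerance = 1e-5)
})

test_that("trajectory export round-trips through CSV", {
  p <- wt_params()
  tr <- integrate_protocol(p, protocol_constant(3, 2),
                           output_grid = seq(0, 2, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$time, tr$times)
  expect_equal(back$E, unname(tr$states[, "E"]), tolerance = 1e-9)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$params$k_Z, p$k_Z)
})
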