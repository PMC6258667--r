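test_that("noise-free ensemble degenerates to the deterministic trajectory", {
  p <- wt_params()
  # compare away from the fast commitment transit, where the Euler scheme's
  # small timing shift would be amplified
  proto <- protocol_constant(15, 14)
  snaps <- simulate_population(p, proto, n_cells = 5,
                               noise = noise_spec(sigma_mult = 0, ic_cv = 0),
                               record_times = c(1, 14))
  tr <- integrate_protocol(p, proto, output_grid = c(0, 1, 14))
  for (k in 1:2) {
    st <- snaps[[k]]$states
    ref <- tr$states[k + 1, ]
    expect_lt(max(abs(st[1, ] - ref) / (abs(ref) + 1e-8)), 0.03)
    # all cells identical
    expect_equal(max(apply(st, 2, function(col) diff(range(col)))), 0)
  }
})

test_that("ensembles are bit-identical under a repeated seed", {
  p <- wt_params()
  proto <- protocol_constant(8, 2)
  ns <- noise_spec(seed = 99)
  a <- simulate_population(p, proto, 50, ns, record_times = 2)
  b <- simulate_population(p, proto, 50, ns, record_times = 2)
  expect_identical(a[[1]]$E_samples, b[[1]]$E_samples)
  c <- simulate_population(p, proto, 50, noise_spec(seed = 100),
                           record_times = 2)
  expect_false(identical(a[[1]]$E_samples, c[[1]]$E_samples))
})

test_that("population mean approaches the deterministic core as noise shrinks", {
  p <- wt_params()
  proto <- protocol_constant(6, 8)
  det <- integrate_protocol(p, proto, output_grid = c(0, 8))
  ref <- det$states[2, "E"]
  errs <- vapply(c(0.05, 0.0125), function(s) {
    sn <- simulate_population(p, proto, 400,
                              noise_spec(sigma_mult = s, ic_cv = 0, seed = 5),
                              record_times = 8)[[1]]
    abs(mean(sn$E_samples) - ref)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.05 * ref + 0.01)
})

test_that("halving the Euler-Maruyama step leaves the deterministic limit stable", {
  p <- wt_params()
  proto <- protocol_constant(15, 6)
  nf <- noise_spec(sigma_mult = 0, ic_cv = 0)
  a <- simulate_population(p, proto, 2, nf, record_times = 6, dt = 0.01)[[1]]
  b <- simulate_population(p, proto, 2, nf, record_times = 6, dt = 0.005)[[1]]
  expect_lt(max(abs(a$states - b$states) / (abs(b$states) + 1e-8)), 0.02)
})

test_that("transition fraction rises monotonically with continuous dose", {
  p <- wt_params()
  thr <- wt_threshold()
  fr <- vapply(c(4, 12.5, 18), function(dose) {
    sn <- simulate_population(p, protocol_constant(dose, 40), 500,
                              noise_spec(seed = 21), record_times = 40)[[1]]
    fraction_transitioned(sn, thr)
  }, numeric(1))
  expect_true(all(diff(fr) >= -0.02))
  expect_lt(fr[1], 0.1)
  expect_gt(fr[3], 0.9)
})

test_that("modality recovers ground truth on lognormal mixtures", {
  set.seed(42)
  one <- rlnorm(2000, meanlog = 0, sdlog = 0.3)
  m1 <- modality(one)
  expect_identical(m1$n_modes, 1L)

  two <- c(rlnorm(1000, meanlog = 0, sdlog = 0.3),
           rlnorm(1000, meanlog = log(10), sdlog = 0.3))
  m2 <- modality(two)
  expect_identical(m2$n_modes, 2L)
  expect_equal(m2$mode_weights, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(m2$mode_locations, c(1, 10), tolerance = 0.15)
  expect_lt(m2$bic_2, m2$bic_1 - 10)
  expect_equal(sum(m2$mode_weights), 1, tolerance = 1e-9)

  cst <- modality(rep(2.5, 100))
  expect_identical(cst$n_modes, 1L)
  expect_identical(cst$bimodality_coefficient, 0)

  expect_error(modality(one[1:10]), "at least 20")
})

test_that("pulse memory: degenerate pulse equals continuous by construction", {
  p <- wt_params()
  r <- pulse_memory_experiment(p, dose = 15, pulse_duration = 6,
                               followup_time = 6, n_cells = 30,
                               noise = noise_spec(seed = 2))
  expect_identical(r$fraction_pulse, r$fraction_continuous)
  expect_error(pulse_memory_experiment(p, 15, 10, 5), "exceed")
})

test_that("reversion without conditioning never leaves the epithelial state", {
  p <- wt_params()
  r <- reversion_experiment(p, pre_dose = 0, pre_duration = 4,
                            post_duration = 6, n_cells = 50,
                            noise = noise_spec(seed = 3),
                            record_times = c(0, 3, 6))
  expect_identical(r$half_time, 0)
  expect_true(all(r$fraction_high > 0.95))
})

test_that("disabling autocrine production accelerates wildtype reversion", {
  base <- wt_params()
  noauto <- emt_params(k_T = 1e-6)
  ns <- noise_spec(sigma_mult = 0, ic_cv = 0)
  rt <- function(p) {
    # deterministic single-cell reversion time against the wildtype threshold
    tr <- integrate_protocol(p, protocol_withdrawal(20, 30, 40),
                             output_grid = seq(30, 70, 0.25),
                             rel_tol = 1e-8)
    thr <- emt_threshold(wt_params())
    tr$times[which(tr$states[, "E"] > thr & tr$times > 30)[1]] - 30
  }
  expect_gt(rt(base), rt(noauto))
})
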