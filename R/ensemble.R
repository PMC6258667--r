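#' Noise specification for population ensembles
#'
#' Multiplicative state noise (Euler-Maruyama term
#' \code{sigma_mult * X * dW} per species) plus lognormal jitter of the
#' initial condition with coefficient of variation \code{ic_cv}. Both keep
#' states non-negative and produce the log-scale population spread seen in
#' single-cell E-cadherin distributions.
#'
#' @param sigma_mult multiplicative noise amplitude (per sqrt time), >= 0.
#' @param ic_cv coefficient of variation of the initial-condition jitter.
#' @param seed integer RNG seed; identical specs give identical ensembles.
#' @return a \code{noise_spec} object.
#' @export
noise_spec <- function(sigma_mult = 0.05, ic_cv = 0.1, seed = 1L) {
  if (sigma_mult < 0 || ic_cv < 0) stop("noise amplitudes must be >= 0")
  structure(list(sigma_mult = sigma_mult, ic_cv = ic_cv,
                 seed = as.integer(seed)), class = "noise_spec")
}

# Lognormal multiplicative jitter with unit mean and given CV.
.lognormal_jitter <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Stochastic simulation of a cell population
#'
#' Each cell is an independent realisation of the circuit driven by the
#' common dose protocol, integrated with the Euler-Maruyama scheme
#' (multiplicative noise per species, step \code{dt}). Initial conditions
#' are the epithelial attractor jittered lognormally per cell and species.
#' With \code{sigma_mult = 0} and \code{ic_cv = 0} every cell reproduces
#' the deterministic trajectory.
#'
#' @inheritParams integrate_protocol
#' @param n_cells number of cells (>= 1).
#' @param noise a [noise_spec()].
#' @param record_times times (within the protocol) at which population
#'   snapshots are taken.
#' @param dt Euler-Maruyama step.
#' @param init optional common initial state; defaults to the epithelial
#'   attractor at dose 0.
#' @return list of \code{population_snapshot} objects, one per record time;
#'   each has \code{time}, \code{E_samples}, \code{states} (n_cells x 4),
#'   \code{n_cells}, \code{protocol}.
#' @export
simulate_population <- function(params, protocol, n_cells = 1000,
                                noise = noise_spec(), record_times = NULL,
                                dt = 0.01, init = NULL) {
  validate_params(params)
  stopifnot(inherits(protocol, "dose_protocol"), inherits(noise, "noise_spec"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  dur <- protocol$total_duration
  if (is.null(record_times)) record_times <- dur
  if (any(record_times < 0 | record_times > dur + 1e-9))
    stop("record_times must lie within the protocol duration")
  record_times <- sort(record_times)

  set.seed(noise$seed)
  if (is.null(init)) init <- epithelial_state(params)
  X <- matrix(rep(.as_state(init), each = n_cells), n_cells, 4,
              dimnames = list(NULL, c("T", "M", "Z", "E")))
  X <- X * matrix(.lognormal_jitter(4L * n_cells, noise$ic_cv), n_cells, 4)

  n_steps <- ceiling(dur / dt - 1e-9)
  step_times <- (seq_len(n_steps) - 1) * dt
  doses <- dose_at(protocol, step_times)
  sqdt <- sqrt(dt)
  snap_step <- pmin(pmax(round(record_times / dt), 0L), n_steps)
  snapshots <- vector("list", length(record_times))
  take <- function(k) {
    hit <- which(snap_step == k)
    for (j in hit)
      snapshots[[j]] <<- structure(
        list(time = record_times[j], E_samples = X[, "E"], states = X,
             n_cells = n_cells, protocol = protocol),
        class = "population_snapshot")
  }
  take(0L)
  for (k in seq_len(n_steps)) {
    d <- .rhs_arrays(X[, 1], X[, 2], X[, 3], X[, 4], params, doses[k])
    drift <- cbind(d$T, d$M, d$Z, d$E) * dt
    X <- X + drift
    if (noise$sigma_mult > 0)
      X <- X + noise$sigma_mult * X * sqdt *
        matrix(stats::rnorm(4L * n_cells), n_cells, 4)
    X[X < 0] <- 0
    take(k)
  }
  snapshots
}

#' @export
print.population_snapshot <- function(x, ...) {
  cat(sprintf("<population_snapshot> t = %g, %d cells, median E = %.3g\n",
              x$time, x$n_cells, stats::median(x$E_samples)))
  invisible(x)
}

#' Modality of a single-cell E-cadherin sample
#'
#' Fits 1- and 2-component Gaussian mixtures to log-transformed samples
#' (\pkg{mclust}, unequal variances) and selects two modes only when the
#' 2-component BIC (in the smaller-is-better \eqn{-2\log L + k \log n}
#' convention) beats the 1-component BIC by more than \code{bic_margin}.
#' Also reports the sample bimodality coefficient
#' \eqn{(g_1^2 + 1) / (g_2 + 3 (n-1)^2 / ((n-2)(n-3)))} based on skewness
#' and excess kurtosis.
#'
#' @param samples numeric vector of E values (>= 20).
#' @param bic_margin evidence margin for selecting two modes.
#' @param pseudo pseudo-count added before log transform to guard zeros.
#' @return a \code{modality_report}: \code{n_modes}, \code{mode_locations}
#'   (on the E scale), \code{mode_weights}, \code{bic_1}, \code{bic_2},
#'   \code{bimodality_coefficient}.
#' @export
modality <- function(samples, bic_margin = 10, pseudo = 1e-6) {
  if (length(samples) < 20) stop("modality needs at least 20 samples")
  if (any(samples < 0)) stop("samples must be non-negative")
  x <- log(samples + pseudo)
  n <- length(x)

  bc <- if (stats::sd(x) < 1e-12) 0 else {
    g1 <- e1071::skewness(x, type = 2)
    g2 <- e1071::kurtosis(x, type = 2)
    (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  }

  if (stats::sd(x) < 1e-12) {
    return(structure(list(n_modes = 1L, mode_locations = exp(x[1]) - pseudo,
                          mode_weights = 1, bic_1 = -Inf, bic_2 = Inf,
                          bimodality_coefficient = bc),
                     class = "modality_report"))
  }

  # Mclust() resolves mclustBIC in the calling frame; alias it locally so
  # the package need not be attached.
  mclustBIC <- mclust::mclustBIC
  fit1 <- mclust::Mclust(x, G = 1, modelNames = "V", verbose = FALSE)
  fit2 <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  bic_of <- function(fit) {
    if (is.null(fit)) return(Inf)
    npar <- mclust::nMclustParams(fit$modelName, d = 1, G = fit$G)
    -2 * fit$loglik + npar * log(n)
  }
  bic_1 <- bic_of(fit1)
  bic_2 <- bic_of(fit2)
  two <- is.finite(bic_2) && bic_2 < bic_1 - bic_margin
  if (two) {
    mu <- as.numeric(fit2$parameters$mean)
    w <- as.numeric(fit2$parameters$pro)
    ord <- order(mu)
    structure(list(n_modes = 2L, mode_locations = exp(mu[ord]) - pseudo,
                   mode_weights = w[ord] / sum(w),
                   bic_1 = bic_1, bic_2 = bic_2,
                   bimodality_coefficient = bc),
              class = "modality_report")
  } else {
    structure(list(n_modes = 1L,
                   mode_locations = exp(as.numeric(fit1$parameters$mean)) - pseudo,
                   mode_weights = 1, bic_1 = bic_1, bic_2 = bic_2,
                   bimodality_coefficient = bc),
              class = "modality_report")
  }
}

#' @export
print.modality_report <- function(x, ...) {
  cat(sprintf("<modality_report> %d mode(s) at %s (weights %s), dBIC = %.1f\n",
              x$n_modes, paste(signif(x$mode_locations, 3), collapse = ", "),
              paste(signif(x$mode_weights, 3), collapse = ", "),
              x$bic_1 - x$bic_2))
  invisible(x)
}

#' Fraction of cells past the EMT threshold
#'
#' @param snapshot a \code{population_snapshot}.
#' @param threshold E-cadherin threshold; cells with E below it count as
#'   transitioned (mesenchymal-like).
#' @return scalar in \verb{[0, 1]}.
#' @export
fraction_transitioned <- function(snapshot, threshold) {
  stopifnot(inherits(snapshot, "population_snapshot"))
  mean(snapshot$E_samples < threshold)
}

#' Pulse-memory experiment
#'
#' Compares a transient pulse of TGF-beta against continuous treatment at
#' the same dose: both populations are scored at \code{followup_time} by
#' the fraction of cells with E-cadherin below the per-parameter-set
#' threshold. In the hysteretic circuit a supra-threshold pulse commits
#' cells to the mesenchymal state, so the two fractions nearly coincide;
#' without hysteresis cells relax back once the pulse ends.
#'
#' @inheritParams simulate_population
#' @param dose pulse / continuous dose (a.u.).
#' @param pulse_duration pulse length (<= followup_time).
#' @param followup_time scoring time.
#' @return list with \code{fraction_pulse}, \code{fraction_continuous},
#'   \code{threshold}.
#' @export
pulse_memory_experiment <- function(params, dose, pulse_duration,
                                    followup_time, n_cells = 500,
                                    noise = noise_spec(), dt = 0.01) {
  if (pulse_duration > followup_time)
    stop("pulse_duration must not exceed followup_time")
  thr <- emt_threshold(params)
  snap_p <- simulate_population(params,
    protocol_pulse(dose, pulse_duration, followup_time),
    n_cells, noise, record_times = followup_time, dt = dt)[[1]]
  snap_c <- simulate_population(params,
    protocol_constant(dose, followup_time),
    n_cells, noise, record_times = followup_time, dt = dt)[[1]]
  list(fraction_pulse = fraction_transitioned(snap_p, thr),
       fraction_continuous = fraction_transitioned(snap_c, thr),
       threshold = thr)
}

#' MET reversion experiment
#'
#' Drives the population to the mesenchymal state under \code{pre_dose},
#' withdraws exogenous TGF-beta, and records the recovery of E-cadherin.
#' The reversion half-time is the first recorded post-withdrawal time at
#' which at least half of the cells are E-high again.
#'
#' @inheritParams simulate_population
#' @param pre_dose conditioning dose.
#' @param pre_duration conditioning time.
#' @param post_duration time simulated after withdrawal.
#' @param record_times snapshot times measured from withdrawal (default: 40
#'   evenly spaced over \code{post_duration}).
#' @return list with \code{snapshots} (post-withdrawal), \code{times}
#'   (relative to withdrawal), \code{fraction_high} per time,
#'   \code{half_time} (NA if never reached), \code{threshold}.
#' @export
reversion_experiment <- function(params, pre_dose, pre_duration = 30,
                                 post_duration = 40, n_cells = 500,
                                 noise = noise_spec(), record_times = NULL,
                                 dt = 0.01) {
  thr <- emt_threshold(params)
  if (is.null(record_times))
    record_times <- seq(0, post_duration, length.out = 41)
  stopifnot(all(record_times >= 0 & record_times <= post_duration + 1e-9))
  proto <- protocol_withdrawal(pre_dose, pre_duration, post_duration)
  snaps <- simulate_population(params, proto, n_cells, noise,
                               record_times = pre_duration + record_times,
                               dt = dt)
  frac_high <- vapply(snaps, function(s) mean(s$E_samples >= thr), numeric(1))
  half_idx <- which(frac_high >= 0.5)[1]
  list(snapshots = snaps, times = record_times, fraction_high = frac_high,
       half_time = if (is.na(half_idx)) NA_real_ else record_times[half_idx],
       threshold = thr)
}
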