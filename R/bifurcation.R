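#' Quasi-static dose sweep of the steady-state E-cadherin response
#'
#' Continuation sweep: the steady state at one dose seeds the integration at
#' the next. The forward sweep starts from the dose-0 epithelial attractor
#' and increases dose; the backward sweep starts from the mesenchymal
#' attractor at the top dose and decreases dose. Inside a bistable window
#' the two branches disagree; this history dependence is the hysteresis the
#' sweep measures. Cold starts deliberately play no role.
#'
#' @param params an [emt_params()] object.
#' @param dose_grid increasing vector of doses (>= 2 points).
#' @param direction \code{"forward"} or \code{"backward"}.
#' @param t_max,convergence_tol passed to [steady_state()].
#' @return an \code{emt_branch}: list with \code{doses}, \code{E_values},
#'   \code{states} (matrix), \code{direction}, \code{converged} flags.
#' @export
sweep_branch <- function(params, dose_grid, direction = c("forward", "backward"),
                         t_max = 2000, convergence_tol = 1e-7) {
  direction <- match.arg(direction)
  validate_params(params)
  if (length(dose_grid) < 2 || any(diff(dose_grid) <= 0))
    stop("dose_grid must be increasing with at least 2 points")
  n <- length(dose_grid)
  order_idx <- if (direction == "forward") seq_len(n) else rev(seq_len(n))
  init <- if (direction == "forward") {
    epithelial_state(params)
  } else {
    top <- max(dose_grid)
    steady_state(params, top, init = c(T = top, M = 0.01, Z = 2, E = 0.05),
                 t_max = t_max, convergence_tol = convergence_tol)
  }
  states <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("T", "M", "Z", "E")))
  converged <- logical(n)
  cur <- .as_state(init)
  for (i in order_idx) {
    s <- steady_state(params, dose_grid[i], init = cur,
                      t_max = t_max, convergence_tol = convergence_tol)
    states[i, ] <- s
    converged[i] <- isTRUE(attr(s, "converged"))
    cur <- .as_state(s)
  }
  structure(list(doses = dose_grid, E_values = states[, "E"],
                 states = states, direction = direction,
                 converged = converged),
            class = "emt_branch")
}

#' @export
print.emt_branch <- function(x, ...) {
  cat("<emt_branch>", x$direction, "sweep,", length(x$doses), "doses in [",
      min(x$doses), ",", max(x$doses), "]\n")
  invisible(x)
}

# ---- reduced steady-state analysis -----------------------------------------
#
# Every steady state of the full system is a root of an explicit scalar
# residual in Z: at steady state M = b_M + k_M/(1+(Z/K_Z')^h_M) is explicit
# in Z, T = (dose + k_T/(1+(M/K_MT)^h_T))/d_T is explicit in M, and the ZEB
# balance closes the loop:
#   r(Z) = (d_Z + k_MZ M(Z)) Z - b_Z - k_Z T(Z)/(K_T + T(Z)).
# Counting sign changes of r on a log-spaced Z grid counts steady states
# exactly (E is slaved and does not feed back).

.count_steady_states <- function(params, dose, n_grid = 1200) {
  p <- params
  z_hi <- 1.05 * (p$b_Z + p$k_Z) / p$d_Z
  z_lo <- 0.5 * p$b_Z / (p$d_Z + p$k_MZ * (p$b_M + p$k_M))
  Z <- exp(seq(log(z_lo), log(z_hi), length.out = n_grid))
  M <- p$b_M + p$k_M / (1 + (Z / p$K_Z_prime)^p$h_M)
  T_ <- (dose + p$k_T / (1 + (M / p$K_MT)^p$h_T)) / p$d_T
  r <- (p$d_Z + p$k_MZ * M) * Z - p$b_Z - p$k_Z * T_ / (p$K_T + T_)
  sum(diff(sign(r)) != 0)
}

# Bisection refinement of a boundary of the multistable dose set.
.refine_edge <- function(params, d_mono, d_multi, resolution_tol) {
  while (abs(d_multi - d_mono) > resolution_tol) {
    mid <- (d_mono + d_multi) / 2
    if (.count_steady_states(params, mid) >= 3) d_multi <- mid else d_mono <- mid
  }
  (d_mono + d_multi) / 2
}

.reduced_window <- function(params, dose_range, resolution_tol, n_scan = 121) {
  doses <- seq(dose_range[1], dose_range[2], length.out = n_scan)
  counts <- vapply(doses, function(d) .count_steady_states(params, d), numeric(1))
  if (counts[n_scan] >= 3)
    stop("window not bracketed: system still bistable at the top of dose_range")
  multi <- which(counts >= 3)
  if (length(multi) == 0)
    return(list(T_low = NA_real_, T_high = NA_real_, extent = 0))
  lo_i <- multi[1]; hi_i <- multi[length(multi)]
  T_low <- if (lo_i == 1) doses[1] else
    .refine_edge(params, doses[lo_i - 1], doses[lo_i], resolution_tol)
  T_high <- .refine_edge(params, doses[hi_i + 1], doses[hi_i], resolution_tol)
  list(T_low = T_low, T_high = T_high, extent = T_high - T_low)
}

# ---- sweep-based window detection ------------------------------------------

# Steady state seeded from a branch state at the nearest evaluated dose.
.branch_point <- function(params, dose, seed_state, t_max = 2000) {
  steady_state(params, dose, init = seed_state, t_max = t_max)
}

#' Locate the bistable dose window
#'
#' The saddle-node bounds \code{T_low} and \code{T_high} of the dose range
#' over which the forward (epithelial-history) and backward
#' (mesenchymal-history) branches disagree in E-cadherin. With
#' \code{method = "sweep"} the bounds come from continuation sweeps plus
#' bisection on branch disagreement; with \code{method = "reduced"} they
#' come from exact root counting of the reduced scalar steady-state
#' equation (fast; used for large parameter scans). Monostable systems
#' return extent 0 with NaN bounds.
#'
#' @inheritParams sweep_branch
#' @param dose_range numeric length-2; must cover the suspected window.
#' @param resolution_tol bisection resolution for the bounds (dose units).
#' @param method \code{"sweep"} or \code{"reduced"}.
#' @param n_grid sweep grid size across \code{dose_range}.
#' @return a \code{bistable_window} list: \code{T_low}, \code{T_high},
#'   \code{extent}, \code{E_gap_at_mid}, \code{method}.
#' @export
bistable_window <- function(params, dose_range = c(0, 30),
                            resolution_tol = 0.02,
                            method = c("sweep", "reduced"), n_grid = 61) {
  method <- match.arg(method)
  validate_params(params)
  stopifnot(length(dose_range) == 2, dose_range[2] > dose_range[1],
            resolution_tol > 0)

  if (method == "reduced") {
    w <- .reduced_window(params, dose_range, resolution_tol)
    gap <- if (w$extent > 0) {
      mid <- (w$T_low + w$T_high) / 2
      ef <- .branch_point(params, mid, epithelial_state(params))[["E"]]
      eb <- .branch_point(params, mid,
              c(T = mid + 20, M = 0.01, Z = 2, E = 0.05))[["E"]]
      abs(ef - eb)
    } else 0
    return(structure(c(w, list(E_gap_at_mid = gap, method = method)),
                     class = "bistable_window"))
  }

  grid <- seq(dose_range[1], dose_range[2], length.out = n_grid)
  fwd <- sweep_branch(params, grid, "forward")
  bwd <- sweep_branch(params, grid, "backward")
  e_ref <- epithelial_state(params)[["E"]]
  tol_e <- 0.05 * e_ref
  disagree <- abs(fwd$E_values - bwd$E_values) > tol_e
  if (disagree[n_grid])
    stop("window not bracketed: branches still disagree at the top of dose_range")
  if (!any(disagree)) {
    # guard: bistability can hide above the forward branch's switch point
    top <- dose_range[2]
    alt <- steady_state(params, top,
                        init = c(T = top + 20, M = 0.01, Z = 2, E = 0.05))
    if (abs(alt[["E"]] - fwd$E_values[n_grid]) > tol_e)
      stop("window not bracketed: system still bistable at the top of dose_range")
    return(structure(list(T_low = NA_real_, T_high = NA_real_, extent = 0,
                          E_gap_at_mid = 0, method = method),
                     class = "bistable_window"))
  }
  lo_i <- which(disagree)[1]
  hi_i <- which(disagree)[length(which(disagree))]

  # lower edge: backward branch jumps up between grid[lo_i - 1] and grid[lo_i]
  T_low <- if (lo_i == 1) grid[1] else {
    a <- grid[lo_i - 1]; b <- grid[lo_i]
    seed_b <- .as_state(bwd$states[lo_i, ])
    while (b - a > resolution_tol) {
      mid <- (a + b) / 2
      eb <- .branch_point(params, mid, seed_b)
      ef <- .branch_point(params, mid, .as_state(fwd$states[max(1, lo_i - 1), ]))
      if (abs(ef[["E"]] - eb[["E"]]) > tol_e) {
        b <- mid; seed_b <- .as_state(eb)
      } else a <- mid
    }
    (a + b) / 2
  }
  # upper edge: forward branch falls off between grid[hi_i] and grid[hi_i + 1]
  T_high <- {
    a <- grid[hi_i]; b <- grid[hi_i + 1]
    seed_f <- .as_state(fwd$states[hi_i, ])
    while (b - a > resolution_tol) {
      mid <- (a + b) / 2
      ef <- .branch_point(params, mid, seed_f)
      eb <- .branch_point(params, mid, .as_state(bwd$states[hi_i + 1, ]))
      if (abs(ef[["E"]] - eb[["E"]]) > tol_e) {
        a <- mid; seed_f <- .as_state(ef)
      } else b <- mid
    }
    (a + b) / 2
  }
  mid <- (T_low + T_high) / 2
  i_near <- which.min(abs(grid - mid))
  gap <- abs(.branch_point(params, mid, .as_state(fwd$states[i_near, ]))[["E"]] -
             .branch_point(params, mid, .as_state(bwd$states[i_near, ]))[["E"]])
  structure(list(T_low = T_low, T_high = T_high, extent = T_high - T_low,
                 E_gap_at_mid = gap, method = method),
            class = "bistable_window")
}

#' @export
print.bistable_window <- function(x, ...) {
  if (x$extent > 0)
    cat(sprintf("<bistable_window> [%.3f, %.3f] extent %.3f (E gap %.3f, %s)\n",
                x$T_low, x$T_high, x$extent, x$E_gap_at_mid, x$method))
  else cat("<bistable_window> monostable (extent 0,", x$method, ")\n")
  invisible(x)
}

#' Hysteresis extent
#'
#' The dose-width of the bistable window (\code{T_high - T_low}), the scalar
#' summary of hysteresis strength used as the sensitivity-analysis output.
#' Exactly 0 for monostable systems.
#'
#' @inheritParams bistable_window
#' @return non-negative scalar.
#' @export
hysteresis_extent <- function(params, dose_range = c(0, 30),
                              resolution_tol = 0.02,
                              method = c("sweep", "reduced")) {
  bistable_window(params, dose_range, resolution_tol, method)$extent
}

#' Classify a parameter set as hysteretic or not
#'
#' \code{"hysteretic"} iff the hysteresis extent strictly exceeds
#' \code{classification_threshold} (default twice the dose resolution).
#'
#' @inheritParams bistable_window
#' @param classification_threshold extent threshold (dose units).
#' @return \code{"hysteretic"} or \code{"non_hysteretic"}.
#' @export
classify_hysteresis <- function(params, dose_range = c(0, 30),
                                resolution_tol = 0.02,
                                classification_threshold = 2 * resolution_tol,
                                method = c("sweep", "reduced")) {
  ext <- hysteresis_extent(params, dose_range, resolution_tol, method)
  if (ext > classification_threshold) "hysteretic" else "non_hysteretic"
}
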