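#' Right-hand side of the single-cell circuit
#'
#' Time derivatives of the four species given the current state and the
#' exogenous TGF-beta dose:
#' \deqn{dT/dt = dose + k_T/(1+(M/K_{MT})^{h_T}) - d_T T}
#' \deqn{dM/dt = b_M + k_M/(1+(Z/K_Z')^{h_M}) - d_M M}
#' \deqn{dZ/dt = b_Z + k_Z T/(K_T+T) - k_{MZ} M Z - d_Z Z}
#' \deqn{dE/dt = b_E + k_E/(1+(Z/K_Z'')^{h_E}) - d_E E}
#' Induction is Michaelis-Menten, promoter repression is Hill, and
#' miR-200-mediated ZEB removal is mass action. The system is autonomous for
#' fixed dose.
#'
#' @param state named numeric vector \code{c(T=, M=, Z=, E=)}, all
#'   non-negative.
#' @param params an [emt_params()] object.
#' @param dose exogenous TGF-beta dose (scalar, >= 0).
#' @return named numeric vector of rates \code{c(T=, M=, Z=, E=)}.
#' @export
emt_derivatives <- function(state, params, dose = 0) {
  validate_params(params)
  if (length(state) != 4) stop("state must have components T, M, Z, E")
  if (any(state < 0)) stop("state components must be non-negative")
  if (!is.numeric(dose) || length(dose) != 1 || dose < 0)
    stop("dose must be a non-negative scalar")
  d <- .rhs_arrays(state[[1]], state[[2]], state[[3]], state[[4]], params, dose)
  c(T = d$T, M = d$M, Z = d$Z, E = d$E)
}

# Vectorised RHS shared by the single-cell integrator, the population
# ensemble and the lattice simulation; T, M, Z, E may be scalars, vectors
# or matrices of a common shape; dose likewise (recycled).
.rhs_arrays <- function(T_, M, Z, E, p, dose) {
  list(
    T = dose + p$k_T / (1 + (M / p$K_MT)^p$h_T) - p$d_T * T_,
    M = p$b_M + p$k_M / (1 + (Z / p$K_Z_prime)^p$h_M) - p$d_M * M,
    Z = p$b_Z + p$k_Z * T_ / (p$K_T + T_) - p$k_MZ * M * Z - p$d_Z * Z,
    E = p$b_E + p$k_E / (1 + (Z / p$K_Z_dblprime)^p$h_E) - p$d_E * E
  )
}

.desolve_rhs <- function(t, y, parms) {
  d <- .rhs_arrays(y[1], y[2], y[3], y[4], parms$p, parms$dose)
  list(c(d$T, d$M, d$Z, d$E))
}

.as_state <- function(x) {
  stopifnot(length(x) == 4)
  stats::setNames(as.numeric(x), c("T", "M", "Z", "E"))
}

# One constant-dose integration leg with non-negativity clamping.
.integrate_leg <- function(p, dose, init, times, rtol, atol) {
  if (length(times) == 1) return(matrix(init, nrow = 1,
    dimnames = list(NULL, c("T", "M", "Z", "E"))))
  out <- deSolve::lsoda(y = .as_state(init), times = times,
                        func = .desolve_rhs, parms = list(p = p, dose = dose),
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure near t = ", max(out[, 1]))
  st <- out[, -1, drop = FALSE]
  if (any(st < -atol))
    stop("negative excursion beyond tolerance near t = ",
         out[which(apply(st, 1, min) < -atol)[1], 1])
  st[st < 0] <- 0
  st
}

#' Integrate the circuit under a dose protocol
#'
#' Integrates the stiff ODE system with an adaptive implicit-capable solver
#' (\code{deSolve::lsoda}), restarting at protocol segment boundaries so
#' dose discontinuities are exact. States are clamped to zero when small
#' negative excursions (below \code{abs_tol}) occur.
#'
#' @param params an [emt_params()] object.
#' @param protocol a [dose_protocol()].
#' @param init initial state \code{c(T=, M=, Z=, E=)}; defaults to the
#'   epithelial attractor at dose 0.
#' @param output_grid increasing vector of output times within the protocol
#'   duration; defaults to 201 evenly spaced points.
#' @param rel_tol,abs_tol integrator tolerances.
#' @return an \code{emt_trajectory}: list with \code{times} (vector),
#'   \code{states} (matrix with columns T, M, Z, E), \code{protocol},
#'   \code{params}.
#' @export
integrate_protocol <- function(params, protocol, init = NULL,
                               output_grid = NULL,
                               rel_tol = 1e-8, abs_tol = 1e-10) {
  validate_params(params)
  stopifnot(inherits(protocol, "dose_protocol"))
  if (is.null(init)) init <- epithelial_state(params)
  init <- .as_state(init)
  if (any(init < 0)) stop("initial state must be non-negative")
  dur <- protocol$total_duration
  if (is.null(output_grid))
    output_grid <- seq(0, dur, length.out = if (dur > 0) 201 else 1)
  if (any(diff(output_grid) <= 0)) stop("output_grid must be increasing")
  if (min(output_grid) < 0 || max(output_grid) > dur + 1e-9)
    stop("output_grid must lie within the protocol duration")

  if (dur == 0 || length(output_grid) == 1) {
    return(structure(list(times = output_grid[1],
                          states = matrix(init, nrow = 1,
                            dimnames = list(NULL, c("T", "M", "Z", "E"))),
                          protocol = protocol, params = params),
                     class = "emt_trajectory"))
  }

  seg <- protocol$segments
  states <- matrix(NA_real_, length(output_grid), 4,
                   dimnames = list(NULL, c("T", "M", "Z", "E")))
  cur <- init
  cur_t <- 0
  if (abs(output_grid[1]) < 1e-12) states[1, ] <- init
  for (i in seq_len(nrow(seg))) {
    t0 <- max(cur_t, seg$start[i]); t1 <- seg$end[i]
    if (t1 <= t0) next
    inside <- which(output_grid > t0 + 1e-12 & output_grid <= t1 + 1e-12)
    leg_times <- unique(c(t0, output_grid[inside], t1))
    st <- .integrate_leg(params, seg$dose[i], cur, leg_times, rel_tol, abs_tol)
    if (length(inside) > 0)
      states[inside, ] <- st[match(output_grid[inside], leg_times), ]
    cur <- st[nrow(st), ]
    cur_t <- t1
  }
  structure(list(times = output_grid, states = states,
                 protocol = protocol, params = params),
            class = "emt_trajectory")
}

#' @export
print.emt_trajectory <- function(x, ...) {
  cat("<emt_trajectory>", length(x$times), "time points over [",
      min(x$times), ",", max(x$times), "]\n")
  invisible(x)
}

#' @export
as.data.frame.emt_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states)
}

#' Export a trajectory as CSV plus a JSON sidecar
#'
#' Writes \code{time,T,M,Z,E} rows to \code{path} and the parameter set plus
#' protocol segments to \code{<path>.json}.
#'
#' @param trajectory an \code{emt_trajectory}.
#' @param path CSV output path.
#' @return invisibly, the CSV path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "emt_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  sidecar <- list(params = unclass(trajectory$params),
                  protocol = trajectory$protocol$segments)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Steady state at constant dose
#'
#' Integrates from \code{init} until the largest relative rate
#' \eqn{\max_i |f_i| / (|x_i| + abs\_tol)} falls below
#' \code{convergence_tol}, or \code{t_max} is reached. Which attractor is
#' reached depends on \code{init}; inside the bistable window this
#' dependence is the circuit's memory.
#'
#' @inheritParams integrate_protocol
#' @param dose constant exogenous dose.
#' @param t_max maximum integration time.
#' @param convergence_tol relative-rate convergence criterion.
#' @return named state vector with attribute \code{converged} (logical).
#' @export
steady_state <- function(params, dose, init = NULL, t_max = 1e4,
                         convergence_tol = 1e-7,
                         rel_tol = 1e-8, abs_tol = 1e-10) {
  validate_params(params)
  if (is.null(init)) init <- c(T = 0, M = 1, Z = 0, E = 1)
  cur <- .as_state(init)
  if (any(cur < 0)) stop("initial state must be non-negative")
  t_done <- 0
  chunk <- 50
  repeat {
    d <- .rhs_arrays(cur[1], cur[2], cur[3], cur[4], params, dose)
    rate <- max(abs(unlist(d)) / (abs(cur) + abs_tol))
    if (rate < convergence_tol) {
      attr(cur, "converged") <- TRUE
      return(cur)
    }
    if (t_done >= t_max) {
      attr(cur, "converged") <- FALSE
      return(cur)
    }
    st <- .integrate_leg(params, dose, cur,
                         c(0, min(chunk, t_max - t_done)), rel_tol, abs_tol)
    cur <- .as_state(st[nrow(st), ])
    t_done <- t_done + chunk
    chunk <- min(chunk * 2, 2000)
  }
}

#' Reference attractors and the E-cadherin classification threshold
#'
#' \code{epithelial_state} is the steady state reached from a naive
#' high-miR-200 state at dose 0 (E-cadherin high). \code{mesenchymal_state}
#' is the steady state at a saturating reference dose (default 25 a.u.,
#' above the wildtype bistable window) reached from a ZEB-high state.
#' \code{emt_threshold} is the geometric midpoint of the two attractors'
#' E-cadherin levels, i.e. the midpoint of \code{log(E)}; it is computed per
#' parameter set so that classification tracks any recalibration.
#'
#' @inheritParams steady_state
#' @param dose_ref reference saturating dose for the mesenchymal attractor.
#' @return a state vector (or a scalar threshold for \code{emt_threshold}).
#' @export
epithelial_state <- function(params, dose = 0) {
  steady_state(params, dose, init = c(T = 0, M = 1, Z = 0, E = 1))
}

#' @rdname epithelial_state
#' @export
mesenchymal_state <- function(params, dose_ref = 25) {
  steady_state(params, dose_ref,
               init = c(T = dose_ref, M = 0.01, Z = 2, E = 0.05))
}

#' @rdname epithelial_state
#' @export
emt_threshold <- function(params, dose_ref = 25) {
  e_hi <- epithelial_state(params)[["E"]]
  e_lo <- mesenchymal_state(params, dose_ref)[["E"]]
  exp((log(e_hi) + log(e_lo)) / 2)
}
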