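#' Configuration of the periodic reaction-diffusion lattice
#'
#' Each lattice site hosts one cell running the full circuit; TGF-beta is a
#' shared field that diffuses between sites (5-point Laplacian, periodic in
#' both directions) while miR-200, ZEB and E-cadherin remain cell-intrinsic.
#' Randomly chosen source sites receive an extra exogenous dose while
#' \code{time < source_duration}, mimicking local treatment of scattered
#' cells; the paracrine spreading beyond the sources is carried entirely by
#' diffusion of secreted TGF-beta.
#'
#' @param n_rows,n_cols lattice dimensions (>= 3 each).
#' @param D TGF-beta diffusion coefficient (lattice units^2 / time).
#' @param dx lattice spacing (default 1).
#' @param dt time step; must satisfy the explicit-scheme stability bound
#'   \code{dt <= dx^2 / (4 D)}.
#' @param source_fraction fraction of sites treated as sources (ignored if
#'   \code{source_index} is given).
#' @param source_index optional integer vector of source sites
#'   (column-major indices).
#' @param source_dose exogenous injection rate at source sites (a.u./time).
#' @param source_duration time during which sources are active.
#' @param seed RNG seed for source placement.
#' @return a \code{lattice_config} object.
#' @export
lattice_config <- function(n_rows = 64, n_cols = 64, D = 3, dx = 1,
                           dt = 0.02, source_fraction = 0.02,
                           source_index = NULL, source_dose = 600,
                           source_duration = 40, seed = 1L) {
  if (n_rows < 3 || n_cols < 3) stop("lattice must be at least 3 x 3")
  if (D < 0 || dx <= 0 || dt <= 0) stop("D, dx, dt must be valid")
  if (D > 0 && dt > dx^2 / (4 * D) + 1e-12)
    stop(sprintf("dt = %g violates the diffusion stability bound dx^2/(4D) = %g",
                 dt, dx^2 / (4 * D)))
  if (is.null(source_index) &&
      (source_fraction < 0 || source_fraction > 1))
    stop("source_fraction must lie in [0, 1]")
  structure(list(n_rows = n_rows, n_cols = n_cols, D = D, dx = dx, dt = dt,
                 source_fraction = source_fraction,
                 source_index = source_index, source_dose = source_dose,
                 source_duration = source_duration, seed = as.integer(seed)),
            class = "lattice_config")
}

# Periodic 5-point Laplacian via torus shifts.
.laplacian5 <- function(X, dx) {
  up <- rbind(X[-1, , drop = FALSE], X[1, , drop = FALSE])
  down <- rbind(X[nrow(X), , drop = FALSE], X[-nrow(X), , drop = FALSE])
  left <- cbind(X[, -1, drop = FALSE], X[, 1, drop = FALSE])
  right <- cbind(X[, ncol(X), drop = FALSE], X[, -ncol(X), drop = FALSE])
  (up + down + left + right - 4 * X) / dx^2
}

#' Initialise a lattice field
#'
#' Every site starts at the dose-0 epithelial attractor (computed once);
#' source sites are drawn uniformly at random using the config seed unless
#' given explicitly.
#'
#' @param config a [lattice_config()].
#' @param params an [emt_params()] object.
#' @return a \code{spatial_field}: matrices \code{T}, \code{M}, \code{Z},
#'   \code{E}, logical matrix \code{sources}, \code{time}, \code{config},
#'   \code{params}.
#' @export
init_field <- function(config, params) {
  stopifnot(inherits(config, "lattice_config"))
  validate_params(params)
  nr <- config$n_rows; nc <- config$n_cols
  epi <- epithelial_state(params)
  mk <- function(v) matrix(v, nr, nc)
  sources <- matrix(FALSE, nr, nc)
  if (!is.null(config$source_index)) {
    sources[config$source_index] <- TRUE
  } else if (config$source_fraction > 0) {
    set.seed(config$seed)
    k <- round(config$source_fraction * nr * nc)
    sources[sample.int(nr * nc, k)] <- TRUE
  }
  structure(list(T = mk(epi[["T"]]), M = mk(epi[["M"]]),
                 Z = mk(epi[["Z"]]), E = mk(epi[["E"]]),
                 sources = sources, time = 0,
                 config = config, params = params),
            class = "spatial_field")
}

#' @export
print.spatial_field <- function(x, ...) {
  cat(sprintf("<spatial_field> %d x %d, t = %g, %d sources, mean E = %.3g\n",
              x$config$n_rows, x$config$n_cols, x$time, sum(x$sources),
              mean(x$E)))
  invisible(x)
}

#' Advance the lattice by one time step
#'
#' Operator splitting: (1) local reaction, every site advances the circuit
#' ODEs by \code{dt} with its local TGF-beta, sources additionally
#' receiving \code{source_dose} while active; (2) diffusion, an explicit
#' 5-point-Laplacian update of the TGF-beta field with periodic wrap. The
#' intracellular species do not diffuse.
#'
#' @param field a \code{spatial_field}.
#' @param exogenous optional matrix (or scalar) of extra exogenous dose
#'   applied uniformly this step, on top of any active sources.
#' @return the advanced \code{spatial_field}.
#' @export
field_step <- function(field, exogenous = 0) {
  stopifnot(inherits(field, "spatial_field"))
  cfg <- field$config
  p <- field$params
  dt <- cfg$dt
  dose <- exogenous + if (field$time < cfg$source_duration)
    cfg$source_dose * field$sources else 0
  d <- .rhs_arrays(field$T, field$M, field$Z, field$E, p, dose)
  field$T <- field$T + dt * d$T
  field$M <- pmax(field$M + dt * d$M, 0)
  field$Z <- pmax(field$Z + dt * d$Z, 0)
  field$E <- pmax(field$E + dt * d$E, 0)
  if (cfg$D > 0)
    field$T <- field$T + dt * cfg$D * .laplacian5(field$T, cfg$dx)
  field$T <- pmax(field$T, 0)
  field$time <- field$time + dt
  field
}

#' Run a lattice simulation
#'
#' @param field an initialised \code{spatial_field}.
#' @param t_end end time.
#' @param record_times snapshot times (default: initial and final state).
#' @param exogenous optional uniform exogenous dose applied at every step.
#' @return list of \code{spatial_field} snapshots at \code{record_times}.
#' @export
run_field <- function(field, t_end, record_times = NULL, exogenous = 0) {
  stopifnot(inherits(field, "spatial_field"))
  if (is.null(record_times)) record_times <- c(field$time, t_end)
  record_times <- sort(record_times)
  stopifnot(all(record_times >= field$time - 1e-9),
            all(record_times <= t_end + 1e-9))
  snaps <- vector("list", length(record_times))
  for (j in seq_along(record_times)) {
    while (field$time < record_times[j] - 1e-9)
      field <- field_step(field, exogenous)
    snaps[[j]] <- field
  }
  snaps
}

#' Fraction of mesenchymal (E-low) lattice sites
#'
#' @param field a \code{spatial_field}.
#' @param threshold E-cadherin threshold; defaults to [emt_threshold()] of
#'   the field's parameter set.
#' @return scalar in \verb{[0, 1]}.
#' @export
mesenchymal_fraction <- function(field, threshold = NULL) {
  stopifnot(inherits(field, "spatial_field"))
  if (is.null(threshold)) threshold <- emt_threshold(field$params)
  mean(field$E < threshold)
}

#' Largest connected patch of mesenchymal sites
#'
#' Connected components of E-low sites under 4-neighbour adjacency with
#' periodic wrap.
#'
#' @inheritParams mesenchymal_fraction
#' @return size (number of sites) of the largest component; 0 if none.
#' @export
largest_patch <- function(field, threshold = NULL) {
  stopifnot(inherits(field, "spatial_field"))
  if (is.null(threshold)) threshold <- emt_threshold(field$params)
  mes <- field$E < threshold
  if (!any(mes)) return(0L)
  nr <- nrow(mes); nc <- ncol(mes)
  idx <- which(mes)
  pos <- match(seq_len(nr * nc), idx)  # site -> vertex id or NA
  edges <- integer(0)
  rr <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  nbr <- function(r, c) (c - 1) * nr + r
  for (shift in list(c(1, 0), c(0, 1))) {
    r2 <- (rr - 1 + shift[1]) %% nr + 1
    c2 <- (cc - 1 + shift[2]) %% nc + 1
    j <- pos[nbr(r2, c2)]
    ok <- !is.na(j)
    edges <- c(edges, rbind(seq_along(idx)[ok], j[ok]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  max(igraph::components(g)$csize)
}

#' Spatially resolved MET reversion
#'
#' Drives the whole lattice to the mesenchymal state under a uniform
#' exogenous dose, then removes it; autocrine production and diffusion
#' alone govern the reversion. Source sites play no role here.
#'
#' @param params an [emt_params()] object.
#' @param config a [lattice_config()]; its sources are disabled.
#' @param pre_dose uniform conditioning dose.
#' @param pre_duration,post_duration conditioning time and time simulated
#'   after withdrawal.
#' @param record_times times (from withdrawal) of the reported fractions
#'   (default: 41 evenly spaced over \code{post_duration}).
#' @return list with \code{times} (from withdrawal), \code{fractions}
#'   (mesenchymal fraction per time), \code{snapshots} at first and last
#'   record time, \code{threshold}.
#' @export
reversion_field_experiment <- function(params, config, pre_dose,
                                       pre_duration = 30, post_duration = 40,
                                       record_times = NULL) {
  cfg <- config
  cfg$source_fraction <- 0
  cfg$source_index <- NULL
  field <- init_field(cfg, params)
  thr <- emt_threshold(params)
  if (is.null(record_times))
    record_times <- seq(0, post_duration, length.out = 41)
  # conditioning
  while (field$time < pre_duration - 1e-9)
    field <- field_step(field, exogenous = pre_dose)
  # withdrawal
  fractions <- numeric(length(record_times))
  snaps <- list()
  for (j in seq_along(record_times)) {
    while (field$time < pre_duration + record_times[j] - 1e-9)
      field <- field_step(field, exogenous = 0)
    fractions[j] <- mesenchymal_fraction(field, thr)
    if (j == 1 || j == length(record_times)) snaps[[length(snaps) + 1]] <- field
  }
  list(times = record_times, fractions = fractions,
       snapshots = snaps, threshold = thr)
}

#' Export lattice snapshots as CSV
#'
#' One file per snapshot (\code{row, col, T, M, Z, E}) plus a summary CSV
#' (\code{time, mesenchymal_fraction}).
#'
#' @param snapshots list of \code{spatial_field} objects.
#' @param prefix output path prefix.
#' @return invisibly, the summary path.
#' @export
write_field_snapshots <- function(snapshots, prefix) {
  thr <- emt_threshold(snapshots[[1]]$params)
  summ <- data.frame(time = numeric(0), mesenchymal_fraction = numeric(0))
  for (s in snapshots) {
    nr <- s$config$n_rows; nc <- s$config$n_cols
    df <- data.frame(row = rep(seq_len(nr), nc),
                     col = rep(seq_len(nc), each = nr),
                     T = as.vector(s$T), M = as.vector(s$M),
                     Z = as.vector(s$Z), E = as.vector(s$E))
    utils::write.csv(df, sprintf("%s_t%g.csv", prefix, s$time),
                     row.names = FALSE)
    summ <- rbind(summ, data.frame(time = s$time,
                                   mesenchymal_fraction =
                                     mesenchymal_fraction(s, thr)))
  }
  path <- paste0(prefix, "_summary.csv")
  utils::write.csv(summ, path, row.names = FALSE)
  invisible(path)
}
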