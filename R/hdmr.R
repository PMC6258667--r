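#' Uniform random design on a scaled hypercube
#'
#' I.i.d. uniform (maximum entropy on a box) samples of the selected model
#' parameters, reproducible from the seed. Optionally log-uniform.
#'
#' @param param_names character vector of parameter names (fields of
#'   [emt_params()]); default the four feedback-loop constants.
#' @param bounds named list of \code{c(low, high)} per parameter, or a
#'   2-row matrix with parameter columns. Defaults to a factor-of-10 box
#'   around the wildtype values: \code{c(v/10, v*10)}.
#' @param n_samples number of rows.
#' @param seed integer RNG seed.
#' @param log_uniform sample uniformly on the log scale instead.
#' @return a \code{hypercube_design}: list with \code{param_names},
#'   \code{bounds}, \code{n_samples}, \code{seed}, \code{X} (values) and
#'   \code{U} (the same rescaled to the unit cube).
#' @export
sample_hypercube <- function(param_names = c("k_Z", "K_Z_prime", "k_MZ",
                                             "K_Z_dblprime"),
                             bounds = NULL, n_samples = 5000, seed = 1L,
                             log_uniform = FALSE) {
  stopifnot(n_samples >= 1)
  wt <- .wildtype_values()
  unknown <- setdiff(param_names, names(wt))
  if (length(unknown) > 0)
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  if (is.null(bounds))
    bounds <- lapply(stats::setNames(param_names, param_names), function(nm)
      wt[[nm]] * c(0.1, 10))
  if (is.matrix(bounds))
    bounds <- lapply(stats::setNames(seq_along(param_names), param_names),
                     function(j) bounds[, j])
  for (nm in param_names) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || b[1] <= 0 || b[2] <= b[1])
      stop("bounds for ", nm, " must be c(low, high) with 0 < low < high")
  }
  set.seed(as.integer(seed))
  d <- length(param_names)
  U <- matrix(stats::runif(n_samples * d), n_samples, d,
              dimnames = list(NULL, param_names))
  X <- U
  for (j in seq_len(d)) {
    b <- bounds[[param_names[j]]]
    X[, j] <- if (log_uniform) exp(log(b[1]) + U[, j] * (log(b[2]) - log(b[1])))
              else b[1] + U[, j] * (b[2] - b[1])
  }
  structure(list(param_names = param_names, bounds = bounds,
                 n_samples = n_samples, seed = as.integer(seed),
                 log_uniform = log_uniform, X = X, U = U),
            class = "hypercube_design")
}

#' @export
print.hypercube_design <- function(x, ...) {
  cat("<hypercube_design>", x$n_samples, "samples of",
      paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Hysteresis extent across a hypercube design
#'
#' For each design row, the named parameters overwrite \code{base_params}
#' and the hysteresis extent is computed from the reduced steady-state
#' analysis. Parameter sets whose bistable window is not bracketed by
#' \code{dose_range} are recorded as \code{NA} and excluded downstream; the
#' count is reported in the \code{n_missing} attribute.
#'
#' @param design a [sample_hypercube()] design.
#' @param base_params parameters providing all non-varied fields.
#' @param dose_range dose range scanned per sample.
#' @param max_missing_frac error if more than this fraction of samples is
#'   unbracketed (bounds likely pathological).
#' @return numeric vector of extents (NA = unbracketed window) with
#'   attribute \code{n_missing}.
#' @export
evaluate_extent_map <- function(design, base_params = default_parameters(),
                                dose_range = c(0, 60),
                                max_missing_frac = 0.2) {
  stopifnot(inherits(design, "hypercube_design"))
  validate_params(base_params)
  n <- design$n_samples
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- modifyList(unclass(base_params),
                    as.list(design$X[i, , drop = TRUE]))
    out[i] <- tryCatch(
      .reduced_window(p, dose_range, resolution_tol = 0.02)$extent,
      error = function(e) NA_real_)
  }
  n_missing <- sum(is.na(out))
  if (n_missing > max_missing_frac * n)
    stop(sprintf("%d of %d samples have unbracketed windows; bounds likely pathological",
                 n_missing, n))
  attr(out, "n_missing") <- n_missing
  out
}

# Orthonormal shifted-Legendre polynomials on [0, 1], degrees 1..k, by the
# three-term recurrence on P_n(2u - 1); columns have zero mean and unit
# variance under the uniform measure.
.legendre_basis <- function(u, k) {
  stopifnot(all(u >= -1e-9 & u <= 1 + 1e-9))
  x <- 2 * u - 1
  P <- matrix(0, length(u), k + 1)
  P[, 1] <- 1
  if (k >= 1) P[, 2] <- x
  if (k >= 2) for (n in 1:(k - 1))
    P[, n + 2] <- ((2 * n + 1) * x * P[, n + 1] - n * P[, n]) / (n + 1)
  B <- P[, -1, drop = FALSE]
  sweep(B, 2, sqrt(2 * seq_len(k) + 1), "*")
}

#' Fit an RS-HDMR expansion to random input-output data
#'
#' Random-sampling HDMR: inputs are rescaled to the unit cube, first-order
#' component functions are expanded in orthonormal shifted-Legendre
#' polynomials (degree \code{degree_first}), second-order components in
#' tensor products (degree \code{degree_second} per factor), and all
#' coefficients are estimated jointly by least squares. Because the basis
#' is orthonormal under the sampling measure, the variance of each
#' component is the sum of its squared coefficients; sensitivity indices
#' \eqn{S_i} and \eqn{S_{ij}} are these variances normalised by the
#' model-consistent total (component variances plus residual mean square),
#' so they are non-negative and sum to one with the residual fraction
#' exactly.
#'
#' @param design a [sample_hypercube()] design.
#' @param outputs numeric vector, one output per design row; NAs (e.g.
#'   unbracketed windows) are dropped pairwise.
#' @param max_order 1 or 2.
#' @param degree_first,degree_second polynomial degrees.
#' @return an \code{hdmr_result}: \code{f0}, \code{S_i} (named),
#'   \code{S_ij} (named, \code{"a:b"}), \code{residual_variance_fraction},
#'   coefficient tables, \code{n_used}, \code{n_missing}.
#' @export
fit_hdmr <- function(design, outputs, max_order = 2,
                     degree_first = 5, degree_second = 3) {
  stopifnot(inherits(design, "hypercube_design"),
            length(outputs) == design$n_samples,
            max_order %in% 1:2, degree_first >= 1, degree_second >= 1)
  keep <- !is.na(outputs)
  n_missing <- sum(!keep)
  y <- outputs[keep]
  U <- design$U[keep, , drop = FALSE]
  d <- ncol(U)
  nms <- design$param_names
  pairs <- if (max_order >= 2 && d >= 2) utils::combn(d, 2) else
    matrix(integer(0), 2, 0)
  n_coef <- d * degree_first + ncol(pairs) * degree_second^2
  if (length(y) < 10 * n_coef)
    stop("need at least ", 10 * n_coef,
         " usable samples for this basis; increase n_samples or lower degrees")

  first_bases <- lapply(seq_len(d), function(j)
    .legendre_basis(U[, j], max(degree_first, degree_second)))
  blocks <- list()
  labels <- character(0)
  for (j in seq_len(d)) {
    blocks[[length(blocks) + 1]] <- first_bases[[j]][, 1:degree_first, drop = FALSE]
    labels <- c(labels, paste0(nms[j], ".", 1:degree_first))
  }
  if (ncol(pairs) > 0) for (q in seq_len(ncol(pairs))) {
    a <- pairs[1, q]; b <- pairs[2, q]
    Ba <- first_bases[[a]][, 1:degree_second, drop = FALSE]
    Bb <- first_bases[[b]][, 1:degree_second, drop = FALSE]
    tp <- matrix(0, length(y), degree_second^2)
    for (r in 1:degree_second) for (s in 1:degree_second)
      tp[, (r - 1) * degree_second + s] <- Ba[, r] * Bb[, s]
    blocks[[length(blocks) + 1]] <- tp
    labels <- c(labels, paste0(nms[a], ":", nms[b], ".", 1:degree_second^2))
  }
  Xmat <- cbind(`(f0)` = 1, do.call(cbind, blocks))
  colnames(Xmat) <- c("(f0)", labels)
  fit <- stats::lm.fit(Xmat, y)
  if (fit$rank < ncol(Xmat))
    stop("rank-deficient HDMR design; increase n_samples or lower degrees")
  cf <- fit$coefficients
  if (stats::var(y) < 1e-300) stop("outputs are constant; indices undefined")
  # component variances via the population-orthonormal basis (sum of squared
  # coefficients); the total is the model-consistent decomposition
  # sum(component variances) + residual mean square, so the indices are
  # non-negative and sum to one with the residual fraction exactly.
  var_comp_first <- stats::setNames(numeric(d), nms)
  coef_first <- list()
  for (j in seq_len(d)) {
    cj <- cf[paste0(nms[j], ".", 1:degree_first)]
    coef_first[[nms[j]]] <- cj
    var_comp_first[j] <- sum(cj^2)
  }
  var_comp_second <- numeric(0)
  coef_second <- list()
  if (ncol(pairs) > 0) for (q in seq_len(ncol(pairs))) {
    a <- pairs[1, q]; b <- pairs[2, q]
    key <- paste0(nms[a], ":", nms[b])
    cq <- cf[paste0(key, ".", 1:degree_second^2)]
    coef_second[[key]] <- matrix(cq, degree_second, degree_second, byrow = TRUE)
    var_comp_second[key] <- sum(cq^2)
  }
  var_resid <- sum(fit$residuals^2) / (length(y) - 1)
  var_total <- sum(var_comp_first) + sum(var_comp_second) + var_resid
  S_i <- var_comp_first / var_total
  S_ij <- var_comp_second / var_total
  structure(list(f0 = unname(cf[1]), S_i = S_i, S_ij = S_ij,
                 residual_variance_fraction = var_resid / var_total,
                 coef_first = coef_first, coef_second = coef_second,
                 degree_first = degree_first, degree_second = degree_second,
                 bounds = design$bounds, log_uniform = design$log_uniform,
                 n_used = length(y), n_missing = n_missing),
            class = "hdmr_result")
}

#' @export
print.hdmr_result <- function(x, ...) {
  cat("<hdmr_result> f0 =", signif(x$f0, 4), " n =", x$n_used,
      "(", x$n_missing, "missing )\n first-order indices:\n")
  print(round(sort(x$S_i, decreasing = TRUE), 4))
  if (length(x$S_ij)) {
    cat(" second-order indices:\n")
    print(round(sort(x$S_ij, decreasing = TRUE), 4))
  }
  cat(" residual variance fraction:",
      signif(x$residual_variance_fraction, 4), "\n")
  invisible(x)
}

#' Evaluate a fitted first-order component function
#'
#' @param result an \code{hdmr_result}.
#' @param param parameter name.
#' @param u points in \verb{[0, 1]} (the rescaled input).
#' @return component values \eqn{f_i(u)} (zero mean under the input
#'   measure).
#' @export
hdmr_component <- function(result, param, u) {
  stopifnot(inherits(result, "hdmr_result"))
  cj <- result$coef_first[[param]]
  if (is.null(cj)) stop("no first-order component for ", param)
  drop(.legendre_basis(u, result$degree_first) %*% cj)
}

#' Rank parameters and pairs by sensitivity index
#'
#' First- and second-order indices merged, sorted descending; ties broken
#' by lexicographic name order.
#'
#' @param result an \code{hdmr_result}.
#' @return data.frame with columns \code{term}, \code{order}, \code{index}.
#' @export
hdmr_ranking <- function(result) {
  stopifnot(inherits(result, "hdmr_result"))
  df <- rbind(
    data.frame(term = names(result$S_i), order = 1L,
               index = unname(result$S_i)),
    if (length(result$S_ij))
      data.frame(term = names(result$S_ij), order = 2L,
                 index = unname(result$S_ij)))
  df[order(-df$index, df$term), , drop = FALSE]
}
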