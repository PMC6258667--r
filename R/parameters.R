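#' Model parameters for the TGF-beta / miR-200 / ZEB circuit
#'
#' Constructs and validates the full set of rate and binding constants of
#' the single-cell circuit: TGF-beta (T) induces ZEB (Z), ZEB represses the
#' miR-200 promoter (constant \code{K_Z_prime}), miR-200 (M) removes ZEB
#' post-transcriptionally (coefficient \code{k_MZ}) and shuts down autocrine
#' TGF-beta production, and ZEB represses the E-cadherin promoter (constant
#' \code{K_Z_dblprime}). All concentrations and doses are in arbitrary
#' units (a.u.); time is in arbitrary time units with all decay rates near 1.
#'
#' @param ... named parameter values overriding the wildtype preset; keys
#'   must be parameter names listed below.
#'
#' @section Fields:
#' \describe{
#'   \item{k_Z, K_T}{maximal rate and half-saturation of TGF-beta induction
#'     of ZEB (Michaelis-Menten).}
#'   \item{K_Z_prime, h_M}{Michaelis constant and Hill coefficient of ZEB
#'     repression of the miR-200 promoter.}
#'   \item{k_MZ}{mass-action coefficient of miR-200-mediated ZEB removal.}
#'   \item{K_Z_dblprime, h_E}{Michaelis constant and Hill coefficient of ZEB
#'     repression of the E-cadherin promoter.}
#'   \item{k_M, b_M, d_M}{maximal, basal and decay rates of miR-200.}
#'   \item{k_E, b_E, d_E}{maximal, basal and decay rates of E-cadherin.}
#'   \item{b_Z, d_Z}{basal production and decay rate of ZEB.}
#'   \item{k_T, K_MT, h_T, d_T}{maximal autocrine TGF-beta production, the
#'     Michaelis constant and Hill coefficient of its repression by miR-200,
#'     and TGF-beta clearance.}
#' }
#'
#' @return an object of class \code{emt_params} (a validated named list).
#' @seealso [default_parameters()]
#' @export
emt_params <- function(...) {
  p <- modifyList(.wildtype_values(), list(...))
  extra <- setdiff(names(list(...)), names(.wildtype_values()))
  if (length(extra) > 0)
    stop("unknown parameter name(s): ", paste(extra, collapse = ", "))
  validate_params(p)
  structure(p, class = "emt_params")
}

.param_rate_names <- function() {
  c("k_Z", "K_Z_prime", "k_MZ", "K_Z_dblprime", "k_M", "b_M", "d_M",
    "k_E", "b_E", "d_E", "b_Z", "d_Z", "K_T", "k_T", "K_MT", "d_T")
}

.param_hill_names <- function() c("h_M", "h_E", "h_T")

.wildtype_values <- function() {
  # Calibrated so the bistable window of the quasi-static dose response is
  # approximately [2.5, 12] a.u.  The calibration procedure is in
  # tools/calibrate_preset.R; its output is frozen here.
  list(
    k_Z = 4.87, K_T = 22.8,
    K_Z_prime = 0.345, h_M = 2,
    k_MZ = 8.44,
    K_Z_dblprime = 0.3, h_E = 2,
    k_M = 1, b_M = 0.01, d_M = 1,
    k_E = 1, b_E = 0.01, d_E = 1,
    b_Z = 0.01, d_Z = 1,
    k_T = 18.4, K_MT = 0.161, h_T = 2, d_T = 1
  )
}

#' Validate a parameter set
#'
#' All rate, decay and Michaelis-Menten constants must be strictly positive
#' and all Hill coefficients at least 1.
#'
#' @param p named list of parameter values.
#' @return invisibly \code{TRUE}; stops on violation.
#' @export
validate_params <- function(p) {
  need <- c(.param_rate_names(), .param_hill_names())
  missing <- setdiff(need, names(p))
  if (length(missing) > 0)
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  for (nm in need) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter ", nm, " must be a single finite number")
  }
  bad <- Filter(function(nm) p[[nm]] <= 0, .param_rate_names())
  if (length(bad) > 0)
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  badh <- Filter(function(nm) p[[nm]] < 1, .param_hill_names())
  if (length(badh) > 0)
    stop("Hill coefficient(s) must be >= 1: ", paste(badh, collapse = ", "))
  invisible(TRUE)
}

#' Built-in parameter presets
#'
#' \code{"wildtype"} is the calibrated bistable circuit whose quasi-static
#' dose response has a bistable window of roughly 2.5 to 12 a.u.
#' \code{"mutant"} models weakened ZEB repression of the miR-200 promoter
#' (as caused by deleting a ZEB binding site): it differs from wildtype only
#' in \code{K_Z_prime}, raised by the smallest factor in the preset family
#' that abolishes bistability, so its dose response is monostable and
#' gradual. \code{"non_hysteretic_alt"} raises \code{K_Z_prime} further and
#' is a deliberately conservative monostable comparator.
#'
#' @param variant one of \code{"wildtype"}, \code{"mutant"},
#'   \code{"non_hysteretic_alt"}.
#' @return an \code{emt_params} object.
#' @examples
#' wt <- default_parameters("wildtype")
#' mut <- default_parameters("mutant")
#' mut$K_Z_prime / wt$K_Z_prime
#' @export
default_parameters <- function(variant = c("wildtype", "mutant",
                                           "non_hysteretic_alt")) {
  if (!is.character(variant) || !variant[1] %in%
      c("wildtype", "mutant", "non_hysteretic_alt"))
    stop("unknown variant '", variant[1],
         "'; valid options: wildtype, mutant, non_hysteretic_alt")
  variant <- variant[1]
  wt <- .wildtype_values()
  p <- switch(variant,
    wildtype = wt,
    mutant = modifyList(wt, list(K_Z_prime = wt$K_Z_prime * 2.5)),
    non_hysteretic_alt = modifyList(wt, list(K_Z_prime = wt$K_Z_prime * 4)))
  validate_params(p)
  structure(p, class = "emt_params")
}

#' @export
print.emt_params <- function(x, ...) {
  cat("<emt_params>\n")
  nm <- c(.param_rate_names(), .param_hill_names())
  cat(paste0("  ", format(nm, width = 13), " = ",
             vapply(nm, function(n) format(x[[n]]), ""), collapse = "\n"), "\n")
  invisible(x)
}

#' Read / write parameter sets as flat key-value files
#'
#' Parameter files are flat JSON or YAML maps whose keys are exactly the
#' field names of [emt_params()]. The format is chosen from the file
#' extension (\code{.json}, \code{.yaml} or \code{.yml}).
#'
#' @param path file path.
#' @return \code{read_parameters} returns an \code{emt_params} object.
#' @export
read_parameters <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported parameter file extension: ", ext))
  do.call(emt_params, as.list(vals))
}

#' @param params an \code{emt_params} object.
#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  validate_params(params)
  vals <- unclass(params)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(vals, path),
    stop("unsupported parameter file extension: ", ext))
  invisible(path)
}
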