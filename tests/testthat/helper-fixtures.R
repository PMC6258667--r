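# Shared fixtures; heavier objects are computed once per test run and cached.

wt_params <- function() default_parameters("wildtype")
mut_params <- function() default_parameters("mutant")

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

wt_window_sweep <- function()
  cached("wt_window_sweep", bistable_window(wt_params(), method = "sweep"))

wt_window_reduced <- function()
  cached("wt_window_reduced", bistable_window(wt_params(), method = "reduced"))

wt_threshold <- function() cached("wt_threshold", emt_threshold(wt_params()))

# small deterministic lattice for structural tests
small_config <- function(...) {
  lattice_config(n_rows = 8, n_cols = 8, source_fraction = 0, ...)
}
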