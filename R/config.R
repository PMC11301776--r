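# Run configuration: documented defaults for every tunable, merged with a
# YAML config file and command-line overrides (overrides win).

default_config <- function() {
  list(
    digestion = list(max_missed = 0L, min_len = 5L, max_len = 30L),
    alignment = list(substitution_matrix = "BLOSUM62", gap_open = 10,
                     gap_extend = 0.5),
    pairing = list(
      overlap_threshold = 0.5,
      weights = list(w_len = 1, w_gravy = 1, w_sub = 0.25)
    ),
    transitions = list(
      precursor_charges = 2L, product_charges = 1L, series = "y",
      n_qualifiers = 3L, precursor_tol = 0.7, product_tol = 0.7
    ),
    validation = list(
      weighting = "none", min_fits = 3L, min_calibrators = 6L,
      tolerance = 15, lloq_tolerance = 20
    ),
    simulation = list(
      levels = c(0.49, 0.98, 1.95, 3.91, 15.63, 62.50, 250.00, 500.00,
                 1000.00),
      replicates = 3L, analyses = 4L, true_slope = 0.01,
      true_intercept = 0.02, noise_cv = 0.05, digestion_cv = 0.15,
      digestion_mu = 0, is_mode = "matrix", seed = NULL
    )
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Build a run configuration
#'
#' Nested list of every tunable with documented defaults: digestion bounds,
#' alignment scoring, pairing threshold and weights, transition charge sets
#' and isobaric tolerances, validation acceptance thresholds, and simulation
#' parameters. Overrides are merged section-wise over the defaults.
#'
#' @param ... Named nested overrides, e.g.
#'   `run_config(digestion = list(max_missed = 1))`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- merge_config(default_config(), list(...))
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file whose sections mirror [run_config()].
#' @param overrides Named nested list merged over the file values (overrides
#'   win).
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  structure(merge_config(cfg, overrides), class = "run_config")
}
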