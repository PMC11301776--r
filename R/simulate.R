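# Seeded simulator of calibration plates, QC sets and study samples with the
# statistical structure the surrogate-IS method assumes: multiplicative
# (lognormal) measurement noise on peak areas and a per-sample digestion
# efficiency shared between analyte and co-digested matrix IS but not with a
# post-digestion SIL-IS spike.

IS_AREA_NOMINAL <- 1e5

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic plate generator. Defaults
#' are the nine-point calibration series (0.49 to 1000 fmol on column),
#' triplicate measurement in four analyses, 5% multiplicative measurement
#' noise and a 15% per-sample digestion-efficiency dispersion.
#'
#' @param seed Integer seed; mandatory, every downstream draw is a
#'   deterministic function of it (no global random state is consumed).
#' @param levels Nominal calibrator concentrations (strictly positive,
#'   distinct).
#' @param replicates Replicates per level per analysis (default 3).
#' @param analyses Number of replicate analyses (default 4).
#' @param true_slope,true_intercept Generating line for the peak-area ratio
#'   vs nominal concentration (ratio units per concentration unit; ratio).
#' @param noise_cv Fractional multiplicative measurement noise: each area (or
#'   ratio) is multiplied by `exp(N(0, noise_cv))`.
#' @param digestion_cv Fractional SD of the per-sample digestion efficiency
#'   `exp(N(digestion_mu, digestion_cv))`.
#' @param digestion_mu Log-scale location of the digestion efficiency
#'   (default 0, i.e. median efficiency 1; set `log(0.7)` for systematically
#'   incomplete digestion).
#' @param is_mode `"matrix"` (co-digested surrogate IS) or `"sil"`
#'   (post-digestion SIL-IS spike).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              levels = c(0.49, 0.98, 1.95, 3.91, 15.63,
                                         62.50, 250.00, 500.00, 1000.00),
                              replicates = 3L, analyses = 4L,
                              true_slope = 0.01, true_intercept = 0.02,
                              noise_cv = 0.05, digestion_cv = 0.15,
                              digestion_mu = 0,
                              is_mode = c("matrix", "sil")) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("`seed` is mandatory for reproducibility")
  }
  is_mode <- match.arg(is_mode)
  if (any(levels <= 0) || anyDuplicated(levels) > 0) {
    abort("`levels` must be strictly positive and distinct")
  }
  if (noise_cv < 0 || digestion_cv < 0) abort("CVs must be >= 0")
  if (replicates < 1 || analyses < 1) {
    abort("`replicates` and `analyses` must be >= 1")
  }
  structure(
    list(levels = levels, replicates = as.integer(replicates),
         analyses = as.integer(analyses), true_slope = true_slope,
         true_intercept = true_intercept, noise_cv = noise_cv,
         digestion_cv = digestion_cv, digestion_mu = digestion_mu,
         is_mode = is_mode, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Distinct deterministic streams for the three table kinds derived from the
# one mandatory seed.
stream_seed <- function(config, offset) config$seed + offset

#' Simulate a replicate calibration plate
#'
#' For each analysis, level and replicate the peak-area ratio is
#' `(true_slope * nominal + true_intercept) * exp(e)` with
#' `e ~ N(0, noise_cv)` drawn independently; the IS area is a fixed nominal
#' constant and the analyte area is `ratio * area_is`. Deterministic under
#' the config seed.
#'
#' @param config A [simulation_config()].
#' @return Area-table tibble (the [read_area_table()] dialect) with
#'   `sample_type = "calibrator"`.
#' @export
simulate_calibration <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- tidyr::crossing(
    analysis_id = sprintf("analysis_%d", seq_len(config$analyses)),
    nominal = config$levels,
    replicate = seq_len(config$replicates)
  )
  ratio0 <- config$true_slope * grid$nominal + config$true_intercept
  eps <- withr::with_seed(stream_seed(config, 0L),
                          rnorm(nrow(grid), 0, config$noise_cv))
  grid |>
    mutate(
      sample_type = "calibrator",
      level_or_id = format(.data$nominal, trim = TRUE, scientific = FALSE),
      area_is = IS_AREA_NOMINAL,
      area_analyte = ratio0 * exp(eps) * IS_AREA_NOMINAL
    ) |>
    select(dplyr::all_of(AREA_TABLE_COLUMNS))
}

#' Simulate quality-control samples
#'
#' Replicate QC rows per level per analysis under the calibration noise
#' model.
#'
#' @param config A [simulation_config()].
#' @param qc_levels Positive QC nominal concentrations (default 32, 125,
#'   600).
#' @return Area-table tibble with `sample_type = "qc"`.
#' @export
make_qc_table <- function(config, qc_levels = c(32, 125, 600)) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(qc_levels <= 0)) abort("`qc_levels` must be positive")
  grid <- tidyr::crossing(
    analysis_id = sprintf("analysis_%d", seq_len(config$analyses)),
    nominal = qc_levels,
    replicate = seq_len(config$replicates)
  )
  ratio0 <- config$true_slope * grid$nominal + config$true_intercept
  eps <- withr::with_seed(stream_seed(config, 1L),
                          rnorm(nrow(grid), 0, config$noise_cv))
  grid |>
    mutate(
      sample_type = "qc",
      level_or_id = sprintf("QC_%s", format(.data$nominal, trim = TRUE)),
      area_is = IS_AREA_NOMINAL,
      area_analyte = ratio0 * exp(eps) * IS_AREA_NOMINAL
    ) |>
    select(dplyr::all_of(AREA_TABLE_COLUMNS))
}

#' Simulate study samples under both internal-standard modes
#'
#' Each sample draws one digestion efficiency
#' `e = exp(N(digestion_mu, digestion_cv))`, shared across both modes and
#' all replicates of the sample. The analyte area always carries `e` (the
#' sample is digested either way). Under `matrix` mode the co-digested IS
#' area carries the same `e`, so it cancels from the ratio; under `sil` mode
#' the IS is spiked after digestion and does not. Replicate measurement noise
#' is drawn independently per area and per mode.
#'
#' @param config A [simulation_config()].
#' @param n_samples Number of study samples.
#' @param true_concs Numeric vector of length `n_samples`: true analyte
#'   concentrations.
#' @return Area-table tibble with `sample_type = "sample"` and extra columns
#'   `is_mode`, `true_concentration`, `digestion_efficiency`; both modes are
#'   emitted for the same underlying samples.
#' @export
simulate_study_samples <- function(config, n_samples, true_concs) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(true_concs) != n_samples) {
    abort("`true_concs` must have length `n_samples`")
  }
  withr::with_seed(stream_seed(config, 2L), {
    eff <- exp(rnorm(n_samples, config$digestion_mu, config$digestion_cv))
    grid <- tidyr::crossing(
      is_mode = c("matrix", "sil"),
      sample = seq_len(n_samples),
      replicate = seq_len(config$replicates)
    )
    eps_analyte <- rnorm(nrow(grid), 0, config$noise_cv)
    eps_is <- rnorm(nrow(grid), 0, config$noise_cv)
    grid |>
      mutate(
        analysis_id = "study",
        sample_type = "sample",
        level_or_id = sprintf("sample_%d", .data$sample),
        nominal = NA_real_,
        true_concentration = true_concs[.data$sample],
        digestion_efficiency = eff[.data$sample],
        ratio0 = config$true_slope * .data$true_concentration +
          config$true_intercept,
        area_analyte = .data$ratio0 * .data$digestion_efficiency *
          exp(eps_analyte) * IS_AREA_NOMINAL,
        area_is = ifelse(.data$is_mode == "matrix",
                         .data$digestion_efficiency, 1) *
          exp(eps_is) * IS_AREA_NOMINAL
      ) |>
      select(dplyr::all_of(AREA_TABLE_COLUMNS), "is_mode",
             "true_concentration", "digestion_efficiency")
  })
}
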