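# broom-style tidiers for the fitted objects.

#' Tidy a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return One row per model term (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) {
  # exact (noise-free) fits make summary.lm warn; the coefficients are fine
  s <- suppressWarnings(summary(x$model)$coefficients)
  tibble(
    analysis_id = x$analysis_id,
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' Glance at a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return One-row tibble: `analysis_id`, `slope`, `intercept`, `r_squared`,
#'   `n_points`, `n_obs`, `weighting`.
#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  tibble(
    analysis_id = x$analysis_id, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, n_points = x$n_points, n_obs = x$n_obs,
    weighting = x$weighting
  )
}

#' Tidy lower assay limits
#'
#' @param x A `lower_limits`.
#' @param ... Unused.
#' @return One-row tibble: `sigma`, `S`, `llod`, `lloq`, `n_analyses`.
#' @exportS3Method generics::tidy
tidy.lower_limits <- function(x, ...) {
  tibble(sigma = x$sigma, S = x$S, llod = x$llod, lloq = x$lloq,
         n_analyses = x$n_analyses)
}

#' Glance at acceptance verdicts
#'
#' @param x An `acceptance_verdicts` tibble.
#' @param ... Unused.
#' @return One-row tibble with `n_levels`, `n_passing`, `overall_pass`.
#' @exportS3Method generics::glance
glance.acceptance_verdicts <- function(x, ...) {
  tibble(
    n_levels = nrow(x),
    n_passing = attr(x, "n_passing"),
    overall_pass = attr(x, "overall_pass")
  )
}
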