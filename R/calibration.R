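# Calibration-curve fitting, lower assay limits (LLOD/LLOQ), back-calculated
# concentrations, and FDA/ICH-style acceptance rules for calibrators and QCs.

AREA_TABLE_COLUMNS <- c("analysis_id", "sample_type", "level_or_id", "nominal",
                        "replicate", "area_analyte", "area_is")
SAMPLE_TYPES <- c("calibrator", "qc", "sample", "blank")

#' Read a peak-area table
#'
#' Reads the tab-delimited dialect used throughout the validation layer:
#' columns `analysis_id`, `sample_type` (calibrator|qc|sample|blank),
#' `level_or_id`, `nominal`, `replicate`, `area_analyte`, `area_is`. Lines
#' starting with `#` are comments (the simulator echoes its configuration
#' there). Extra columns (e.g. `is_mode`) are preserved. Dialect violations
#' are errors naming the offending row and column.
#'
#' @param path Path to a TSV area table.
#' @return Tibble in the area-table dialect.
#' @export
read_area_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("area table not found: %s", path))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(AREA_TABLE_COLUMNS, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing required columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  tbl$level_or_id <- as.character(tbl$level_or_id)
  bad_type <- which(!tbl$sample_type %in% SAMPLE_TYPES)
  if (length(bad_type) > 0) {
    abort(sprintf("'%s': row %d, column 'sample_type': unknown value '%s'",
                  path, bad_type[1], tbl$sample_type[bad_type[1]]))
  }
  for (col in c("nominal", "area_analyte", "area_is")) {
    if (is.logical(tbl[[col]]) && all(is.na(tbl[[col]]))) {
      tbl[[col]] <- as.numeric(tbl[[col]])
    }
    if (!is.numeric(tbl[[col]])) {
      abort(sprintf("'%s': column '%s' must be numeric", path, col))
    }
  }
  bad_area <- which(tbl$area_analyte < 0 | tbl$area_is <= 0)
  if (length(bad_area) > 0) {
    abort(sprintf("'%s': row %d: areas must be positive", path, bad_area[1]))
  }
  tbl
}

#' Write a peak-area table
#'
#' @param data Area-table tibble.
#' @param path Output TSV path.
#' @param config Optional [simulation_config()] or named list echoed into
#'   `#`-prefixed header comments for provenance.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(data, path, config = NULL) {
  header <- character()
  if (!is.null(config)) {
    flat <- unlist(config)
    header <- sprintf("# %s: %s", names(flat), as.character(flat))
  }
  writeLines(header, path)
  readr::write_tsv(as_tibble(data), path, append = length(header) > 0,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Add peak-area ratios
#'
#' @param data Area-table tibble.
#' @return `data` with a `ratio = area_analyte / area_is` column.
#' @export
calibration_ratios <- function(data) {
  mutate(as_tibble(data), ratio = .data$area_analyte / .data$area_is)
}

#' Fit a calibration curve for one analysis
#'
#' Least-squares line of peak-area ratio on nominal concentration, with
#' replicate ratios entering as individual observations. Optional `1/x` or
#' `1/x^2` weighting in the nominal concentration.
#'
#' @param data Tibble with `nominal` and `ratio` columns (ratios computed via
#'   [calibration_ratios()] if needed) for a single analysis; rows with
#'   `nominal = 0` (zero calibrator) are excluded from the fit.
#' @param weighting `"none"` (default), `"1/x"` or `"1/x^2"`.
#' @param use_means Fit on per-level replicate means instead of individual
#'   observations (default `FALSE`; individual observations give the
#'   intercept dispersion the lower-limit formulas need).
#' @return A `calibration_fit`: analysis id, `slope`, `intercept`,
#'   `r_squared`, weighting, point counts, the underlying `lm` and data.
#' @examples
#' d <- tibble::tibble(nominal = c(1, 2, 4, 8), ratio = 2 * c(1, 2, 4, 8) + 0.5)
#' fit_calibration(d)
#' @export
fit_calibration <- function(data, weighting = c("none", "1/x", "1/x^2"),
                            use_means = FALSE) {
  weighting <- match.arg(weighting)
  data <- as_tibble(data)
  if (!"ratio" %in% names(data)) data <- calibration_ratios(data)
  if ("analysis_id" %in% names(data) &&
      length(unique(data$analysis_id)) > 1) {
    abort("`data` spans several analyses; use fit_calibrations()")
  }
  analysis_id <- if ("analysis_id" %in% names(data)) data$analysis_id[[1]] else "analysis"
  pts <- filter(data, .data$nominal > 0)
  if (length(unique(pts$nominal)) < 2) {
    abort("degenerate design: need at least 2 distinct nonzero nominal levels")
  }
  if (use_means) {
    pts <- pts |> group_by(.data$nominal) |>
      summarise(ratio = mean(.data$ratio), .groups = "drop")
  }
  w <- switch(weighting, none = NULL, `1/x` = 1 / pts$nominal,
              `1/x^2` = 1 / pts$nominal^2)
  fit <- if (is.null(w)) lm(ratio ~ nominal, data = pts) else
    lm(ratio ~ nominal, data = pts, weights = w)
  # coefficient of determination computed directly (the summary.lm route
  # warns on exactly linear, i.e. noise-free, inputs)
  wts <- w %||% rep(1, nrow(pts))
  ss_res <- sum(wts * stats::residuals(fit)^2)
  ss_tot <- sum(wts * (pts$ratio - stats::weighted.mean(pts$ratio, wts))^2)
  structure(
    list(
      analysis_id = analysis_id,
      slope = unname(coef(fit)[["nominal"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
      weighting = weighting,
      n_points = length(unique(pts$nominal)),
      n_obs = nrow(pts),
      model = fit,
      data = pts
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit '%s'> ratio = %.6g * nominal + %.6g  (R2 = %.5f, %d levels, %d obs, weighting %s)\n",
    x$analysis_id, x$slope, x$intercept, x$r_squared, x$n_points, x$n_obs,
    x$weighting
  ))
  invisible(x)
}

#' Fit calibration curves for every analysis in a table
#'
#' @inheritParams fit_calibration
#' @param data Area/ratio tibble with an `analysis_id` column; only
#'   `sample_type == "calibrator"` rows are used when the column is present.
#' @return Named list of `calibration_fit` objects, one per analysis.
#' @export
fit_calibrations <- function(data, weighting = c("none", "1/x", "1/x^2"),
                             use_means = FALSE) {
  weighting <- match.arg(weighting)
  data <- as_tibble(data)
  if ("sample_type" %in% names(data)) {
    data <- filter(data, .data$sample_type == "calibrator")
  }
  split(data, data$analysis_id) |>
    lapply(fit_calibration, weighting = weighting, use_means = use_means)
}

#' Lower limits of detection and quantitation
#'
#' `LLOD = 3.3 * sigma / S` and `LLOQ = 10 * sigma / S`, with `sigma` the
#' sample standard deviation (n-1 denominator) of the y-intercepts of the
#' replicate-analysis regression lines and `S` the mean slope. The
#' alternative `sigma_mode = "residual"` uses the pooled residual standard
#' error instead of the intercept dispersion.
#'
#' @param fits List of `calibration_fit` objects from replicate analyses.
#' @param min_fits Minimum analyses required (default 3).
#' @param sigma_mode `"intercepts"` (default) or `"residual"`.
#' @return A `lower_limits` object: `sigma`, `S`, `llod`, `lloq`,
#'   `n_analyses`. `lloq / llod` is exactly `10 / 3.3` by construction.
#' @examples
#' d <- tidyr::crossing(analysis_id = 1:3, nominal = c(1, 2, 4, 8)) |>
#'   dplyr::mutate(ratio = 0.1 * nominal + 0.02 + 0.001 * analysis_id)
#' lower_limits(fit_calibrations(d))
#' @export
lower_limits <- function(fits, min_fits = 3L,
                         sigma_mode = c("intercepts", "residual")) {
  sigma_mode <- match.arg(sigma_mode)
  if (inherits(fits, "calibration_fit")) fits <- list(fits)
  if (length(fits) < min_fits) {
    abort(sprintf("insufficient replication: %d analyses provided, %d required",
                  length(fits), min_fits))
  }
  intercepts <- map_dbl(fits, "intercept")
  slopes <- map_dbl(fits, "slope")
  sigma <- switch(sigma_mode,
    intercepts = sd(intercepts),
    residual = sqrt(mean(map_dbl(fits, ~ summary(.x$model)$sigma^2)))
  )
  S <- mean(slopes)
  llod <- 3.3 * sigma / S
  structure(
    list(sigma = sigma, S = S, llod = llod, lloq = llod * (10 / 3.3),
         n_analyses = length(fits), sigma_mode = sigma_mode),
    class = "lower_limits"
  )
}

#' @export
print.lower_limits <- function(x, ...) {
  cat(sprintf(
    "<lower_limits> sigma = %.4g, S = %.4g (n = %d) -> LLOD = %.4g, LLOQ = %.4g\n",
    x$sigma, x$S, x$n_analyses, x$llod, x$lloq
  ))
  invisible(x)
}

#' Back-calculate concentration from a peak-area ratio
#'
#' `(ratio - intercept) / slope`. Values may be negative and are reported
#' as-is; when `limits` is supplied a `below_llod` flag is attached.
#'
#' @param ratio Numeric vector of peak-area ratios.
#' @param fit A `calibration_fit` (or any list with `slope` and `intercept`).
#' @param limits Optional `lower_limits` used to flag values below LLOD.
#' @return Numeric vector of concentrations (with a `below_llod` logical
#'   attribute when `limits` is given).
#' @export
back_calculate <- function(ratio, fit, limits = NULL) {
  if (fit$slope == 0) abort("cannot back-calculate with zero slope")
  conc <- (ratio - fit$intercept) / fit$slope
  if (!is.null(limits)) attr(conc, "below_llod") <- conc < limits$llod
  conc
}

acceptance_metrics <- function(data, fit, lloq_level, tolerance,
                               lloq_tolerance) {
  data |>
    filter(.data$nominal > 0) |>
    mutate(back_calc = back_calculate(.data$ratio, fit)) |>
    group_by(level = .data$nominal) |>
    summarise(
      n = dplyr::n(),
      mean_recovery_pct = 100 * mean(.data$back_calc) / .data$nominal[1],
      cv_pct = 100 * sd(.data$back_calc) / mean(.data$back_calc),
      re_pct = 100 * (mean(.data$back_calc) - .data$nominal[1]) /
        .data$nominal[1],
      .groups = "drop"
    ) |>
    mutate(
      tolerance_pct = ifelse(!is.na(lloq_level) & .data$level == lloq_level,
                             lloq_tolerance, tolerance),
      pass = abs(.data$mean_recovery_pct - 100) <= .data$tolerance_pct &
        .data$cv_pct <= .data$tolerance_pct &
        abs(.data$re_pct) <= .data$tolerance_pct
    )
}

#' Assess calibrator acceptance
#'
#' Per nonzero level: mean % recovery (`100 * mean(back-calculated) /
#' nominal`), precision (%CV of the back-calculated replicates) and accuracy
#' (% relative error). The tolerance is ±`lloq_tolerance` (default 20%) at
#' the LLOQ-level calibrator and ±`tolerance` (default 15%) elsewhere; a
#' level passes iff all three metrics are within tolerance. The analysis
#' passes overall iff at least `min_calibrators` (default 6) nonzero levels
#' pass.
#'
#' @param fit `calibration_fit` for the analysis.
#' @param data Calibrator rows (with `nominal` and `ratio`) of the same
#'   analysis; the zero calibrator is excluded from verdicts.
#' @param lloq_level Nominal concentration of the LLOQ-level calibrator
#'   (default: the lowest nonzero level).
#' @param tolerance,lloq_tolerance Acceptance tolerances in percent.
#' @param min_calibrators Minimum passing nonzero levels for an overall pass.
#' @return An `acceptance_verdicts` tibble (`level`, `n`,
#'   `mean_recovery_pct`, `cv_pct`, `re_pct`, `tolerance_pct`, `pass`) with
#'   attributes `overall_pass` and `n_passing`.
#' @export
assess_calibrators <- function(fit, data, lloq_level = NULL, tolerance = 15,
                               lloq_tolerance = 20, min_calibrators = 6L) {
  data <- as_tibble(data)
  if (!"ratio" %in% names(data)) data <- calibration_ratios(data)
  if ("sample_type" %in% names(data)) {
    data <- filter(data, .data$sample_type == "calibrator")
  }
  lloq_level <- lloq_level %||% min(data$nominal[data$nominal > 0])
  verdicts <- acceptance_metrics(data, fit, lloq_level, tolerance,
                                 lloq_tolerance)
  structure(verdicts,
            class = c("acceptance_verdicts", class(verdicts)),
            overall_pass = sum(verdicts$pass) >= min_calibrators,
            n_passing = sum(verdicts$pass),
            min_calibrators = min_calibrators)
}

#' Assess quality-control samples
#'
#' Same metrics as [assess_calibrators()] with a ±`tolerance` (default 15%)
#' acceptance band at every QC level; QC levels need not coincide with
#' calibrator levels.
#'
#' @param data QC rows (`nominal`, `ratio`) measured against `fit`.
#' @param fit `calibration_fit` used for back-calculation.
#' @param tolerance Acceptance tolerance in percent (default 15).
#' @return An `acceptance_verdicts` tibble (no overall ≥6 rule for QCs;
#'   `overall_pass` is TRUE iff every level passes).
#' @export
assess_qc <- function(data, fit, tolerance = 15) {
  data <- as_tibble(data)
  if (!"ratio" %in% names(data)) data <- calibration_ratios(data)
  if ("sample_type" %in% names(data)) {
    data <- filter(data, .data$sample_type == "qc")
  }
  verdicts <- acceptance_metrics(data, fit, lloq_level = NA_real_,
                                 tolerance = tolerance,
                                 lloq_tolerance = tolerance)
  structure(verdicts,
            class = c("acceptance_verdicts", class(verdicts)),
            overall_pass = all(verdicts$pass),
            n_passing = sum(verdicts$pass),
            min_calibrators = NA_integer_)
}

# Exact Mann-Whitney for small untied samples, normal approximation with
# tie correction otherwise.
wilcoxon_rank_sum_p <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 20
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Compare two internal-standard methods per sample
#'
#' Two-sided Wilcoxon test of the per-sample replicate concentrations
#' measured under method A (e.g. co-digested matrix surrogate IS) and method
#' B (e.g. SIL-IS). The rank-sum (Mann-Whitney) form for independent
#' replicate groups is the default; a paired signed-rank mode is available.
#' The exact distribution is used for combined n <= 20 without ties, the
#' normal approximation with tie correction otherwise.
#'
#' @param a,b Data frames with columns `sample_id` and `conc` (replicate
#'   back-calculated concentrations per sample) for the two methods.
#' @param test `"rank-sum"` (default) or `"signed-rank"` (paired).
#' @param alpha Significance thresholds flagged in the output.
#' @return A `method_comparison` tibble: per sample, replicate counts, mean
#'   concentrations, `p_value`, significance flags at 0.05 and 0.01, and a
#'   `note` for samples with insufficient replication (p is `NA` there, not
#'   an error).
#' @export
compare_methods <- function(a, b, test = c("rank-sum", "signed-rank"),
                            alpha = c(0.05, 0.01)) {
  test <- match.arg(test)
  samples <- union(unique(a$sample_id), unique(b$sample_id))
  out <- map_dfr(samples, function(id) {
    xa <- a$conc[a$sample_id == id]
    xb <- b$conc[b$sample_id == id]
    note <- NA_character_
    p <- NA_real_
    if (length(xa) < 2 || length(xb) < 2) {
      note <- "insufficient replicates (need >= 2 per method)"
    } else if (test == "signed-rank" && length(xa) != length(xb)) {
      note <- "paired test requires equal replicate counts"
    } else {
      p <- if (test == "rank-sum") {
        wilcoxon_rank_sum_p(xa, xb)
      } else {
        suppressWarnings(wilcox.test(xa, xb, paired = TRUE,
                                     alternative = "two.sided")$p.value)
      }
    }
    tibble(
      sample_id = id,
      n_a = length(xa), n_b = length(xb),
      mean_conc_a = mean(xa), mean_conc_b = mean(xb),
      p_value = p,
      signif_05 = !is.na(p) & p < alpha[1],
      signif_01 = !is.na(p) & p < alpha[2],
      note = note
    )
  })
  class(out) <- c("method_comparison", class(out))
  out
}
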