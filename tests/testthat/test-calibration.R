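test_that("calibration fitting recovers exact lines and rejects degenerate designs", {
  d <- tibble::tibble(nominal = c(1, 2, 4, 8), ratio = 2 * c(1, 2, 4, 8) + 0.5)
  fit <- fit_calibration(d)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 4)

  expect_error(fit_calibration(tibble::tibble(nominal = c(5, 5, 5),
                                              ratio = c(1, 1.1, 0.9))),
               "degenerate")
})

test_that("weighted fits equal the normal-equations oracle", {
  set.seed(51)
  x <- rep(c(0.5, 1, 2, 5, 10, 50, 100), each = 3)
  y <- (0.08 * x + 0.3) * exp(rnorm(length(x), 0, 0.1))
  d <- tibble::tibble(nominal = x, ratio = y)
  for (wmode in c("none", "1/x", "1/x^2")) {
    fit <- fit_calibration(d, weighting = wmode)
    w <- switch(wmode, none = rep(1, length(x)), `1/x` = 1 / x,
                `1/x^2` = 1 / x^2)
    beta <- oracle_wls(x, y, w)
    expect_equal(fit$slope, unname(beta["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(beta["intercept"]), tolerance = 1e-10)
  }
})

test_that("lower limits implement 3.3*sigma/S and 10*sigma/S with the exact ratio", {
  mkfit <- function(slope, intercept) {
    structure(list(analysis_id = "a", slope = slope, intercept = intercept),
              class = "calibration_fit")
  }
  z <- lower_limits(list(mkfit(2, 0.1), mkfit(2, 0.1), mkfit(2, 0.1)))
  expect_equal(z$sigma, 0)
  expect_equal(z$llod, 0)
  expect_equal(z$lloq, 0)

  # sigma 0.03, mean slope 0.1 -> llod 0.99, lloq 3.0
  ints <- c(0.1, 0.13, 0.16)
  expect_equal(sd(ints), 0.03)
  z2 <- lower_limits(list(mkfit(0.1, ints[1]), mkfit(0.1, ints[2]),
                          mkfit(0.1, ints[3])))
  expect_equal(z2$llod, 0.99, tolerance = 1e-9)
  expect_equal(z2$lloq, 3.0, tolerance = 1e-9)

  set.seed(52)
  for (k in 1:25) {
    fits <- lapply(1:4, function(i) mkfit(runif(1, 0.01, 2), rnorm(1, 0, 0.2)))
    zz <- lower_limits(fits)
    expect_equal(zz$lloq / zz$llod, 10 / 3.3, tolerance = 1e-15)
    expect_equal(zz$llod,
                 3.3 * sd(sapply(fits, `[[`, "intercept")) /
                   mean(sapply(fits, `[[`, "slope")))
  }

  expect_error(lower_limits(list(mkfit(1, 0), mkfit(1, 0))),
               "insufficient replication")
})

test_that("back-calculation inverts the fit", {
  fit <- structure(list(slope = 2, intercept = 0.5), class = "calibration_fit")
  expect_equal(back_calculate(4.5, fit), 2.0)
  expect_equal(back_calculate(0.5, fit), 0)
  expect_error(back_calculate(1, structure(list(slope = 0, intercept = 0),
                                           class = "calibration_fit")),
               "zero slope")

  set.seed(53)
  for (k in 1:30) {
    f <- structure(list(slope = runif(1, 0.01, 5), intercept = rnorm(1)),
                   class = "calibration_fit")
    conc <- runif(5, 0, 100)
    pred <- f$slope * conc + f$intercept
    expect_equal(back_calculate(pred, f), conc, tolerance = 1e-12)
  }

  lim <- structure(list(llod = 1), class = "lower_limits")
  flagged <- back_calculate(c(0.6, 4.5), fit, limits = lim)
  expect_equal(attr(flagged, "below_llod"), c(TRUE, FALSE))
})

test_that("calibrator verdicts apply the 15/20 percent rules and the six-calibrator gate", {
  levels <- c(0.5, 1, 2, 5, 10, 50, 100, 500, 1000)
  perfect <- tidyr::crossing(nominal = levels, replicate = 1:3) |>
    dplyr::mutate(ratio = 0.01 * nominal + 0.02)
  fit <- fit_calibration(perfect)
  v <- assess_calibrators(fit, perfect)
  expect_true(all(v$pass))
  expect_equal(v$mean_recovery_pct, rep(100, 9), tolerance = 1e-9)
  expect_equal(v$tolerance_pct, c(20, rep(15, 8)))
  expect_true(attr(v, "overall_pass"))

  # one non-LLOQ level reading 80% of nominal fails (20% error > 15%)
  bias <- perfect |>
    dplyr::mutate(ratio = ifelse(nominal == 10, 0.01 * (0.8 * nominal) + 0.02,
                                 ratio))
  vb <- assess_calibrators(fit, bias)
  expect_false(vb$pass[vb$level == 10])
  expect_equal(vb$re_pct[vb$level == 10], -20, tolerance = 1e-9)
  expect_true(attr(vb, "overall_pass")) # still 8 passing levels

  # fewer than six passing levels -> overall fail
  few <- dplyr::filter(perfect, nominal <= 10)
  vf <- assess_calibrators(fit_calibration(few), few)
  expect_true(all(vf$pass))
  expect_false(attr(vf, "overall_pass"))

  # LLOQ-level calibrator gets the wider 20% band
  edge <- perfect |>
    dplyr::mutate(ratio = ifelse(nominal == 0.5, 0.01 * (0.82 * nominal) + 0.02,
                                 ratio))
  ve <- assess_calibrators(fit, edge)
  expect_true(ve$pass[ve$level == 0.5])
})

test_that("verdicts equal a spreadsheet-style oracle on a noisy synthetic series", {
  set.seed(54)
  levels <- c(0.49, 0.98, 1.95, 3.91, 15.63, 62.5, 250, 500, 1000)
  d <- tidyr::crossing(nominal = levels, replicate = 1:3) |>
    dplyr::mutate(ratio = (0.01 * nominal + 0.02) *
                    exp(rnorm(dplyr::n(), 0, 0.05)))
  fit <- fit_calibration(d)
  v <- assess_calibrators(fit, d)
  want <- oracle_verdicts(d$nominal, d$ratio, fit$slope, fit$intercept,
                          lloq_level = 0.49)
  expect_equal(v$level, want$level)
  expect_equal(v$mean_recovery_pct, want$mean_recovery_pct, tolerance = 1e-9)
  expect_equal(v$cv_pct, want$cv_pct, tolerance = 1e-9)
  expect_equal(v$re_pct, want$re_pct, tolerance = 1e-9)
  expect_equal(v$pass, want$pass)

  # verdicts are invariant to rescaling all areas by a common factor
  areas <- d |>
    dplyr::mutate(analysis_id = "a1", sample_type = "calibrator",
                  level_or_id = as.character(nominal),
                  area_is = 2e4, area_analyte = ratio * area_is) |>
    dplyr::select(-ratio)
  scaled <- dplyr::mutate(areas, area_is = area_is * 7.3,
                          area_analyte = area_analyte * 7.3)
  v1 <- assess_calibrators(fit, calibration_ratios(areas))
  v2 <- assess_calibrators(fit, calibration_ratios(scaled))
  expect_equal(as.data.frame(v1), as.data.frame(v2), tolerance = 1e-12)
})

test_that("QC assessment uses a 15% band at every level", {
  fit <- structure(list(slope = 0.01, intercept = 0.02, analysis_id = "a"),
                   class = "calibration_fit")
  qc <- tidyr::crossing(nominal = c(32, 125, 600), replicate = 1:3) |>
    dplyr::mutate(ratio = 0.01 * nominal + 0.02)
  v <- assess_qc(qc, fit)
  expect_true(all(v$pass))
  expect_equal(v$mean_recovery_pct, rep(100, 3), tolerance = 1e-9)
  expect_equal(v$tolerance_pct, rep(15, 3))

  # 116% recovery breaches the 115% bound
  high <- dplyr::mutate(qc, ratio = 0.01 * (1.16 * nominal) + 0.02)
  vh <- assess_qc(high, fit)
  expect_false(any(vh$pass))
  expect_equal(vh$mean_recovery_pct, rep(116, 3), tolerance = 1e-9)

  # simulated QC plate equals independent recomputation
  set.seed(55)
  sim <- make_qc_table(simulation_config(seed = 7, analyses = 1))
  simr <- calibration_ratios(sim)
  vsim <- assess_qc(simr, fit)
  want <- oracle_verdicts(simr$nominal, simr$ratio, 0.01, 0.02,
                          lloq_level = NA, tol = 15, lloq_tol = 15)
  expect_equal(vsim$mean_recovery_pct, want$mean_recovery_pct,
               tolerance = 1e-9)
  expect_equal(vsim$pass, want$pass)
})

test_that("method comparison uses the exact rank-sum distribution and is symmetric", {
  mk <- function(id, v) tibble::tibble(sample_id = id, conc = v)
  eq <- compare_methods(mk("s1", c(1, 2, 3)), mk("s1", c(1, 2, 3)))
  expect_equal(eq$p_value, 1)

  sep <- compare_methods(mk("s1", c(1, 2, 3)), mk("s1", c(10, 11, 12)))
  expect_equal(sep$p_value, 0.1, tolerance = 1e-12)
  expect_false(sep$signif_05)

  # symmetry in argument order
  set.seed(56)
  for (k in 1:10) {
    a <- mk("s", rnorm(4))
    b <- mk("s", rnorm(5))
    expect_equal(compare_methods(a, b)$p_value, compare_methods(b, a)$p_value)
  }

  # insufficient replication is a diagnostic, not an error
  short <- compare_methods(mk("s1", 1), mk("s1", c(1, 2, 3)))
  expect_true(is.na(short$p_value))
  expect_match(short$note, "insufficient")

  # paired signed-rank mode
  pr <- compare_methods(mk("s1", c(1, 2, 3, 4)), mk("s1", c(2, 3, 4, 5)),
                        test = "signed-rank")
  expect_true(pr$p_value > 0 && pr$p_value <= 1)
})

test_that("area tables round-trip with validation errors naming row and column", {
  cfg <- simulation_config(seed = 3)
  tbl <- simulate_calibration(cfg)
  tf <- tempfile(fileext = ".tsv")
  write_area_table(tbl, tf, config = cfg)
  back <- read_area_table(tf)
  expect_equal(nrow(back), nrow(tbl))
  expect_equal(back$area_analyte, tbl$area_analyte, tolerance = 1e-9)
  expect_true(startsWith(readLines(tf, n = 1), "#"))

  broken <- dplyr::mutate(tbl, sample_type = replace(sample_type, 3, "junk"))
  tf2 <- tempfile(fileext = ".tsv")
  write_area_table(broken, tf2)
  expect_error(read_area_table(tf2), "row 3.*sample_type")

  missing_col <- dplyr::select(tbl, -area_is)
  tf3 <- tempfile(fileext = ".tsv")
  readr::write_tsv(missing_col, tf3)
  expect_error(read_area_table(tf3), "missing required columns.*area_is")
})
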