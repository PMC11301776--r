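# Physicochemical constants. Residue masses are monoisotopic (Da) for the 20
# standard amino acids; water and proton to the precision needed to reproduce
# unit-resolution MRM tables at 1 dp.

RESIDUE_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764, V = 99.068414,
  T = 101.047678, C = 103.009185, L = 113.084064, I = 113.084064,
  N = 114.042927, D = 115.026943, Q = 128.058578, K = 128.094963,
  E = 129.042593, M = 131.040485, H = 137.058912, F = 147.068414,
  R = 156.101111, Y = 163.063329, W = 186.079313
)

WATER_MONO <- 18.010565
PROTON_MASS <- 1.007276

# Kyte & Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

STANDARD_RESIDUES <- names(RESIDUE_MONO)

# Assert every residue of every sequence is standard; error names the first
# offending record and position.
check_standard_residues <- function(sequence, what = "sequence") {
  for (i in seq_along(sequence)) {
    res <- strsplit(sequence[[i]], "")[[1]]
    bad <- which(!res %in% STANDARD_RESIDUES)
    if (length(bad) > 0) {
      abort(sprintf(
        "non-standard residue '%s' at position %d of %s '%s'",
        res[bad[1]], bad[1], what, sequence[[i]]
      ))
    }
  }
  invisible(sequence)
}

residue_masses <- function(sequence) {
  check_standard_residues(sequence)
  lapply(strsplit(sequence, ""), function(r) unname(RESIDUE_MONO[r]))
}

#' Peptide monoisotopic mass
#'
#' Sum of standard residue monoisotopic masses plus one water (18.010565 Da).
#' No fixed or variable modifications are applied by default; `fixed_mods`
#' adds a per-residue mass delta (e.g. `c(C = 57.021464)` for
#' carbamidomethyl-cysteine).
#'
#' @param sequence Character vector of peptide sequences (uppercase, standard
#'   residues only).
#' @param fixed_mods Named numeric vector of per-residue mass deltas in Da.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("LVNEVTEFAK")
#' @export
monoisotopic_mass <- function(sequence, fixed_mods = NULL) {
  stopifnot(is.character(sequence), all(nchar(sequence) >= 1))
  masses <- residue_masses(sequence)
  vapply(seq_along(masses), function(i) {
    m <- sum(masses[[i]]) + WATER_MONO
    if (!is.null(fixed_mods)) {
      res <- strsplit(sequence[[i]], "")[[1]]
      m <- m + sum(fixed_mods[res], na.rm = TRUE)
    }
    m
  }, numeric(1))
}

#' Precursor m/z at a given charge
#'
#' `(M + z * 1.007276) / z` with `M` the peptide monoisotopic mass.
#'
#' @inheritParams monoisotopic_mass
#' @param charge Positive integer charge state (vectorized).
#' @return Numeric vector of m/z values.
#' @examples
#' precursor_mz("TSALSAK", 2)
#' @export
precursor_mz <- function(sequence, charge = 2L, fixed_mods = NULL) {
  if (any(charge <= 0) || any(charge != as.integer(charge))) {
    abort("`charge` must be a positive integer")
  }
  (monoisotopic_mass(sequence, fixed_mods) + charge * PROTON_MASS) / charge
}

#' Fragment-ion m/z for the b/y series
#'
#' y-ion neutral mass is the sum of the C-terminal `index` residue masses plus
#' water; b-ion neutral mass is the sum of the N-terminal `index` residue
#' masses. m/z is `(neutral + charge * proton) / charge`.
#'
#' @param sequence Single peptide sequence.
#' @param series `"b"` or `"y"`.
#' @param index Fragment index, in `[1, nchar(sequence) - 1]` (vectorized).
#' @param charge Positive integer product charge.
#' @return A tibble with columns `sequence`, `series`, `index`, `charge`,
#'   `mz`, and `annotation` (e.g. `"y5"`).
#' @examples
#' fragment_mz("LVNEVTEFAK", "y", 5:6)
#' @export
fragment_mz <- function(sequence, series = c("y", "b"), index, charge = 1L) {
  stopifnot(length(sequence) == 1)
  series <- match.arg(series)
  n <- nchar(sequence)
  if (any(index < 1) || any(index > n - 1)) {
    abort(sprintf("fragment index must lie in [1, %d] for '%s'", n - 1, sequence))
  }
  if (any(charge <= 0)) abort("`charge` must be a positive integer")
  m <- residue_masses(sequence)[[1]]
  neutral <- vapply(index, function(i) {
    if (series == "y") sum(m[(n - i + 1):n]) + WATER_MONO else sum(m[1:i])
  }, numeric(1))
  tidyr::crossing(tibble(index = index, neutral = neutral), charge = charge) |>
    mutate(
      sequence = sequence,
      series = series,
      mz = (.data$neutral + .data$charge * PROTON_MASS) / .data$charge,
      annotation = paste0(series, .data$index)
    ) |>
    select("sequence", "series", "index", "charge", "mz", "annotation")
}

#' All b/y fragment ions of a peptide
#'
#' @inheritParams fragment_mz
#' @param series Character vector over `c("b", "y")`.
#' @param charges Integer vector of product charge states.
#' @return Tibble as in [fragment_mz()], one row per (series, index, charge).
#' @export
fragment_ions <- function(sequence, series = c("b", "y"), charges = 1L) {
  n <- nchar(sequence)
  map_dfr(series, function(s) fragment_mz(sequence, s, seq_len(n - 1), charges))
}

#' GRAVY hydrophobicity index
#'
#' Grand average of hydropathy: the mean Kyte-Doolittle hydropathy value over
#' the residues of the peptide. Used as a retention-behavior proxy when
#' matching surrogate peptides to their targets.
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector of GRAVY values (dimensionless).
#' @examples
#' gravy("QTALVELVK")
#' @export
gravy <- function(sequence) {
  check_standard_residues(sequence)
  vapply(strsplit(sequence, ""), function(r) mean(KYTE_DOOLITTLE[r]), numeric(1))
}

#' Round half away from zero
#'
#' Presentation helper matching the rounding convention of printed MRM tables
#' (1 dp for m/z, 2 dp for GRAVY). Base `round()` rounds half to even, which
#' can differ at the printed precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tabulate peptide physicochemical properties
#'
#' Data-frame-first wrapper adding `length`, `monoisotopic_mass`, `mz_2plus`,
#' `mz_3plus` and `gravy` columns for a column of peptide sequences.
#'
#' @param data A data frame with a peptide-sequence column.
#' @param sequence Tidy-selected column holding sequences (default
#'   `sequence`).
#' @return `data` as a tibble with the property columns appended.
#' @examples
#' tibble::tibble(sequence = c("TSALSAK", "VLEPTLK")) |> peptide_properties()
#' @export
peptide_properties <- function(data, sequence = "sequence") {
  seqs <- dplyr::pull(data, {{ sequence }})
  as_tibble(data) |>
    mutate(
      length = nchar(seqs),
      monoisotopic_mass = monoisotopic_mass(seqs),
      mz_2plus = precursor_mz(seqs, 2L),
      mz_3plus = precursor_mz(seqs, 3L),
      gravy = gravy(seqs)
    )
}
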