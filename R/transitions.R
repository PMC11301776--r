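# MRM transition enumeration, isobaric-conflict screening within an assay
# background, and quantifier/qualifier role assignment.

#' Enumerate candidate MRM transitions for a peptide
#'
#' Full cross-product of the requested precursor charges, fragment series,
#' fragment indices and product charges, with m/z from the peptide property
#' layer. Output order is deterministic: precursor charge, series, index,
#' product charge.
#'
#' @param peptide Peptide sequence (string) or one-row digest tibble (parent
#'   and span are carried through when present).
#' @param precursor_charges Integer vector of precursor charge states
#'   (default 2).
#' @param series Fragment series subset of `c("b", "y")` (default `"y"`).
#' @param min_index,max_index Fragment index bounds; `max_index = NULL` means
#'   `length - 1`.
#' @param product_charges Integer vector of product charge states (default 1).
#' @return Tibble of candidate transitions: `protein`, `peptide`,
#'   `precursor_mz`, `precursor_charge`, `series`, `fragment_index`,
#'   `product_mz`, `product_charge`, `annotation`, `role = "candidate"`.
#' @examples
#' enumerate_transitions("TSALSAK", series = "y", min_index = 3, max_index = 6)
#' @export
enumerate_transitions <- function(peptide, precursor_charges = 2L,
                                  series = "y", min_index = 1L,
                                  max_index = NULL, product_charges = 1L) {
  if (is.data.frame(peptide)) {
    protein <- peptide$parent[[1]] %||% NA_character_
    pep_start <- peptide$start[[1]] %||% NA_integer_
    seq <- peptide$sequence[[1]]
  } else {
    protein <- NA_character_
    pep_start <- NA_integer_
    seq <- peptide
  }
  n <- nchar(seq)
  max_index <- max_index %||% (n - 1L)
  if (min_index < 1 || max_index > n - 1 || min_index > max_index) {
    abort(sprintf("fragment index bounds must lie in [1, %d]", n - 1))
  }
  frags <- map_dfr(sort(series), function(s) {
    fragment_mz(seq, s, seq(min_index, max_index), product_charges)
  })
  tidyr::crossing(precursor_charge = sort(as.integer(precursor_charges)),
                  frags) |>
    mutate(
      protein = protein,
      peptide = seq,
      peptide_start = pep_start,
      precursor_mz = precursor_mz(seq, .data$precursor_charge)
    ) |>
    arrange(.data$precursor_charge, .data$series, .data$index, .data$charge) |>
    transmute(
      protein = .data$protein, peptide = .data$peptide,
      peptide_start = .data$peptide_start,
      precursor_mz = .data$precursor_mz,
      precursor_charge = .data$precursor_charge,
      series = .data$series, fragment_index = .data$index,
      product_mz = .data$mz, product_charge = .data$charge,
      annotation = .data$annotation, role = "candidate"
    )
}

#' Detect isobaric conflicts against a background digest
#'
#' A candidate transition conflicts with a background peptide (other than the
#' candidate's own digest entry) iff the background precursor at the
#' candidate's precursor charge lies within `precursor_tol` AND any b/y
#' product of the background peptide (over the candidate's product charge
#' set) lies within `product_tol`. All conflicts are reported, one row per
#' interfering ion.
#'
#' @param candidates Transition tibble from [enumerate_transitions()].
#' @param background Digest tibble (or character vector of sequences) of the
#'   assay background: panel peptides and optionally a matrix proteome digest.
#' @param precursor_tol,product_tol Tolerances in Da (defaults 0.7, the width
#'   of a unit-resolution quadrupole window).
#' @return Conflict tibble: candidate identity, `interferer_peptide`,
#'   `interferer_annotation`, `precursor_delta`, `product_delta`.
#' @export
detect_isobaric_conflicts <- function(candidates, background,
                                      precursor_tol = 0.7, product_tol = 0.7) {
  if (precursor_tol <= 0 || product_tol <= 0) {
    abort("tolerances must be positive")
  }
  if (is.character(background)) {
    background <- tibble(parent = NA_character_, sequence = background,
                         start = NA_integer_)
  }
  if (nrow(candidates) == 0 || nrow(background) == 0) {
    return(empty_conflicts())
  }
  product_charges <- sort(unique(candidates$product_charge))
  bg <- distinct(as_tibble(background), .data$sequence, .data$parent,
                 .data$start)
  bg_products <- map(bg$sequence, fragment_ions, charges = product_charges)
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    bg_prec <- precursor_mz(bg$sequence, cand$precursor_charge)
    is_self <- bg$sequence == cand$peptide &
      (is.na(cand$protein) | is.na(bg$parent) |
         (bg$parent == cand$protein &
            (is.na(cand$peptide_start) | is.na(bg$start) |
               bg$start == cand$peptide_start)))
    # Bare-sequence backgrounds carry no identity, so an exact sequence
    # duplicate there is a genuine interferer.
    if (all(is.na(bg$parent))) is_self <- rep(FALSE, nrow(bg))
    hits <- which(!is_self & abs(bg_prec - cand$precursor_mz) <= precursor_tol)
    if (length(hits) == 0) next
    out[[i]] <- map_dfr(hits, function(j) {
      prods <- bg_products[[j]]
      close <- abs(prods$mz - cand$product_mz) <= product_tol
      if (!any(close)) return(NULL)
      tibble(
        candidate_peptide = cand$peptide,
        candidate_annotation = cand$annotation,
        precursor_charge = cand$precursor_charge,
        product_charge = cand$product_charge,
        interferer_peptide = bg$sequence[j],
        interferer_parent = bg$parent[j],
        interferer_annotation = paste0(prods$annotation[close],
                                       ifelse(prods$charge[close] > 1,
                                              paste0("(", prods$charge[close], "+)"),
                                              "")),
        precursor_delta = bg_prec[j] - cand$precursor_mz,
        product_delta = prods$mz[close] - cand$product_mz
      )
    })
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) empty_conflicts() else res
}

empty_conflicts <- function() {
  tibble(
    candidate_peptide = character(), candidate_annotation = character(),
    precursor_charge = integer(), product_charge = integer(),
    interferer_peptide = character(), interferer_parent = character(),
    interferer_annotation = character(),
    precursor_delta = numeric(), product_delta = numeric()
  )
}

# Default transition ranking key (lower is better): y-series first, longer
# fragments first, lower product charge, then product m/z.
default_transition_rank <- function(candidates) {
  with(candidates,
       (series != "y") * 1e6 - fragment_index * 1e3 +
         product_charge * 10 + product_mz * 1e-6)
}

#' Assign quantifier and qualifier roles
#'
#' Removes conflicted candidates, then per peptide promotes the top-ranked
#' remaining transition to quantifier and the next `n_qualifiers` to
#' qualifiers. The default ranking prefers the y series, then longer
#' fragments, then lower product charge, with ties broken by product m/z.
#' Peptides left with no conflict-free candidate are reported in the
#' `failures` attribute (and a message), not raised.
#'
#' @param candidates Transition tibble from [enumerate_transitions()].
#' @param n_qualifiers Qualifier transitions to keep per peptide (default 3,
#'   giving the common 4-products-monitored pattern).
#' @param ranking Optional hook `function(candidates) -> numeric` returning a
#'   rank key (lower is better) to override the default ordering.
#' @param conflicts Conflict tibble from [detect_isobaric_conflicts()]
#'   (default none).
#' @return Finalized transition tibble (`role` in quantifier/qualifier), with
#'   attribute `failures` listing peptides that could not be designed.
#' @export
finalize_roles <- function(candidates, n_qualifiers = 3L, ranking = NULL,
                           conflicts = NULL) {
  ranking <- ranking %||% default_transition_rank
  ok <- candidates
  if (!is.null(conflicts) && nrow(conflicts) > 0) {
    ok <- anti_join(candidates, conflicts,
                    by = c("peptide" = "candidate_peptide",
                           "annotation" = "candidate_annotation",
                           "precursor_charge", "product_charge"))
  }
  failures <- setdiff(unique(candidates$peptide), unique(ok$peptide))
  if (length(failures) > 0) {
    inform(sprintf("no conflict-free transition for: %s",
                   paste(failures, collapse = ", ")))
  }
  if (nrow(ok) == 0) {
    return(structure(ok, failures = failures))
  }
  final <- ok |>
    mutate(.key = ranking(ok)) |>
    group_by(.data$peptide) |>
    arrange(.data$.key, .by_group = TRUE) |>
    mutate(role = c("quantifier", rep("qualifier", n()))[seq_len(n())]) |>
    filter(row_number() <= n_qualifiers + 1) |>
    ungroup() |>
    select(-".key")
  structure(final, failures = failures)
}

TRANSITION_COLUMNS <- c("protein", "peptide", "precursor_mz",
                        "precursor_charge", "product_mz",
                        "product_annotation", "product_charge",
                        "collision_energy", "role")

#' Export a finalized transition list
#'
#' Writes the fixed-dialect CSV (columns `protein`, `peptide`,
#' `precursor_mz`, `precursor_charge`, `product_mz`, `product_annotation`,
#' `product_charge`, `collision_energy`, `role`; m/z at 4 dp) that
#' [read_transition_list()] reads back.
#'
#' @param transitions Finalized transition tibble ([finalize_roles()]).
#' @param path Output CSV path.
#' @param collision_energy Optional numeric vector (recycled) of
#'   instrument-specific collision energies in eV; transitions carry no CE
#'   prediction.
#' @return `path`, invisibly.
#' @export
export_transition_list <- function(transitions, path, collision_energy = NA_real_) {
  out <- as_tibble(transitions)
  if (!"product_annotation" %in% names(out)) {
    out$product_annotation <- out$annotation
  }
  if (!"collision_energy" %in% names(out)) {
    out$collision_energy <- collision_energy
  }
  out <- out |>
    mutate(precursor_mz = round(.data$precursor_mz, 4),
           product_mz = round(.data$product_mz, 4)) |>
    select(dplyr::all_of(TRANSITION_COLUMNS))
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) abort(sprintf("failed to write '%s': %s", path,
                                      conditionMessage(e)))
  )
  invisible(path)
}

#' Read a transition list written by [export_transition_list()]
#'
#' @param path CSV path.
#' @return Transition tibble in the export dialect.
#' @export
read_transition_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("transition list not found: %s", path))
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(TRANSITION_COLUMNS, names(tr))
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing transition columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  tr
}
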