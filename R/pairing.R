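# Homology-anchored surrogate peptide pairing: global protein alignment,
# species-specificity screening, positional mapping of tryptic peptides
# between species, and similarity scoring.

#' Global pairwise protein alignment
#'
#' End-gap-penalized (Needleman-Wunsch-type) global alignment via
#' `Biostrings::pairwiseAlignment`, defaulting to BLOSUM62 with gap open 10
#' and gap extension 0.5. "Similar" positions are aligned non-identical
#' columns with a positive substitution score.
#'
#' @param a,b Protein sequences (strings) or one-row record tibbles.
#' @param substitution_matrix Name of a Biostrings scoring matrix or a matrix.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return A `protein_alignment` object: list with `aligned_a`, `aligned_b`,
#'   `score`, `alignment_length`, `identical_positions`, `similar_positions`,
#'   `identity_fraction` and `column_map` (for each ungapped position of `a`,
#'   the aligned ungapped position of `b`, or `NA`).
#' @examples
#' align_global("TSALSAK", "TSALSDK")
#' @export
align_global <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  a <- if (is.data.frame(a)) a$sequence[[1]] else a
  b <- if (is.data.frame(b)) b$sequence[[1]] else b
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  check_standard_residues(c(a, b), what = "protein")
  submat <- substitution_matrix
  if (is.character(submat)) {
    submat <- get(data(list = substitution_matrix,
                       package = "Biostrings", envir = environment()))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  ga <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- ga != "-" & gb != "-"
  identical_pos <- sum(both & ga == gb)
  simscore <- rep(0, length(ga))
  simscore[both] <- submat[cbind(ga[both], gb[both])]
  similar_pos <- sum(both & ga != gb & simscore > 0)
  # aligned column index -> ungapped position in b, then restrict to a's rows
  b_pos <- cumsum(gb != "-")
  column_map <- ifelse(gb != "-", b_pos, NA_integer_)[ga != "-"]
  out <- list(
    a = a, b = b,
    aligned_a = paste(ga, collapse = ""),
    aligned_b = paste(gb, collapse = ""),
    score = Biostrings::score(pa),
    alignment_length = length(ga),
    identical_positions = identical_pos,
    similar_positions = similar_pos,
    identity_fraction = identical_pos / length(ga),
    column_map = as.integer(column_map),
    substitution_matrix = submat,
    gap_open = gap_open, gap_extend = gap_extend
  )
  structure(out, class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf(
    "<protein_alignment> length %d, score %.1f\n  identical %d (%.1f%%), similar %d\n",
    x$alignment_length, x$score, x$identical_positions,
    100 * x$identity_fraction, x$similar_positions
  ))
  invisible(x)
}

#' Species-specificity verdict for a peptide
#'
#' A peptide is species specific iff its sequence occurs exactly once in its
#' own proteome digest (proteotypic) and never in the other species' digest.
#'
#' @param peptide Peptide sequence (string) or a one-row digest tibble.
#' @param own_index,other_index `peptide_index` objects built from full
#'   digests of the respective proteomes (at the missed-cleavage settings
#'   used for design).
#' @return One-row tibble: `sequence`, `species_specific`, `n_own`,
#'   `n_other`, and list columns `own_hits`, `other_hits` with all offending
#'   hits.
#' @export
check_species_specificity <- function(peptide, own_index, other_index) {
  seq <- if (is.data.frame(peptide)) peptide$sequence[[1]] else peptide
  own <- lookup_peptide(own_index, seq)
  other <- lookup_peptide(other_index, seq)
  tibble(
    sequence = seq,
    species_specific = nrow(own) == 1 && nrow(other) == 0,
    n_own = nrow(own),
    n_other = nrow(other),
    own_hits = list(own),
    other_hits = list(other)
  )
}

# Count of differing columns (mismatches plus gapped columns) after aligning
# the two peptide sequences themselves.
peptide_substitution_count <- function(a, b, alignment_params = list()) {
  al <- do.call(align_global, c(list(a = a, b = b), alignment_params))
  ga <- strsplit(al$aligned_a, "")[[1]]
  gb <- strsplit(al$aligned_b, "")[[1]]
  sum(ga != gb)
}

#' Map homologous tryptic peptides between two aligned proteins
#'
#' For each target peptide, every surrogate peptide whose aligned span covers
#' at least `overlap_threshold` of the target positions is emitted as an
#' unscored candidate pair; candidates below the threshold (but with nonzero
#' overlap) are flagged `low_homology`. A target peptide aligned entirely
#' opposite a gap yields no candidate.
#'
#' @param target_digest,surrogate_digest Digest tibbles of the two proteins
#'   the alignment was computed from.
#' @param alignment A `protein_alignment` of target vs surrogate protein.
#' @param overlap_threshold Minimum span overlap fraction (default 0.5).
#' @return Tibble of candidate pairs: target/surrogate sequence and span,
#'   `span_overlap_fraction`, `length_delta`, `gravy_delta`,
#'   `substitution_count`, `exclusion_flags` (list of character vectors).
#' @export
map_homologous_peptides <- function(target_digest, surrogate_digest, alignment,
                                    overlap_threshold = 0.5) {
  stopifnot(inherits(alignment, "protein_alignment"))
  check_digest_matches <- function(dg, protein, label) {
    ok <- substring(protein, dg$start, dg$end) == dg$sequence
    if (!all(ok)) {
      abort(sprintf("%s digest does not derive from the aligned %s protein",
                    label, label))
    }
  }
  check_digest_matches(target_digest, alignment$a, "target")
  check_digest_matches(surrogate_digest, alignment$b, "surrogate")
  cmap <- alignment$column_map
  pairs <- map_dfr(seq_len(nrow(target_digest)), function(i) {
    t <- target_digest[i, ]
    partners <- cmap[t$start:t$end]
    map_dfr(seq_len(nrow(surrogate_digest)), function(j) {
      s <- surrogate_digest[j, ]
      inside <- !is.na(partners) & partners >= s$start & partners <= s$end
      frac <- mean(inside)
      if (frac == 0) return(NULL)
      tibble(
        target_sequence = t$sequence, target_parent = t$parent,
        target_start = t$start, target_end = t$end,
        surrogate_sequence = s$sequence, surrogate_parent = s$parent,
        surrogate_start = s$start, surrogate_end = s$end,
        span_overlap_fraction = frac,
        length_delta = nchar(s$sequence) - nchar(t$sequence),
        gravy_delta = abs(gravy(t$sequence) - gravy(s$sequence)),
        substitution_count = peptide_substitution_count(
          t$sequence, s$sequence,
          list(substitution_matrix = alignment$substitution_matrix,
               gap_open = alignment$gap_open, gap_extend = alignment$gap_extend)
        )
      )
    })
  })
  if (nrow(pairs) == 0) return(mutate(pairs, exclusion_flags = list()))
  pairs$exclusion_flags <- map(pairs$span_overlap_fraction, function(f) {
    if (f < overlap_threshold) "low_homology" else character()
  })
  pairs
}

#' Score candidate surrogate pairs
#'
#' `score = w_len * |length_delta| + w_gravy * gravy_delta +
#' w_sub * substitution_count`; lower is better. Pairs carrying exclusion
#' flags must not be scored (contract error).
#'
#' @param pairs Candidate tibble from [map_homologous_peptides()].
#' @param w_len,w_gravy,w_sub Similarity weights (defaults 1, 1, 0.25).
#' @return `pairs` with a `score` column, ranked ascending with deterministic
#'   tie-break by `(substitution_count, surrogate_start)`.
#' @export
score_pairs <- function(pairs, w_len = 1, w_gravy = 1, w_sub = 0.25) {
  if (nrow(pairs) > 0 && any(lengths(pairs$exclusion_flags %||% list()) > 0)) {
    abort("cannot score pairs carrying exclusion flags")
  }
  pairs |>
    mutate(score = w_len * abs(.data$length_delta) +
             w_gravy * .data$gravy_delta +
             w_sub * .data$substitution_count) |>
    arrange(.data$score, .data$substitution_count, .data$surrogate_start)
}

#' Design a surrogate-IS peptide panel
#'
#' Full selection pipeline for each panel entry: digest target and surrogate
#' proteins; screen every peptide for species specificity against the full
#' digests of both species' panel proteomes; map homology-anchored candidate
#' pairs through the global protein alignment; screen both members of each
#' pair for isobaric conflicts within the panel background (a pair is
#' excluded only if a member has no conflict-free transition); and score and
#' rank the surviving pairs. Every excluded candidate is retained in the
#' output with its flags and an infinite score, so `score` is finite iff
#' `exclusion_flags` is empty. The result is deterministic given inputs and
#' config.
#'
#' @param panel A validated `panel_definition` ([define_panel()]).
#' @param config A [run_config()] list (digestion bounds, alignment scoring,
#'   overlap threshold, scoring weights, transition settings, tolerances).
#' @param instrument_response Optional ranking hook, a
#'   `function(pairs) -> numeric` returning an additive score adjustment per
#'   row (criterion "(iii)"; default none — empirical response ranking is
#'   instrument-specific).
#' @return A `panel_design` object: list with `pairs` (all candidates, ranked
#'   within each target peptide), `specificity` (per-peptide verdicts),
#'   `alignments` (per-entry summary) and the effective `config`.
#' @export
design_panel <- function(panel, config = run_config(),
                         instrument_response = NULL) {
  msgs <- validate_panel(panel)
  if (length(msgs) > 0) {
    abort(paste(c("panel failed validation:", msgs), collapse = "\n  "))
  }
  dg <- config$digestion
  al <- config$alignment
  pr <- config$pairing
  digest_rec <- function(rec) {
    digest(rec, max_missed = dg$max_missed, min_len = dg$min_len,
           max_len = dg$max_len)
  }
  target_digests <- map(panel$target, digest_rec)
  surrogate_digests <- map(panel$surrogate, digest_rec)
  own_index <- peptide_index(bind_rows(target_digests))
  other_index <- peptide_index(bind_rows(surrogate_digests))
  background <- bind_rows(bind_rows(target_digests), bind_rows(surrogate_digests))

  specificity <- bind_rows(
    map_dfr(seq_len(nrow(own_index)), function(i) {
      mutate(check_species_specificity(own_index$sequence[i], own_index,
                                       other_index),
             proteome = "target")
    }) |> distinct(.data$sequence, .keep_all = TRUE),
    map_dfr(seq_len(nrow(other_index)), function(i) {
      mutate(check_species_specificity(other_index$sequence[i], other_index,
                                       own_index),
             proteome = "surrogate")
    }) |> distinct(.data$sequence, .keep_all = TRUE)
  )
  spec_ok <- setNames(specificity$species_specific, specificity$sequence)

  # Isobaric screening: a peptide is viable if at least one candidate
  # transition survives conflict detection against the panel background.
  tr <- config$transitions
  has_clean_transition <- function(pep_row) {
    cands <- enumerate_transitions(
      pep_row, precursor_charges = tr$precursor_charges,
      series = tr$series, product_charges = tr$product_charges
    )
    conf <- detect_isobaric_conflicts(
      cands, background, precursor_tol = tr$precursor_tol,
      product_tol = tr$product_tol
    )
    nrow(anti_join(cands, conf,
                   by = c("peptide" = "candidate_peptide",
                          "annotation" = "candidate_annotation",
                          "precursor_charge", "product_charge"))) > 0
  }

  entries <- map_dfr(seq_len(nrow(panel)), function(k) {
    alignment <- align_global(panel$target[[k]], panel$surrogate[[k]],
                              substitution_matrix = al$substitution_matrix,
                              gap_open = al$gap_open, gap_extend = al$gap_extend)
    pairs <- map_homologous_peptides(target_digests[[k]], surrogate_digests[[k]],
                                     alignment,
                                     overlap_threshold = pr$overlap_threshold)
    if (nrow(pairs) == 0) return(NULL)
    pairs$entry <- panel$entry[[k]]
    iso_cache <- new.env(parent = emptyenv())
    iso_ok <- function(dgst, seq) {
      if (is.null(iso_cache[[seq]])) {
        row <- dgst[dgst$sequence == seq, ][1, ]
        iso_cache[[seq]] <- has_clean_transition(row)
      }
      iso_cache[[seq]]
    }
    pairs$exclusion_flags <- pmap(
      list(pairs$target_sequence, pairs$surrogate_sequence, pairs$exclusion_flags),
      function(ts, ss, flags) {
        if (!spec_ok[[ts]] || !spec_ok[[ss]]) {
          flags <- c(flags, "not_species_specific")
        }
        if (!iso_ok(target_digests[[k]], ts) ||
            !iso_ok(surrogate_digests[[k]], ss)) {
          flags <- c(flags, "isobaric_conflict")
        }
        flags
      }
    )
    pairs
  })

  if (nrow(entries) > 0) {
    clean <- lengths(entries$exclusion_flags) == 0
    w <- pr$weights
    scored <- entries
    scored$score <- w$w_len * abs(entries$length_delta) +
      w$w_gravy * entries$gravy_delta + w$w_sub * entries$substitution_count
    if (!is.null(instrument_response)) {
      scored$score <- scored$score + instrument_response(scored)
    }
    scored$score[!clean] <- Inf
    entries <- scored |>
      group_by(.data$entry, .data$target_sequence) |>
      arrange(.data$score, .data$substitution_count, .data$surrogate_start,
              .by_group = TRUE) |>
      mutate(rank = ifelse(is.finite(.data$score),
                           cumsum(is.finite(.data$score)), NA_integer_)) |>
      ungroup()
  }

  alignments <- map_dfr(seq_len(nrow(panel)), function(k) {
    alx <- align_global(panel$target[[k]], panel$surrogate[[k]],
                        substitution_matrix = al$substitution_matrix,
                        gap_open = al$gap_open, gap_extend = al$gap_extend)
    tibble(entry = panel$entry[[k]],
           alignment_length = alx$alignment_length,
           identical_positions = alx$identical_positions,
           similar_positions = alx$similar_positions,
           identity_fraction = alx$identity_fraction)
  })

  structure(
    list(pairs = entries, specificity = specificity, alignments = alignments,
         background = background, config = config),
    class = "panel_design"
  )
}

#' @export
print.panel_design <- function(x, ...) {
  clean <- sum(lengths(x$pairs$exclusion_flags) == 0)
  cat(sprintf("<panel_design> %d candidate pair(s), %d accepted, %d excluded\n",
              nrow(x$pairs), clean, nrow(x$pairs) - clean))
  invisible(x)
}

#' @rdname design_panel
#' @param x A `panel_design`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.panel_design <- function(x, ...) {
  x$pairs |>
    mutate(excluded = lengths(.data$exclusion_flags) > 0,
           flags = map_chr(.data$exclusion_flags, paste, collapse = ";"))
}
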