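# In-silico tryptic digestion. Classic rule: cleave C-terminal to K or R
# except when the next residue is P; the protein C-terminus always closes a
# peptide.

# 1-based positions after which trypsin cleaves (protein end excluded).
cleavage_sites <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2) return(integer())
  which(res[-n] %in% c("K", "R") & res[-1] != "P")
}

digest_one <- function(identifier, sequence, species, max_missed, min_len, max_len) {
  n <- nchar(sequence)
  bounds <- c(0L, cleavage_sites(sequence), n)
  bounds <- unique(bounds)
  nb <- length(bounds)
  out <- vector("list", nb - 1)
  for (j in seq_len(nb - 1)) {
    last <- min(nb, j + 1 + max_missed)
    ends <- bounds[seq(j + 1, last)]
    start <- bounds[j] + 1L
    len <- ends - start + 1L
    keep <- len >= min_len & len <= max_len
    if (!any(keep)) next
    out[[j]] <- tibble(
      parent = identifier,
      species = species,
      sequence = substring(sequence, start, ends[keep]),
      start = start,
      end = ends[keep],
      missed_cleavages = (seq(j + 1, last) - j - 1L)[keep]
    )
  }
  bind_rows(out)
}

#' Tryptic digestion of protein records
#'
#' Cleaves after K/R unless followed by P, emitting every peptide with
#' `0..max_missed` missed cleavages whose length lies in
#' `[min_len, max_len]`. Positions are 1-based inclusive spans in the parent
#' sequence; output is ordered by parent, start, then missed cleavages.
#'
#' @param proteins Protein-record tibble ([read_fasta()]) or a single
#'   sequence string.
#' @param max_missed Maximum internal missed cleavage sites (default 0, i.e.
#'   fully cleaved peptides only).
#' @param min_len,max_len Peptide length bounds (defaults 5 and 30; typical
#'   quantotypic peptides fall well inside).
#' @return Tibble with columns `parent`, `species`, `sequence`, `start`,
#'   `end`, `missed_cleavages`.
#' @examples
#' digest("TSALSAKVLEPTLK", min_len = 1)
#' @export
digest <- function(proteins, max_missed = 0L, min_len = 5L, max_len = 30L) {
  if (max_missed < 0) abort("`max_missed` must be >= 0")
  if (min_len < 1 || min_len > max_len) {
    abort("length bounds must satisfy 1 <= min_len <= max_len")
  }
  if (is.character(proteins)) {
    proteins <- tibble(identifier = paste0("protein_", seq_along(proteins)),
                       species = NA_character_, sequence = proteins)
  }
  check_standard_residues(proteins$sequence, what = "protein")
  pmap(
    list(proteins$identifier, proteins$sequence,
         proteins$species %||% NA_character_),
    digest_one,
    max_missed = max_missed, min_len = min_len, max_len = max_len
  ) |>
    bind_rows() |>
    arrange(match(.data$parent, proteins$identifier), .data$start,
            .data$missed_cleavages)
}

#' Index digested peptides by sequence
#'
#' Builds a lookup of every occurrence of each peptide sequence across one or
#' more digests, supporting proteotypicity and cross-species specificity
#' checks.
#'
#' @param peptides Digest tibble from [digest()] (possibly several bound
#'   together).
#' @return A `peptide_index` tibble with columns `sequence`, `parent`,
#'   `start`, `end`.
#' @export
peptide_index <- function(peptides) {
  idx <- as_tibble(peptides) |>
    distinct(.data$sequence, .data$parent, .data$start, .data$end) |>
    arrange(.data$sequence, .data$parent, .data$start)
  class(idx) <- c("peptide_index", class(idx))
  idx
}

#' Look up a peptide sequence in an index
#'
#' @param index A `peptide_index` from [peptide_index()].
#' @param sequence Peptide sequence to look up.
#' @return Tibble of hits `(parent, start, end)`; zero rows if absent.
#' @export
lookup_peptide <- function(index, sequence) {
  as_tibble(index) |>
    filter(.data$sequence == !!sequence) |>
    select("parent", "start", "end")
}
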