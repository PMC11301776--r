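# Protein sequence input. FASTA parsing is delegated to Biostrings; a light
# pre-scan supplies the line-number diagnostics Biostrings does not report.

# Diagnose structural FASTA problems with line numbers before parsing.
prescan_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) return(invisible(0L))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(sprintf("%s: line %d: expected a '>' header before sequence data",
                  path, nonblank[1]))
  }
  headers <- which(startsWith(trimws(lines), ">"))
  for (h in headers) {
    id <- strsplit(sub("^\\s*>", "", trimws(lines[h])), "\\s+")[[1]][1]
    if (is.na(id) || id == "") {
      abort(sprintf("%s: line %d: malformed header (empty identifier)", path, h))
    }
    body <- lines[seq(h + 1, length.out = max(0, min(c(headers[headers > h] - 1,
                                                       length(lines))) - h))]
    if (all(trimws(body) == "") || length(body) == 0) {
      abort(sprintf("%s: line %d: entry '%s' has an empty sequence", path, h, id))
    }
  }
  invisible(length(headers))
}

#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a tibble of protein records. Everything after `>`
#' up to the first whitespace is the identifier; the remainder of the header
#' is the description. Sequence bodies are uppercased and whitespace is
#' stripped, so line-wrapping and case do not affect the result.
#'
#' In strict mode (default) any residue outside the 20 standard one-letter
#' codes is an error naming the record and position. In lenient mode such
#' records are kept but flagged `valid = FALSE` (they are never given a
#' mass).
#'
#' @param path Path to a FASTA file.
#' @param species Free-text species tag attached to every record (e.g.
#'   `"human"`, `"bovine"`).
#' @param strict Reject non-standard residues (`TRUE`, default) or flag them.
#' @return A tibble with columns `identifier`, `species`, `sequence`,
#'   `description`, `valid`; one row per FASTA entry, order preserved.
#' @examples
#' fa <- system.file("extdata", "human_panel_synthetic.fasta", package = "surropep")
#' read_fasta(fa, species = "human")
#' @export
read_fasta <- function(path, species = NA_character_, strict = TRUE) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  n <- prescan_fasta(path)
  empty <- tibble(
    identifier = character(), species = character(), sequence = character(),
    description = character(), valid = logical()
  )
  if (n == 0L) return(empty)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  records <- tibble(
    identifier = vapply(strsplit(headers, "\\s+"), `[`, character(1), 1),
    species = species,
    sequence = unname(toupper(gsub("\\s", "", as.character(set)))),
    description = trimws(sub("^\\S+\\s*", "", headers))
  )
  bad <- map(strsplit(records$sequence, ""),
             function(r) which(!r %in% STANDARD_RESIDUES))
  records$valid <- lengths(bad) == 0
  if (strict && any(!records$valid)) {
    i <- which(!records$valid)[1]
    res <- strsplit(records$sequence[i], "")[[1]]
    abort(sprintf(
      "record '%s': non-standard residue '%s' at position %d (strict mode)",
      records$identifier[i], res[bad[[i]][1]], bad[[i]][1]
    ))
  }
  records
}

#' Write protein records to FASTA
#'
#' @param records Tibble of protein records as returned by [read_fasta()].
#' @param path Output path.
#' @param width Sequence line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  desc <- records$description %||% rep("", nrow(records))
  headers <- ifelse(is.na(desc) | desc == "", records$identifier,
                    paste(records$identifier, desc))
  set <- Biostrings::BStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Define a target/surrogate assay panel
#'
#' Pairs each target-species protein with its surrogate-species homolog, by
#' row order. The panel is the input to [design_panel()].
#'
#' @param targets,surrogates Protein-record tibbles ([read_fasta()]) of equal
#'   row count, with differing species tags.
#' @return A `panel_definition` tibble with columns `entry`, `target`,
#'   `surrogate` (one-row record tibbles in list columns).
#' @export
define_panel <- function(targets, surrogates) {
  if (nrow(targets) != nrow(surrogates)) {
    abort("`targets` and `surrogates` must have the same number of records")
  }
  panel <- tibble(
    entry = targets$identifier,
    target = map(seq_len(nrow(targets)), ~ targets[.x, ]),
    surrogate = map(seq_len(nrow(surrogates)), ~ surrogates[.x, ])
  )
  class(panel) <- c("panel_definition", class(panel))
  panel
}

#' Validate a panel definition
#'
#' Checks panel invariants and returns diagnostics instead of raising:
#' each entry must pair exactly two differing species tags, and sequences
#' must be non-empty over the standard residue alphabet.
#'
#' @param panel A `panel_definition` from [define_panel()].
#' @return Character vector of messages; empty iff all invariants hold.
#' @export
validate_panel <- function(panel) {
  msgs <- character()
  for (i in seq_len(nrow(panel))) {
    tgt <- panel$target[[i]]
    sur <- panel$surrogate[[i]]
    lab <- panel$entry[[i]]
    if (identical(tgt$species, sur$species)) {
      msgs <- c(msgs, sprintf(
        "entry '%s': target and surrogate share species tag '%s'", lab, tgt$species
      ))
    }
    for (rec in list(tgt, sur)) {
      if (is.na(rec$sequence) || nchar(rec$sequence) == 0) {
        msgs <- c(msgs, sprintf("entry '%s': record '%s' has an empty sequence",
                                lab, rec$identifier))
        next
      }
      res <- strsplit(rec$sequence, "")[[1]]
      bad <- which(!res %in% STANDARD_RESIDUES)
      if (length(bad) > 0) {
        msgs <- c(msgs, sprintf(
          "entry '%s': record '%s' has non-standard residue '%s' at position %d",
          lab, rec$identifier, res[bad[1]], bad[1]
        ))
      }
    }
  }
  msgs
}
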