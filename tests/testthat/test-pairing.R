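test_that("global alignment handles identity, single mismatch, and gap-free mapping", {
  al <- align_global("TSALSAK", "TSALSAK")
  expect_equal(al$identity_fraction, 1)
  expect_equal(al$identical_positions, 7)
  expect_equal(al$column_map, 1:7)

  al2 <- align_global("TSALSAK", "TSALSDK")
  expect_equal(al2$identical_positions, 6)
  expect_equal(al2$alignment_length, 7)
  expect_lt(al2$identity_fraction, 1)

  # identity_fraction == 1 iff sequences equal
  set.seed(31)
  for (p in random_peptides(15, 6, 12)) {
    q <- p
    substr(q, 2, 2) <- if (substr(p, 2, 2) == "A") "G" else "A"
    expect_lt(align_global(p, q)$identity_fraction, 1)
    expect_equal(align_global(p, p)$identity_fraction, 1)
  }
})

test_that("alignment score equals the exhaustive gapped-alignment oracle", {
  submat <- as.matrix(
    get(data("BLOSUM62", package = "Biostrings", envir = environment()))
  )
  alph <- c("A", "G", "K", "P")
  seqs2 <- c(alph, apply(expand.grid(alph, alph), 1, paste, collapse = ""))
  for (a in seqs2) {
    for (b in seqs2) {
      expect_equal(align_global(a, b)$score,
                   oracle_align_score(a, b, submat),
                   tolerance = 1e-9,
                   label = sprintf("score(%s, %s)", a, b))
    }
  }
  set.seed(32)
  for (k in 1:40) {
    a <- paste(sample(alph, sample(3:4, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alph, sample(3:4, 1), replace = TRUE), collapse = "")
    expect_equal(align_global(a, b)$score, oracle_align_score(a, b, submat),
                 tolerance = 1e-9)
  }
})

test_that("species specificity requires proteotypic-own and absent-other", {
  own <- peptide_index(digest("AAAKTSALSAKGGGR", min_len = 1))
  other <- peptide_index(digest("AAAKTSALSDKGGGR", min_len = 1))
  v <- check_species_specificity("TSALSAK", own, other)
  expect_true(v$species_specific)
  expect_equal(v$n_own, 1)
  expect_equal(v$n_other, 0)

  # present in both -> not specific, both hit lists reported
  shared_other <- peptide_index(digest("CCCRTSALSAKR", min_len = 1))
  v2 <- check_species_specificity("TSALSAK", own, shared_other)
  expect_false(v2$species_specific)
  expect_equal(nrow(v2$other_hits[[1]]), 1)

  # duplicated within own proteome -> not proteotypic
  dup <- peptide_index(digest(
    tibble::tibble(identifier = c("p1", "p2"), species = "h",
                   sequence = c("AAAKTSALSAKGGGR", "CCCRTSALSAKR")),
    min_len = 1
  ))
  v3 <- check_species_specificity("TSALSAK", dup, other)
  expect_false(v3$species_specific)
  expect_equal(v3$n_own, 2)
})

test_that("homology mapping emits pairs by aligned span overlap", {
  # gap-free two-peptide proteins: overlap 1 at corresponding positions
  t_seq <- "LVNEVTEFAKQTALVELVK"
  s_seq <- "LVNELTEFAKQTALVELLK"
  al <- align_global(t_seq, s_seq)
  td <- digest(t_seq)
  sd_ <- digest(s_seq)
  pairs <- map_homologous_peptides(td, sd_, al)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$span_overlap_fraction, c(1, 1))
  expect_equal(pairs$target_sequence, c("LVNEVTEFAK", "QTALVELVK"))
  expect_equal(pairs$surrogate_sequence, c("LVNELTEFAK", "QTALVELLK"))
  expect_equal(pairs$length_delta, c(0L, 0L))
  expect_equal(pairs$substitution_count, c(1L, 1L))

  # insertion in the surrogate: overlap fractions equal a counting oracle
  t2 <- "TSALSAKVLEPTLK"
  s2 <- "TSALSAKAAAVLEPTLK"
  al2 <- align_global(t2, s2)
  p2 <- map_homologous_peptides(digest(t2), digest(s2), al2)
  sd2 <- digest(s2)
  for (i in seq_len(nrow(p2))) {
    partners <- al2$column_map[p2$target_start[i]:p2$target_end[i]]
    srow <- sd2[sd2$sequence == p2$surrogate_sequence[i], ]
    frac <- mean(!is.na(partners) & partners >= srow$start &
                   partners <= srow$end)
    expect_equal(p2$span_overlap_fraction[i], frac)
  }
  expect_true("VLEPTLK" %in% p2$target_sequence)

  # digest/alignment mismatch is a contract error
  expect_error(map_homologous_peptides(digest("AAAKAAAR", min_len = 1), sd_, al),
               "does not derive")
})

test_that("pair scoring is the weighted sum of similarity deltas", {
  al <- align_global("LVNEVTEFAK", "LVNELTEFAK")
  pairs <- map_homologous_peptides(digest("LVNEVTEFAK"), digest("LVNELTEFAK"), al)
  scored <- score_pairs(pairs)
  # |gravy delta| = |0.17 - 0.13| = 0.04; one substitution at w_sub 0.25
  expect_equal(scored$score, 0.29, tolerance = 1e-9)

  same <- pairs
  same$gravy_delta <- 0
  same$substitution_count <- 0L
  same$length_delta <- 0L
  expect_equal(score_pairs(same)$score, 0)

  # monotonic in each delta
  set.seed(33)
  for (k in 1:20) {
    base <- same
    base$gravy_delta <- runif(1, 0, 1)
    base$length_delta <- sample(0:3, 1)
    base$substitution_count <- sample(0:4, 1)
    s0 <- score_pairs(base)$score
    up <- base
    up$gravy_delta <- base$gravy_delta + 0.1
    expect_gt(score_pairs(up)$score, s0)
    up <- base
    up$substitution_count <- base$substitution_count + 1L
    expect_gt(score_pairs(up)$score, s0)
    up <- base
    up$length_delta <- base$length_delta + 1L
    expect_gt(score_pairs(up)$score, s0)
  }

  flagged <- pairs
  flagged$exclusion_flags <- list("low_homology")
  expect_error(score_pairs(flagged), "exclusion flags")
})

test_that("design_panel excludes total homology and ranks the engineered survivor", {
  # identical proteomes: every candidate not species specific, no finite score
  rec <- function(id, sp, seq) tibble::tibble(identifier = id, species = sp,
                                              sequence = seq, description = "",
                                              valid = TRUE)
  same <- design_panel(define_panel(rec("t", "human", "AAAAAKLVNEVTEFAK"),
                                    rec("s", "bovine", "AAAAAKLVNEVTEFAK")))
  expect_true(all(lengths(same$pairs$exclusion_flags) > 0))
  expect_true(all(purrr::map_lgl(same$pairs$exclusion_flags,
                                 ~ "not_species_specific" %in% .x)))
  expect_false(any(is.finite(same$pairs$score)))

  # shared AAAAAK fails specificity; homologous pair survives and ranks first
  d <- design_panel(define_panel(rec("t", "human", "AAAAAKLVNEVTEFAK"),
                                 rec("s", "bovine", "AAAAAKLVNELTEFAK")))
  clean <- d$pairs[lengths(d$pairs$exclusion_flags) == 0, ]
  expect_equal(nrow(clean), 1)
  expect_equal(clean$target_sequence, "LVNEVTEFAK")
  expect_equal(clean$surrogate_sequence, "LVNELTEFAK")
  expect_equal(clean$rank, 1L)
  excluded <- d$pairs[lengths(d$pairs$exclusion_flags) > 0, ]
  expect_gte(nrow(excluded), 1)
  expect_true("AAAAAK" %in% excluded$target_sequence)
})

test_that("no accepted pair ever occurs in the other species' digest, and roles transpose", {
  fa <- panel_fasta_paths()
  hu <- read_fasta(fa[["human"]], "human")
  bo <- read_fasta(fa[["bovine"]], "bovine")
  d <- design_panel(define_panel(hu, bo))
  clean <- d$pairs[lengths(d$pairs$exclusion_flags) == 0, ]
  bovine_index <- peptide_index(digest(bo))
  human_index <- peptide_index(digest(hu))
  for (p in clean$target_sequence) {
    expect_equal(nrow(lookup_peptide(bovine_index, p)), 0)
  }
  for (p in clean$surrogate_sequence) {
    expect_equal(nrow(lookup_peptide(human_index, p)), 0)
  }

  # swapping roles transposes the accepted pair set on this gap-free panel
  d_swap <- design_panel(define_panel(bo, hu))
  clean_swap <- d_swap$pairs[lengths(d_swap$pairs$exclusion_flags) == 0, ]
  expect_setequal(
    paste(clean$target_sequence, clean$surrogate_sequence),
    paste(clean_swap$surrogate_sequence, clean_swap$target_sequence)
  )
})
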