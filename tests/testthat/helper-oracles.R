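# Independent oracles and fixture generators. Every oracle here is written
# against the definitions directly (frozen constants, exhaustive enumeration,
# normal equations) and never calls the code path it checks.

# Frozen monoisotopic residue masses, independent copy for oracle use.
ORACLE_MASSES <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764, V = 99.068414,
  T = 101.047678, C = 103.009185, L = 113.084064, I = 113.084064,
  N = 114.042927, D = 115.026943, Q = 128.058578, K = 128.094963,
  E = 129.042593, M = 131.040485, H = 137.058912, F = 147.068414,
  R = 156.101111, Y = 163.063329, W = 186.079313
)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276

oracle_mass <- function(seq) {
  sum(ORACLE_MASSES[strsplit(seq, "")[[1]]]) + ORACLE_WATER
}

oracle_mz <- function(seq, z) (oracle_mass(seq) + z * ORACLE_PROTON) / z

random_peptides <- function(n, min_len = 5, max_len = 20,
                            alphabet = names(ORACLE_MASSES)) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

random_proteins <- function(n, len,
                            alphabet = names(ORACLE_MASSES)) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Exhaustive digestion oracle: every substring bounded by valid cleavage
# sites (or the termini) with at most max_missed internal sites.
oracle_digest <- function(seq, max_missed, min_len, max_len) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  is_site <- function(i) {
    i >= 1 && i < n && res[i] %in% c("K", "R") && res[i + 1] != "P"
  }
  out <- list()
  for (s in 1:n) {
    for (e in s:n) {
      len <- e - s + 1
      if (len < min_len || len > max_len) next
      if (s != 1 && !is_site(s - 1)) next
      if (e != n && !is_site(e)) next
      internal <- sum(vapply(s:(e - 1), is_site, logical(1)))
      if (e == s) internal <- 0
      if (internal > max_missed) next
      out[[length(out) + 1]] <- data.frame(
        sequence = paste(res[s:e], collapse = ""), start = s, end = e,
        missed_cleavages = internal
      )
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$missed_cleavages), , drop = FALSE]
}

# Brute-force global alignment score: enumerate every gapped alignment of a
# and b, scoring matches by the substitution matrix and each maximal gap run
# as -(gap_open + gap_extend * run_length), end gaps included.
oracle_align_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  best <- -Inf
  # state: (i, j, last_move) with moves D(iag), A(gap in b), B(gap in a)
  rec <- function(i, j, last, acc) {
    if (i > length(ra) && j > length(rb)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= length(ra) && j <= length(rb)) {
      rec(i + 1, j + 1, "D", acc + submat[ra[i], rb[j]])
    }
    if (i <= length(ra)) {
      pen <- if (last == "A") gap_extend else gap_open + gap_extend
      rec(i + 1, j, "A", acc - pen)
    }
    if (j <= length(rb)) {
      pen <- if (last == "B") gap_extend else gap_open + gap_extend
      rec(i, j + 1, "B", acc - pen)
    }
  }
  rec(1, 1, "-", 0)
  best
}

# Quadratic all-pairs isobaric conflict oracle.
oracle_conflicts <- function(candidates, bg_sequences, precursor_tol,
                             product_tol, product_charges = 1L) {
  hits <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    for (bseq in bg_sequences) {
      if (identical(bseq, cand$peptide)) next
      prec <- oracle_mz(bseq, cand$precursor_charge)
      if (abs(prec - cand$precursor_mz) > precursor_tol) next
      res <- strsplit(bseq, "")[[1]]
      nb <- length(res)
      for (series in c("b", "y")) {
        for (idx in 1:(nb - 1)) {
          neutral <- if (series == "y") {
            sum(ORACLE_MASSES[res[(nb - idx + 1):nb]]) + ORACLE_WATER
          } else {
            sum(ORACLE_MASSES[res[1:idx]])
          }
          for (z in product_charges) {
            pm <- (neutral + z * ORACLE_PROTON) / z
            if (abs(pm - cand$product_mz) <= product_tol) {
              hits[[length(hits) + 1]] <- data.frame(
                candidate_peptide = cand$peptide,
                candidate_annotation = cand$annotation,
                interferer_peptide = bseq,
                interferer_series = series, interferer_index = idx,
                product_delta = pm - cand$product_mz
              )
            }
          }
        }
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_rank_sum_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  n_tot <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(n_tot, m)
  u_dist <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_le <- mean(u_dist <= u_obs)
  p_ge <- mean(u_dist >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Weighted least squares via explicit normal equations.
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  c(intercept = beta[1], slope = beta[2])
}

# Per-level recovery/CV/RE recomputation, plain base R.
oracle_verdicts <- function(nominal, ratio, slope, intercept, lloq_level,
                            tol = 15, lloq_tol = 20) {
  bc <- (ratio - intercept) / slope
  levels <- sort(unique(nominal[nominal > 0]))
  do.call(rbind, lapply(levels, function(l) {
    v <- bc[nominal == l]
    rec <- 100 * mean(v) / l
    cv <- 100 * sd(v) / mean(v)
    re <- 100 * (mean(v) - l) / l
    t <- if (!is.na(lloq_level) && l == lloq_level) lloq_tol else tol
    data.frame(level = l, mean_recovery_pct = rec, cv_pct = cv, re_pct = re,
               tolerance_pct = t,
               pass = abs(rec - 100) <= t & cv <= t & abs(re) <= t)
  }))
}

write_temp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}
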