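# Independent oracles used to freeze expected values. These deliberately
# re-derive results by exhaustive enumeration / textbook formulas and share
# no code with the package internals.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Exhaustive enumeration of every (loop_length, loop_start, stem_length)
# triple whose loop contains the site, checking each stem pair explicitly.
# Returns NULL for structure-free sites.
oracle_best_hairpin <- function(seq, site0, min_stem = 3, max_stem = 12,
                                min_loop = 3, max_loop = 11,
                                scores = c(GC = 3, AT = 2, GU = 1),
                                allow_GU = FALSE) {
  ch <- strsplit(chartr("Uu", "Tt", toupper(seq)), "", fixed = TRUE)[[1]]
  n <- length(ch)
  si <- site0 + 1
  pair_score <- function(x, y) {
    if ((x == "G" && y == "C") || (x == "C" && y == "G")) return(scores[["GC"]])
    if ((x == "A" && y == "T") || (x == "T" && y == "A")) return(scores[["AT"]])
    if (allow_GU && ((x == "G" && y == "T") || (x == "T" && y == "G")))
      return(scores[["GU"]])
    0
  }
  best <- NULL
  for (L in min_loop:max_loop) {
    for (ls in 1:(n - L + 1)) {
      if (si < ls || si > ls + L - 1) next
      for (k in min_stem:max_stem) {
        if (ls - k < 1 || ls + L - 1 + k > n) next
        sc <- vapply(0:(k - 1),
                     function(j) pair_score(ch[ls - 1 - j], ch[ls + L + j]),
                     numeric(1))
        if (any(sc == 0)) next
        cand <- list(stem_length = k, loop_length = L, strength = sum(sc),
                     arm5_start = ls - k, site_loop_position = si - ls + 1)
        if (is.null(best) ||
            cand$strength > best$strength ||
            (cand$strength == best$strength &&
             (cand$loop_length < best$loop_length ||
              (cand$loop_length == best$loop_length &&
               cand$arm5_start < best$arm5_start)))) best <- cand
      }
    }
  }
  best
}

# Classical rank-difference formula for Spearman's rho (untied data).
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# Build a tiny RNA-count cohort by hand: `spec` is a list of per-site lists
# with fields seq_id, pos, alt_a3a, cov (per-sample counts applied to every
# sample of the cohort).
toy_rna_counts <- function(spec, n_a3a = 6, n_null = 6) {
  samples <- c(sprintf("A%02d", 1:n_a3a), sprintf("N%02d", 1:n_null))
  rows <- list()
  for (s in spec) {
    for (i in seq_along(samples)) {
      is_a3a <- i <= n_a3a
      alt <- if (is_a3a) s$alt_a3a else s$alt_null
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = samples[i], sequence_id = s$seq_id, position = s$pos,
        ref_reads = s$cov - alt, alt_reads = alt, stringsAsFactors = FALSE)
    }
  }
  list(rna_counts = do.call(rbind, rows),
       cohorts = data.frame(sample_id = samples,
                            cohort = rep(c("A3A+", "APOBEC-"),
                                         c(n_a3a, n_null)),
                            stringsAsFactors = FALSE))
}
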