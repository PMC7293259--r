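#' Editing fraction with Wilson score interval
#'
#' Point estimate `alt/total` and a Wilson 95% (by default) score interval.
#' Vectorized over sites.
#'
#' @param alt_reads,total_reads non-negative integer vectors.
#' @param conf confidence level (default 0.95).
#' @return data.frame with `fraction`, `lower`, `upper`.
#' @examples
#' editing_fraction(8, 100)
#' @export
editing_fraction <- function(alt_reads, total_reads, conf = 0.95) {
  if (any(total_reads < 1))
    abort("total_reads must be >= 1: fraction undefined at zero coverage",
          "undefined_fraction_error")
  if (any(alt_reads < 0) || any(alt_reads > total_reads))
    stop_input("alt_reads must lie in [0, total_reads]")
  w <- wilson_interval(alt_reads, total_reads, conf)
  data.frame(fraction = alt_reads / total_reads,
             lower = w$lower, upper = w$upper)
}

# Wilson score interval for a binomial proportion (vectorized).
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Discover DNA-absent C-to-U RNA-editing sites
#'
#' Contrasts A3A+ against APOBEC- samples site by site. A candidate site
#' must (i) be a cytosine on the transcript strand (checked when a
#' reference is supplied), (ii) show DNA variant-allele fraction at or below
#' `max_dna_vaf` in every sample where DNA covers it (default 0: strictly
#' DNA-absent), and (iii) reach `min_cov` coverage with at least `min_alt`
#' edited reads in at least `min_samples` A3A+ samples. Surviving sites are
#' tested with a one-sided Fisher exact test on cohort-aggregated alt/ref
#' counts (A3A+ vs APOBEC-) and corrected by Benjamini-Hochberg; sites with
#' q below `fdr_q` are returned ranked by A3A+ editing fraction.
#'
#' @param rna_counts data.frame: `sample_id`, `sequence_id`, `position`
#'   (0-based), `ref_reads`, `alt_reads`.
#' @param cohorts data.frame with `sample_id`, `cohort` (labels among
#'   `"A3A+"`, `"A3B+"`, `"APOBEC-"`, `"unknown"`), or a named character
#'   vector.
#' @param dna_calls data.frame with `sample_id`, `sequence_id`, `position`,
#'   `vaf` for DNA-covered sites; `NULL` means no DNA evidence against any
#'   site.
#' @param reference optional, see [as_reference()]; enables the transcript
#'   C check.
#' @param filters list with `min_cov` (10), `min_alt` (2), `max_dna_vaf`
#'   (0), `min_samples` (2).
#' @param fdr_q FDR threshold (default 0.05).
#' @return data.frame of class `editing_sites`: `sequence_id`, `position`,
#'   per-cohort aggregated counts and editing fractions, `n_pass_samples`,
#'   `p`, `q`; attribute `all_sites` keeps the full tested table.
#' @export
call_editing_sites <- function(rna_counts, cohorts, dna_calls = NULL,
                               reference = NULL,
                               filters = list(), fdr_q = 0.05) {
  f <- utils::modifyList(
    list(min_cov = 10L, min_alt = 2L, max_dna_vaf = 0, min_samples = 2L),
    filters)
  extra <- setdiff(names(filters), c("min_cov", "min_alt", "max_dna_vaf",
                                     "min_samples"))
  if (length(extra))
    stop_param(paste("unknown filter(s):", paste(extra, collapse = ", ")))
  if (!is.data.frame(cohorts))
    cohorts <- data.frame(sample_id = names(cohorts),
                          cohort = unname(cohorts), stringsAsFactors = FALSE)
  rc <- rna_counts
  key <- paste(rc$sample_id, rc$sequence_id, rc$position)
  if (anyDuplicated(key))
    abort("duplicate (sample, site) rows in rna_counts",
          "input_integrity_error")
  rc$cohort <- cohorts$cohort[match(rc$sample_id, cohorts$sample_id)]
  if (!any(rc$cohort == "APOBEC-", na.rm = TRUE))
    abort("no APOBEC- samples: null cohort required for site discovery",
          "no_null_cohort_error")
  if (!any(rc$cohort == "A3A+", na.rm = TRUE))
    stop_input("no A3A+ samples in rna_counts")

  site_key <- paste(rc$sequence_id, rc$position)
  sites <- unique(rc[, c("sequence_id", "position")])
  sites_key <- paste(sites$sequence_id, sites$position)

  # (i) transcript-strand cytosine check
  if (!is.null(reference)) {
    seqs <- as_reference(reference)
    base <- render_alphabet(substr_at(seqs, sites$sequence_id, sites$position),
                            "DNA")
    keep <- base == "C"
    sites <- sites[keep, , drop = FALSE]
    sites_key <- sites_key[keep]
  }

  # (ii) DNA absence in every DNA-covered sample
  if (!is.null(dna_calls) && nrow(dna_calls) > 0L) {
    dkey <- paste(dna_calls$sequence_id, dna_calls$position)
    bad <- unique(dkey[dna_calls$vaf > f$max_dna_vaf])
    keep <- !(sites_key %in% bad)
    sites <- sites[keep, , drop = FALSE]
    sites_key <- sites_key[keep]
  }
  if (nrow(sites) == 0L)
    return(empty_editing_sites())

  rc <- rc[site_key %in% sites_key, , drop = FALSE]
  rc$total <- rc$ref_reads + rc$alt_reads
  rc$skey <- paste(rc$sequence_id, rc$position)

  a3a <- rc[rc$cohort == "A3A+", , drop = FALSE]
  nul <- rc[rc$cohort == "APOBEC-", , drop = FALSE]

  # (iii) per-sample support filter in the A3A+ cohort
  pass <- a3a$total >= f$min_cov & a3a$alt_reads >= f$min_alt
  n_pass <- tapply(pass, a3a$skey, sum)
  supported <- names(n_pass)[n_pass >= f$min_samples]
  if (!length(supported))
    return(empty_editing_sites())

  agg <- function(df, keys) {
    alt <- tapply(df$alt_reads, df$skey, sum)[keys]
    ref <- tapply(df$ref_reads, df$skey, sum)[keys]
    alt[is.na(alt)] <- 0; ref[is.na(ref)] <- 0
    list(alt = as.numeric(alt), ref = as.numeric(ref))
  }
  a <- agg(a3a, supported)
  b <- agg(nul, supported)
  p <- vapply(seq_along(supported), function(i) {
    stats::fisher.test(matrix(c(a$alt[i], a$ref[i], b$alt[i], b$ref[i]),
                              nrow = 2, byrow = TRUE),
                       alternative = "greater")$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  idx <- match(supported, sites_key)
  tab <- data.frame(
    sequence_id = sites$sequence_id[idx],
    position = sites$position[idx],
    alt_a3a = a$alt, ref_a3a = a$ref,
    alt_null = b$alt, ref_null = b$ref,
    editing_a3a = ifelse(a$alt + a$ref > 0, a$alt / (a$alt + a$ref), NA_real_),
    editing_null = ifelse(b$alt + b$ref > 0, b$alt / (b$alt + b$ref), NA_real_),
    n_pass_samples = as.integer(n_pass[supported]),
    p = p, q = q, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$editing_a3a, tab$q, tab$sequence_id, tab$position), ]
  rownames(tab) <- NULL
  out <- tab[tab$q <= fdr_q, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_sites") <- tab
  attr(out, "filters") <- f
  attr(out, "fdr_q") <- fdr_q
  class(out) <- c("editing_sites", "data.frame")
  out
}

empty_editing_sites <- function() {
  out <- data.frame(sequence_id = character(), position = integer(),
                    alt_a3a = numeric(), ref_a3a = numeric(),
                    alt_null = numeric(), ref_null = numeric(),
                    editing_a3a = numeric(), editing_null = numeric(),
                    n_pass_samples = integer(), p = numeric(), q = numeric(),
                    stringsAsFactors = FALSE)
  attr(out, "all_sites") <- out
  class(out) <- c("editing_sites", "data.frame")
  out
}

#' Base-frequency logogram around top edited sites
#'
#' Aggregates the `2*flank_k + 1` nt windows centred on the edited C of the
#' `top_n` highest-edited sites into a column-normalized base-frequency
#' matrix (the numeric form of a sequence logo).
#'
#' @param site_table an [call_editing_sites()] result (ranked by A3A+
#'   editing fraction).
#' @param reference see [as_reference()].
#' @param top_n number of top sites to aggregate (default 50).
#' @param flank_k flank width on each side (default 5).
#' @param strict error (instead of warn) when fewer than `top_n` sites are
#'   available.
#' @return matrix of class `logogram`: 4 rows (A, C, G, U) by positions
#'   `-flank_k .. +flank_k`; every column sums to 1.
#' @export
build_logogram <- function(site_table, reference, top_n = 50L, flank_k = 5L,
                           strict = FALSE) {
  seqs <- as_reference(reference)
  n_avail <- nrow(site_table)
  if (n_avail < top_n) {
    msg <- sprintf("only %d sites available (top_n = %d)", n_avail, top_n)
    if (strict) stop_input(msg)
    warning(msg, call. = FALSE)
    top_n <- n_avail
  }
  if (top_n == 0L) stop_input("no sites to aggregate")
  top <- site_table[seq_len(top_n), , drop = FALSE]
  width <- 2L * flank_k + 1L
  counts <- matrix(0, nrow = 4L, ncol = width,
                   dimnames = list(.RNA_LETTERS, as.character(-flank_k:flank_k)))
  used <- 0L
  for (r in seq_len(top_n)) {
    s <- seqs[[top$sequence_id[r]]]
    pos0 <- top$position[r]
    if (pos0 - flank_k < 0L || pos0 + flank_k > nchar(s) - 1L) next
    win <- render_alphabet(substr(s, pos0 - flank_k + 1L, pos0 + flank_k + 1L),
                           "RNA")
    ch <- strsplit(win, "", fixed = TRUE)[[1]]
    hit <- match(ch, .RNA_LETTERS)
    ok <- !is.na(hit)
    counts[cbind(hit[ok], which(ok))] <- counts[cbind(hit[ok], which(ok))] + 1
    used <- used + 1L
  }
  if (used == 0L) stop_input("no site had full flanking sequence")
  freq <- sweep(counts, 2, colSums(counts), "/")
  attr(freq, "n_sites") <- used
  class(freq) <- c("logogram", class(freq))
  freq
}

#' @export
print.logogram <- function(x, digits = 3, ...) {
  cat(sprintf("<logogram> base frequencies around the edited C (%d sites)\n",
              attr(x, "n_sites")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Stratify editing by hairpin loop geometry
#'
#' Annotates each site with its best hairpin (RNA pairing: G:U wobble
#' allowed by default) and reports the mean A3A+ editing fraction and site
#' count per (loop-size, loop-position) bin. Loop sizes are binned as 3, 4,
#' 5, `"other"` (qualifying hairpin of another size) and `"none"`
#' (structure-free); empty bins are omitted, not reported as zero.
#'
#' @inheritParams build_logogram
#' @param params [hairpin_params()]; default enables G:U wobble for RNA.
#' @param window hairpin search window half-width (default 25 nt).
#' @return data.frame: `loop_bin`, `site_loop_position`, `n_sites`,
#'   `mean_editing`.
#' @export
stratify_by_hairpin <- function(site_table, reference,
                                params = hairpin_params(allow_GU = TRUE),
                                window = 25L) {
  seqs <- as_reference(reference)
  n <- nrow(site_table)
  if (n == 0L)
    return(data.frame(loop_bin = character(), site_loop_position = integer(),
                      n_sites = integer(), mean_editing = numeric(),
                      stringsAsFactors = FALSE))
  loop_bin <- character(n)
  pos_in_loop <- rep(NA_integer_, n)
  for (r in seq_len(n)) {
    hp <- windowed_hairpin(seqs[[site_table$sequence_id[r]]],
                           site_table$position[r], params, window)
    if (hp$stem_length == 0L) {
      loop_bin[r] <- "none"
    } else {
      loop_bin[r] <- if (hp$loop_length %in% 3:5)
        as.character(hp$loop_length) else "other"
      pos_in_loop[r] <- hp$site_loop_position
    }
  }
  key <- paste(loop_bin, pos_in_loop)
  agg <- lapply(split(seq_len(n), key), function(ix) {
    data.frame(loop_bin = loop_bin[ix[1]],
               site_loop_position = pos_in_loop[ix[1]],
               n_sites = length(ix),
               mean_editing = mean(site_table$editing_a3a[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$loop_bin, out$site_loop_position), ]
  rownames(out) <- NULL
  out
}

#' Per-sample RNA-editing index over a hotspot panel
#'
#' Coverage-weighted mean editing fraction per sample: the sum of edited
#' reads over the sum of total reads across the panel sites (pooled ratio,
#' not a mean of per-site fractions, so low-coverage sites cannot dominate).
#' Samples with zero panel coverage get an `NA` index and `defined = FALSE`.
#'
#' @param rna_counts as in [call_editing_sites()].
#' @param panel data.frame with `sequence_id`, `position` (0-based) of the
#'   panel sites (e.g. the discovered top sites).
#' @return data.frame: `sample_id`, `index`, `alt_reads`, `total_reads`,
#'   `defined`.
#' @export
editing_index <- function(rna_counts, panel) {
  if (is.null(panel) || nrow(panel) == 0L)
    stop_param("panel must contain at least one site")
  pkey <- unique(paste(panel$sequence_id, panel$position))
  rc <- rna_counts[paste(rna_counts$sequence_id, rna_counts$position) %in% pkey,
                   , drop = FALSE]
  samples <- unique(rna_counts$sample_id)
  alt <- tapply(rc$alt_reads, rc$sample_id, sum)[samples]
  tot <- tapply(rc$ref_reads + rc$alt_reads, rc$sample_id, sum)[samples]
  alt[is.na(alt)] <- 0; tot[is.na(tot)] <- 0
  data.frame(sample_id = samples,
             index = ifelse(tot > 0, alt / tot, NA_real_),
             alt_reads = as.numeric(alt), total_reads = as.numeric(tot),
             defined = tot > 0, stringsAsFactors = FALSE)
}

#' Correlate per-sample editing indices with gene expression
#'
#' Spearman rank correlation (shared machinery with
#' [burden_expression_correlation()]) between the editing index and the
#' named gene across overlapping samples.
#'
#' @param indices an [editing_index()] table.
#' @param expression data.frame with `sample_id` and one column per gene.
#' @param gene gene column name (e.g. `"A3A"`).
#' @return list with `rho`, `p`, `n`.
#' @export
correlate_editing_with_expression <- function(indices, expression, gene) {
  if (!gene %in% names(expression))
    stop_input(sprintf("gene '%s' not found in the expression table", gene))
  m <- match(indices$sample_id, expression$sample_id)
  keep <- !is.na(m) & indices$defined
  if (sum(keep) < 3L)
    abort("fewer than 3 overlapping samples with a defined editing index",
          "insufficient_data_error")
  spearman_cor(indices$index[keep], expression[[gene]][m[keep]])
}
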