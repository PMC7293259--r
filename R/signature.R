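#' Build a somatic SNV mutation catalog
#'
#' Validates a table of single-base substitutions against the reference and
#' returns a canonical catalog data.frame. Positions are 0-based internally;
#' use [read_vcf_catalog()] to ingest 1-based VCF records.
#'
#' @param snvs data.frame with columns `sequence_id`, `position` (0-based),
#'   `ref`, `alt`; an optional `tumor_id` column allows multi-tumor tables.
#' @param reference see [as_reference()].
#' @param tumor_id tumor identifier used when `snvs` lacks a `tumor_id`
#'   column.
#' @return data.frame of class `mutation_catalog` with columns
#'   `tumor_id`, `sequence_id`, `position`, `ref`, `alt`.
#' @export
mutation_catalog <- function(snvs, reference, tumor_id = "tumor") {
  seqs <- as_reference(reference)
  req <- c("sequence_id", "position", "ref", "alt")
  if (!all(req %in% names(snvs)))
    stop_input(paste("snvs must have columns:", paste(req, collapse = ", ")))
  if (!"tumor_id" %in% names(snvs)) snvs$tumor_id <- rep(tumor_id, nrow(snvs))
  snvs$ref <- toupper(snvs$ref); snvs$alt <- toupper(snvs$alt)
  if (any(nchar(snvs$ref) != 1L | nchar(snvs$alt) != 1L))
    stop_input("all records must be single-base substitutions")
  miss <- setdiff(unique(snvs$sequence_id), names(seqs))
  if (length(miss))
    abort(paste("reference sequence(s) missing:", paste(miss, collapse = ", ")),
          "missing_reference_error")
  at <- substr_at(seqs, snvs$sequence_id, snvs$position)
  bad <- which(at != snvs$ref)
  if (length(bad))
    stop_input(sprintf("ref allele mismatch at %d record(s), first: %s:%d (%s vs reference %s)",
                       length(bad), snvs$sequence_id[bad[1]],
                       snvs$position[bad[1]], snvs$ref[bad[1]], at[bad[1]]))
  out <- snvs[, c("tumor_id", "sequence_id", "position", "ref", "alt")]
  out$position <- as.integer(out$position)
  class(out) <- c("mutation_catalog", "data.frame")
  out
}

# Vectorized single-base lookup across sequences; pos 0-based.
substr_at <- function(seqs, sequence_id, pos0) {
  substring(seqs[sequence_id], pos0 + 1L, pos0 + 1L)
}

# Logical mask: which catalog rows are pyrimidine-strand TpC C>T/C>G events.
tpc_mutation_mask <- function(catalog, seqs) {
  plus <- catalog$ref == "C" & catalog$alt %in% c("T", "G")
  minus <- catalog$ref == "G" & catalog$alt %in% c("A", "C")
  mask <- rep(FALSE, nrow(catalog))
  if (any(plus)) {
    p <- which(plus & catalog$position >= 1L)
    five <- substr_at(seqs, catalog$sequence_id[p], catalog$position[p] - 1L)
    mask[p] <- five == "T"
  }
  if (any(minus)) {
    m <- which(minus)
    lens <- nchar(seqs[catalog$sequence_id[m]])
    ok <- catalog$position[m] + 1L <= lens - 1L
    m <- m[ok]
    three <- substr_at(seqs, catalog$sequence_id[m], catalog$position[m] + 1L)
    mask[m] <- three == "A"
  }
  mask
}

#' APOBEC burden of a mutation catalog
#'
#' Counts C>T and C>G SNVs whose 5' neighbour on the pyrimidine strand is T
#' (the TpC deamination context; G>A/G>C with a 3' A on the given strand are
#' the same events read from the opposite strand).
#'
#' @param catalog a [mutation_catalog()] for one tumor.
#' @param reference see [as_reference()].
#' @return list with `tpc_fraction`, `n_tpc`, `n_snvs`.
#' @export
apobec_burden <- function(catalog, reference) {
  if (nrow(catalog) == 0L)
    abort("empty catalog: APOBEC burden undefined", "undefined_burden_error")
  seqs <- as_reference(reference)
  mask <- tpc_mutation_mask(catalog, seqs)
  list(tpc_fraction = mean(mask), n_tpc = sum(mask), n_snvs = nrow(catalog))
}

#' Annotate reference TpC sites with context and loop membership
#'
#' Enumerates TpC cytosines on both strands of the reference (or a seeded
#' uniform sample of them when there are more than `max_sites`), extracts
#' the strand-normalized tetranucleotide, and calls [best_hairpin()] on a
#' window around each site. The resulting table provides (a) the background
#' loop fraction used as the denominator of loop enrichment and (b) a cache
#' for per-mutation loop lookups.
#'
#' @inheritParams hairpin_annotate
#' @param max_sites sample size cap for the background (default 10000).
#' @param seed integer seed for the background sample.
#' @return data.frame: `sequence_id`, `position` (0-based), `strand`,
#'   `tetranucleotide`, `character`, `in_loop`, `loop_length`,
#'   `site_loop_position`, `stem_length`, `stem_strength`, with attribute
#'   `sampled` (logical).
#' @export
annotate_tpc_sites <- function(sequences, params = hairpin_params(),
                               window = 25L, max_sites = 10000L, seed = 1L) {
  seqs <- as_reference(sequences)
  sites <- do.call(rbind, lapply(names(seqs), function(id) {
    p <- tpc_positions_plus(seqs[[id]])
    m <- tpc_positions_minus(seqs[[id]])
    rbind(
      if (length(p)) data.frame(sequence_id = id, position = p, strand = "+",
                                stringsAsFactors = FALSE),
      if (length(m)) data.frame(sequence_id = id, position = m, strand = "-",
                                stringsAsFactors = FALSE)
    )
  }))
  if (is.null(sites) || nrow(sites) == 0L)
    stop_input("reference contains no TpC sites")
  sampled <- FALSE
  if (nrow(sites) > max_sites) {
    set.seed(as.integer(seed))
    sites <- sites[sort(sample.int(nrow(sites), max_sites)), , drop = FALSE]
    sampled <- TRUE
  }
  n <- nrow(sites)
  sites$tetranucleotide <- NA_character_
  sites$character <- NA_character_
  sites$in_loop <- FALSE
  sites$loop_length <- NA_integer_
  sites$site_loop_position <- NA_integer_
  sites$stem_length <- 0L
  sites$stem_strength <- 0
  for (r in seq_len(n)) {
    s <- seqs[[sites$sequence_id[r]]]
    pos0 <- sites$position[r]
    ctx <- tryCatch(tetranucleotide_context(s, pos0),
                    apobecedit_error = function(e) NULL)
    if (!is.null(ctx)) {
      sites$tetranucleotide[r] <- ctx$tetranucleotide
      sites$character[r] <- ctx$character
    }
    hp <- windowed_hairpin(s, pos0, params, window)
    sites$in_loop[r] <- hp$stem_length > 0L
    sites$loop_length[r] <- hp$loop_length
    sites$site_loop_position[r] <- hp$site_loop_position
    sites$stem_length[r] <- hp$stem_length
    sites$stem_strength[r] <- hp$stem_strength
  }
  rownames(sites) <- NULL
  attr(sites, "sampled") <- sampled
  sites
}

#' A3A-vs-A3B character of a tumor's TpC mutations
#'
#' For every TpC mutation of the catalog, extracts the strand-normalized
#' tetranucleotide and the hairpin placement of the site, then summarizes:
#' the fractions of TpC mutations in YTCA and RTCA context, the fraction
#' falling inside a stem-loop loop, and that loop fraction divided by the
#' loop fraction over the reference's own TpC sites (loop enrichment).
#'
#' @inheritParams apobec_burden
#' @param params [hairpin_params()].
#' @param window hairpin search window half-width (default 25 nt).
#' @param tpc_annotation optional precomputed [annotate_tpc_sites()] table;
#'   computed (sampled, seeded) when missing.
#' @param seed seed for the background sample when `tpc_annotation` is NULL.
#' @return list with `ytca_fraction`, `rtca_fraction`, `loop_fraction`,
#'   `loop_enrichment`, `n_tpc`.
#' @export
a3a_a3b_character <- function(catalog, reference, params = hairpin_params(),
                              window = 25L, tpc_annotation = NULL, seed = 1L) {
  seqs <- as_reference(reference)
  if (is.null(tpc_annotation))
    tpc_annotation <- annotate_tpc_sites(seqs, params, window, seed = seed)
  mask <- tpc_mutation_mask(catalog, seqs)
  n_tpc <- sum(mask)
  if (n_tpc == 0L)
    return(list(ytca_fraction = NA_real_, rtca_fraction = NA_real_,
                loop_fraction = NA_real_, loop_enrichment = NA_real_,
                n_tpc = 0L))
  muts <- catalog[mask, , drop = FALSE]
  key <- paste(muts$sequence_id, muts$position)
  akey <- paste(tpc_annotation$sequence_id, tpc_annotation$position)
  hit <- match(key, akey)
  tet <- tpc_annotation$tetranucleotide[hit]
  in_loop <- tpc_annotation$in_loop[hit]
  todo <- which(is.na(hit))
  for (r in todo) {
    s <- seqs[[muts$sequence_id[r]]]
    pos0 <- muts$position[r]
    ctx <- tryCatch(tetranucleotide_context(s, pos0),
                    apobecedit_error = function(e) NULL)
    tet[r] <- if (is.null(ctx)) NA_character_ else ctx$tetranucleotide
    in_loop[r] <- windowed_hairpin(s, pos0, params, window)$stem_length > 0L
  }
  char <- classify_tetranucleotide(tet)
  bg <- mean(tpc_annotation$in_loop)
  lf <- mean(in_loop)
  list(ytca_fraction = mean(char == "YTCA-like", na.rm = FALSE),
       rtca_fraction = mean(char == "RTCA-like", na.rm = FALSE),
       loop_fraction = lf,
       loop_enrichment = if (bg > 0) lf / bg else NA_real_,
       n_tpc = n_tpc)
}

#' Per-tumor signature profiles for a cohort
#'
#' Runs [apobec_burden()] and [a3a_a3b_character()] for every tumor of a
#' combined catalog, computing the reference TpC annotation once and reusing
#' it across tumors.
#'
#' @param catalogs a [mutation_catalog()] data.frame with a `tumor_id`
#'   column covering one or more tumors.
#' @inheritParams a3a_a3b_character
#' @return data.frame of class `tumor_profiles`: one row per tumor with
#'   `tumor_id`, `n_snvs`, `n_tpc`, `tpc_fraction`, `ytca_fraction`,
#'   `rtca_fraction`, `loop_fraction`, `loop_enrichment`.
#' @export
profile_tumors <- function(catalogs, reference, params = hairpin_params(),
                           window = 25L, tpc_annotation = NULL, seed = 1L) {
  seqs <- as_reference(reference)
  if (is.null(tpc_annotation))
    tpc_annotation <- annotate_tpc_sites(seqs, params, window, seed = seed)
  ids <- unique(catalogs$tumor_id)
  rows <- lapply(ids, function(id) {
    cat_i <- catalogs[catalogs$tumor_id == id, , drop = FALSE]
    b <- apobec_burden(cat_i, seqs)
    ch <- a3a_a3b_character(cat_i, seqs, params, window, tpc_annotation)
    data.frame(tumor_id = id, n_snvs = b$n_snvs, n_tpc = b$n_tpc,
               tpc_fraction = b$tpc_fraction,
               ytca_fraction = ch$ytca_fraction,
               rtca_fraction = ch$rtca_fraction,
               loop_fraction = ch$loop_fraction,
               loop_enrichment = ch$loop_enrichment,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tumor_profiles", "data.frame")
  out
}

#' Classification thresholds for tumor labelling
#'
#' @param tau_burden minimum TpC fraction for APOBEC positivity (default
#'   0.10).
#' @param tau_char minimum YTCA (or RTCA) share of the combined
#'   YTCA+RTCA character for an A3A+ (A3B+) call (default 0.6).
#' @param tau_loop minimum loop enrichment marking A3A character (default
#'   1.5).
#' @param min_tpc minimum TpC mutation count for APOBEC positivity
#'   (default 10).
#' @return validated list of thresholds.
#' @export
classification_thresholds <- function(tau_burden = 0.10, tau_char = 0.6,
                                      tau_loop = 1.5, min_tpc = 10L) {
  for (v in c(tau_burden = tau_burden, tau_char = tau_char)) {
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop_param("fraction thresholds must lie in (0, 1)")
  }
  if (!is.finite(tau_loop) || tau_loop <= 0)
    stop_param("tau_loop must be positive")
  list(tau_burden = tau_burden, tau_char = tau_char,
       tau_loop = tau_loop, min_tpc = as.integer(min_tpc))
}

#' Classify tumors as A3A+, A3B+, or APOBEC-
#'
#' Deterministic rule over the signature profile: a tumor is `APOBEC-` when
#' its TpC fraction or TpC count falls below the burden thresholds;
#' otherwise `A3A+` when the YTCA share of YTCA+RTCA character reaches
#' `tau_char` or loop enrichment reaches `tau_loop`; otherwise `A3B+` when
#' the RTCA share reaches `tau_char`; otherwise the larger character
#' fraction decides (ties, including zero character, resolve to A3B+ since
#' loop enrichment already had the chance to mark A3A).
#'
#' @param profiles a [profile_tumors()] table.
#' @param thresholds a [classification_thresholds()] list.
#' @return `profiles` with an added `label` column.
#' @export
classify_tumors <- function(profiles, thresholds = classification_thresholds()) {
  thresholds <- do.call(classification_thresholds, thresholds)
  lab <- character(nrow(profiles))
  for (r in seq_len(nrow(profiles))) {
    p <- profiles[r, ]
    if (is.na(p$tpc_fraction) || p$tpc_fraction < thresholds$tau_burden ||
        p$n_tpc < thresholds$min_tpc) {
      lab[r] <- "APOBEC-"
      next
    }
    tot <- p$ytca_fraction + p$rtca_fraction
    ry <- if (!is.na(tot) && tot > 0) p$ytca_fraction / tot else NA_real_
    loop_hi <- !is.na(p$loop_enrichment) &&
      p$loop_enrichment >= thresholds$tau_loop
    if ((!is.na(ry) && ry >= thresholds$tau_char) || loop_hi) {
      lab[r] <- "A3A+"
    } else if (!is.na(ry) && (1 - ry) >= thresholds$tau_char) {
      lab[r] <- "A3B+"
    } else if (!is.na(ry) && ry > 0.5) {
      lab[r] <- "A3A+"
    } else {
      lab[r] <- "A3B+"
    }
  }
  profiles$label <- lab
  profiles
}

#' Spearman rank correlation with exact small-n p-value
#'
#' Shared correlation machinery: exact permutation p for n <= 9 (no ties),
#' t approximation otherwise. Constant input is an error (flagged, never a
#' silent NaN).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    abort("fewer than 3 complete observation pairs", "insufficient_data_error")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    abort("constant vector: rank correlation undefined",
          "undefined_correlation_error")
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= 9L && !anyDuplicated(x) && !anyDuplicated(y)) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate a per-tumor mutation metric with gene expression
#'
#' Spearman rank correlation between a profile column (default the TpC
#' burden fraction) and the named gene's expression across overlapping
#' samples. The same machinery serves the RNA-editing/expression
#' correlation.
#'
#' @param profiles a [profile_tumors()] table (or any data.frame with a
#'   `tumor_id` column and the metric column).
#' @param expression data.frame with `sample_id` and one column per gene.
#' @param gene gene column name (e.g. `"A3A"`).
#' @param metric profile column to correlate (default `"tpc_fraction"`).
#' @return list with `rho`, `p`, `n` (see [spearman_cor()]).
#' @export
burden_expression_correlation <- function(profiles, expression, gene,
                                          metric = "tpc_fraction") {
  if (!gene %in% names(expression))
    stop_input(sprintf("gene '%s' not found in the expression table", gene))
  if (!metric %in% names(profiles))
    stop_param(sprintf("metric '%s' not found in profiles", metric))
  m <- match(profiles$tumor_id, expression$sample_id)
  keep <- !is.na(m)
  if (sum(keep) < 3L)
    abort("fewer than 3 overlapping samples between profiles and expression",
          "insufficient_data_error")
  spearman_cor(profiles[[metric]][keep], expression[[gene]][m[keep]])
}
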