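# Named sub-seed streams: every generator draws from its own stream derived
# from the master seed, so any single stage is reproducible in isolation.
.SEED_STREAMS <- c(reference = 11L, catalog = 23L, rna = 37L,
                   expression = 41L, droplet = 53L, background = 67L)

#' Derive a named sub-seed from a master seed
#'
#' `sub = (master * 1009 + offset(stream) + index) mod (2^31 - 2) + 1`, with
#' a fixed integer offset per stream name. Deterministic, keeps all seeds in
#' 32-bit integer range, and decorrelates streams that share a master seed.
#'
#' @param master integer master seed.
#' @param stream one of `names(apobecedit:::.SEED_STREAMS)`.
#' @param index optional per-item offset (e.g. tumor number).
#' @return integer sub-seed.
#' @export
derive_seed <- function(master, stream, index = 0L) {
  if (!stream %in% names(.SEED_STREAMS))
    stop_param(paste("unknown seed stream:", stream))
  off <- .SEED_STREAMS[[stream]]
  as.integer((as.numeric(master) * 1009 + off * 1e5 + index) %% 2147483646) + 1L
}

default_hairpin_specs <- function() {
  list(list(stem_length = 7L, loop_seq = "CATC", count = 3L),
       list(stem_length = 6L, loop_seq = "TTC", count = 2L),
       list(stem_length = 6L, loop_seq = "AATCA", count = 2L))
}

#' Generate reference sequences with planted hairpins
#'
#' Builds uniform-random backbones and plants non-overlapping perfect
#' hairpins (random arm, its reverse complement, and the requested loop
#' sequence). Default loop sequences carry the CAUC-type TpC/UpC motifs the
#' editing machinery targets (rendered in DNA letters), so downstream
#' discovery stages have A3A-optimal sites with known geometry.
#'
#' @param n_seqs number of sequences (default 4).
#' @param length length of each sequence in nt (default 8000, minimum 60).
#' @param hairpin_specs list of `list(stem_length, loop_seq, count)`
#'   entries, each planted `count` times per sequence.
#' @param seed integer seed.
#' @return list with `sequences` (named character), `truth` (data.frame:
#'   `sequence_id`, `arm5_start`, `stem_length`, `loop_seq`, `loop_start`,
#'   `loop_length`, `tc_c_position`, `c_loop_position`; positions 0-based)
#'   and `seed`.
#' @export
make_reference <- function(n_seqs = 4L, length = 8000L,
                           hairpin_specs = default_hairpin_specs(),
                           seed = 1L) {
  if (length < 60L) stop_param("sequence length must be >= 60")
  set.seed(derive_seed(seed, "reference"))
  seqs <- character(n_seqs)
  names(seqs) <- sprintf("chr%02d", seq_len(n_seqs))
  truth <- list()
  for (s in seq_len(n_seqs)) {
    backbone <- sample(.DNA_LETTERS, length, replace = TRUE)
    occupied <- logical(length)
    for (spec in hairpin_specs) {
      stem <- as.integer(spec$stem_length)
      loop <- toupper(spec$loop_seq)
      total <- 2L * stem + nchar(loop)
      for (k in seq_len(spec$count)) {
        placed <- FALSE
        for (try in seq_len(500L)) {
          start <- sample.int(length - total - 10L, 1L) + 5L
          span <- seq(start, start + total - 1L)
          # small buffer so adjacent plants cannot merge into one structure
          buf <- seq(max(1L, start - 5L), min(length, start + total + 4L))
          if (any(occupied[buf])) next
          arm5 <- sample(.DNA_LETTERS, stem, replace = TRUE)
          motif <- c(arm5, strsplit(loop, "", fixed = TRUE)[[1]],
                     strsplit(revcomp(paste(arm5, collapse = "")), "",
                              fixed = TRUE)[[1]])
          backbone[span] <- motif
          occupied[buf] <- TRUE
          loop_start0 <- start - 1L + stem
          lch <- strsplit(loop, "", fixed = TRUE)[[1]]
          tc <- which(lch == "C" & c("", lch[-nchar(loop)]) == "T")
          truth[[length(truth) + 1L]] <- data.frame(
            sequence_id = names(seqs)[s],
            arm5_start = start - 1L,
            stem_length = stem, loop_seq = loop,
            loop_start = loop_start0, loop_length = nchar(loop),
            tc_c_position = if (length(tc)) loop_start0 + tc[1L] - 1L
                            else NA_integer_,
            c_loop_position = if (length(tc)) tc[1L] else NA_integer_,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          abort(sprintf("could not place hairpin (stem %d, loop %s) without overlap",
                        stem, loop),
                "placement_error")
      }
    }
    seqs[s] <- paste(backbone, collapse = "")
  }
  list(sequences = seqs,
       truth = do.call(rbind, truth),
       seed = as.integer(seed))
}

#' Simulate one tumor's mutation catalog with planted class character
#'
#' A3A-like tumors draw their APOBEC mutations from reference TpC sites
#' weighted toward YTCA context (`w_motif`) and loop residence (`w_loop`);
#' A3B-like tumors weight RTCA context only; the remaining
#' `background_rate` share of mutations (and the entire catalog of
#' `"background"` tumors) are uniform SNVs over the reference with a
#' uniform alternate allele. Alt alleles at APOBEC draws are the two
#' deamination outcomes C>T/C>G (strand-mapped for minus-strand sites).
#'
#' @param reference see [as_reference()].
#' @param class_label `"A3A"`, `"A3B"`, or `"background"`.
#' @param n_mut number of SNVs (default 500).
#' @param params list: `w_loop` (5), `w_motif` (5), `background_rate`
#'   (0.4 — the share of non-APOBEC mutations in signature-class tumors).
#' @param seed integer seed.
#' @param tumor_id identifier for the catalog.
#' @param tpc_annotation optional precomputed [annotate_tpc_sites()] table
#'   over the full reference (computed if missing).
#' @return list with `catalog` (a [mutation_catalog()]) and `truth`
#'   (per-draw component and site table).
#' @export
simulate_mutation_catalog <- function(reference, class_label, n_mut = 500L,
                                      params = list(), seed = 1L,
                                      tumor_id = "tumor",
                                      tpc_annotation = NULL) {
  p <- utils::modifyList(list(w_loop = 5, w_motif = 5, background_rate = 0.4),
                         params)
  class_label <- match.arg(class_label, c("A3A", "A3B", "background"))
  seqs <- as_reference(reference)
  set.seed(derive_seed(seed, "catalog"))
  n_mut <- as.integer(n_mut)

  n_apobec <- if (class_label == "background") 0L
              else as.integer(round(n_mut * (1 - p$background_rate)))
  n_bg <- n_mut - n_apobec

  rows <- list()
  if (n_apobec > 0L) {
    if (is.null(tpc_annotation))
      tpc_annotation <- annotate_tpc_sites(seqs, max_sites = .Machine$integer.max)
    ann <- tpc_annotation
    if (n_apobec > nrow(ann))
      stop_param("n_mut exceeds available TpC sites for without-replacement draws")
    w <- rep(1, nrow(ann))
    if (class_label == "A3A") {
      w <- w * ifelse(!is.na(ann$character) & ann$character == "YTCA-like",
                      p$w_motif, 1)
      w <- w * ifelse(ann$in_loop, p$w_loop, 1)
    } else {
      w <- w * ifelse(!is.na(ann$character) & ann$character == "RTCA-like",
                      p$w_motif, 1)
    }
    pick <- sample.int(nrow(ann), n_apobec, prob = w)
    site <- ann[pick, , drop = FALSE]
    to_t <- stats::runif(n_apobec) < 0.5
    plus <- site$strand == "+"
    ref <- ifelse(plus, "C", "G")
    alt <- ifelse(plus, ifelse(to_t, "T", "G"), ifelse(to_t, "A", "C"))
    rows[[1]] <- data.frame(sequence_id = site$sequence_id,
                            position = site$position,
                            ref = ref, alt = alt,
                            component = "apobec", stringsAsFactors = FALSE)
  }
  if (n_bg > 0L) {
    lens <- nchar(seqs)
    cum <- cumsum(lens)
    gpos <- sample.int(sum(lens), n_bg)
    sidx <- findInterval(gpos - 1L, c(0L, cum[-length(cum)]))
    pos0 <- gpos - c(0L, cum)[sidx] - 1L
    sid <- names(seqs)[sidx]
    ref <- substr_at(seqs, sid, pos0)
    alt <- vapply(ref, function(b) sample(setdiff(.DNA_LETTERS, b), 1L),
                  character(1), USE.NAMES = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(sequence_id = sid, position = pos0,
                                            ref = ref, alt = alt,
                                            component = "background",
                                            stringsAsFactors = FALSE)
  }
  draws <- do.call(rbind, rows)
  # Drop any rare duplicate position within the tumor (a site mutates once).
  draws <- draws[!duplicated(paste(draws$sequence_id, draws$position)), ,
                 drop = FALSE]
  catalog <- mutation_catalog(draws[, c("sequence_id", "position", "ref", "alt")],
                              seqs, tumor_id = tumor_id)
  list(catalog = catalog,
       truth = list(class_label = class_label, draws = draws,
                    params = p, seed = as.integer(seed)))
}

#' Simulate a tumor cohort with known class labels
#'
#' Generates `n_per_class` tumors for each of the three classes (A3A-like,
#' A3B-like, background) over one reference, reusing a single TpC
#' annotation for all tumors.
#'
#' @param reference a [make_reference()] result, any [as_reference()] input,
#'   or `NULL` to build the default reference.
#' @param n_per_class tumors per class (default 50).
#' @param n_mut SNVs per tumor (default 500).
#' @param params generator weights, see [simulate_mutation_catalog()].
#' @param seed master seed; per-tumor sub-seeds derive from it.
#' @return list with `catalogs` (combined [mutation_catalog()]), `truth`
#'   (data.frame `tumor_id`, `true_class`, `true_label`), `reference`
#'   (named character), `tpc_annotation`.
#' @export
simulate_tumor_cohort <- function(reference = NULL, n_per_class = 50L,
                                  n_mut = 500L, params = list(), seed = 1L) {
  if (is.null(reference)) reference <- make_reference(seed = seed)
  seqs <- if (is.list(reference) && !is.null(reference$sequences))
    as_reference(reference$sequences) else as_reference(reference)
  ann <- annotate_tpc_sites(seqs, max_sites = .Machine$integer.max)
  classes <- c(A3A = "A3A+", A3B = "A3B+", background = "APOBEC-")
  cats <- list(); labels <- list()
  i <- 0L
  for (cl in names(classes)) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1L
      id <- sprintf("%s_%03d", cl, k)
      sim <- simulate_mutation_catalog(seqs, cl, n_mut, params,
                                       seed = derive_seed(seed, "catalog", i),
                                       tumor_id = id, tpc_annotation = ann)
      cats[[i]] <- sim$catalog
      labels[[i]] <- data.frame(tumor_id = id, true_class = cl,
                                true_label = classes[[cl]],
                                stringsAsFactors = FALSE)
    }
  }
  catalogs <- do.call(rbind, cats)
  class(catalogs) <- c("mutation_catalog", "data.frame")
  list(catalogs = catalogs, truth = do.call(rbind, labels),
       reference = seqs, tpc_annotation = ann)
}

#' Simulate an RNA-editing cohort with planted hotspots
#'
#' Plants `n_hotspots` edited sites at loop TpC positions of the reference
#' (geometry-graded mean editing: 4-nt loops highest, then 3, then 5) and
#' `n_null_sites` unedited cytosines. Per sample and site, coverage is
#' Poisson and edited reads are binomial with a per-sample Beta-distributed
#' editing fraction (hotspots, A3A+ samples only) plus a sequencing error
#' rate everywhere. A3A expression follows a linear link on each sample's
#' mean true editing plus Gaussian noise. Matched DNA calls report VAF 0 at
#' every site (the RNA mutations have no DNA counterpart).
#'
#' @param reference a [make_reference()] result or `NULL` for the default.
#' @param n_hotspots planted editing hotspots (default 10).
#' @param n_null_sites unedited cytosine sites (default 190).
#' @param n_per_class samples per cohort (A3A+ and APOBEC-; default 20).
#' @param coverage_mean Poisson mean read coverage (default 50).
#' @param error_rate per-read C>U error probability (default 0.001).
#' @param editing_params list: `mean_by_loop` (named means by loop length,
#'   default 3: 0.05, 4: 0.08, 5: 0.03 — the few-percent per-target range,
#'   maximal in 4-nt loops), `default_mean` 0.05, `concentration` 30 (Beta
#'   concentration across samples).
#' @param expression_link list: `a` 1, `b` 50, `sigma` 0.4 (expression =
#'   a + b * sample mean editing + N(0, sigma)).
#' @param seed master seed.
#' @return list with `rna_counts`, `cohorts`, `dna_calls`, `expression`,
#'   `reference`, and `truth` (hotspot table with true means and geometry,
#'   per-sample true editing matrix, link parameters).
#' @export
simulate_rna_editing_cohort <- function(reference = NULL, n_hotspots = 10L,
                                        n_null_sites = 190L, n_per_class = 20L,
                                        coverage_mean = 50, error_rate = 0.001,
                                        editing_params = list(),
                                        expression_link = list(), seed = 1L) {
  ep <- utils::modifyList(
    list(mean_by_loop = c("3" = 0.05, "4" = 0.08, "5" = 0.03),
         default_mean = 0.05, concentration = 30), editing_params)
  link <- utils::modifyList(list(a = 1, b = 50, sigma = 0.4), expression_link)
  if (is.null(reference)) reference <- make_reference(seed = seed)
  if (!(is.list(reference) && !is.null(reference$truth)))
    stop_param("reference must be a make_reference() result (planted truth required)")
  seqs <- as_reference(reference$sequences)
  planted <- reference$truth[!is.na(reference$truth$tc_c_position), ,
                             drop = FALSE]
  if (nrow(planted) < n_hotspots)
    stop_param("not enough planted loop TpC sites for the requested hotspots")
  set.seed(derive_seed(seed, "rna"))
  hs <- planted[sample.int(nrow(planted), n_hotspots), , drop = FALSE]
  mean_ed <- ep$mean_by_loop[as.character(hs$loop_length)]
  mean_ed[is.na(mean_ed)] <- ep$default_mean
  hotspots <- data.frame(sequence_id = hs$sequence_id,
                         position = hs$tc_c_position,
                         loop_length = hs$loop_length,
                         c_loop_position = hs$c_loop_position,
                         true_mean_editing = unname(mean_ed),
                         stringsAsFactors = FALSE)
  if (any(hotspots$true_mean_editing + error_rate > 1))
    stop_param("editing + error rate exceeds 1")

  # null sites: plus-strand cytosines away from the hotspots
  all_c <- do.call(rbind, lapply(names(seqs), function(id) {
    ch <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
    pos <- which(ch == "C") - 1L
    data.frame(sequence_id = id, position = pos, stringsAsFactors = FALSE)
  }))
  hkey <- paste(hotspots$sequence_id, hotspots$position)
  all_c <- all_c[!(paste(all_c$sequence_id, all_c$position) %in% hkey), ,
                 drop = FALSE]
  nulls <- all_c[sample.int(nrow(all_c), n_null_sites), , drop = FALSE]
  sites <- rbind(hotspots[, c("sequence_id", "position")], nulls)
  is_hot <- c(rep(TRUE, nrow(hotspots)), rep(FALSE, nrow(nulls)))

  samples <- c(sprintf("A3A_%02d", seq_len(n_per_class)),
               sprintf("NEG_%02d", seq_len(n_per_class)))
  cohort <- rep(c("A3A+", "APOBEC-"), each = n_per_class)

  n_sites <- nrow(sites)
  # per-sample, per-hotspot true editing fractions
  edit_mat <- matrix(0, nrow = length(samples), ncol = n_sites,
                     dimnames = list(samples, NULL))
  k <- ep$concentration
  for (j in which(is_hot)) {
    m <- hotspots$true_mean_editing[j]
    f <- stats::rbeta(n_per_class, m * k, (1 - m) * k)
    edit_mat[seq_len(n_per_class), j] <- f
  }
  cov <- matrix(stats::rpois(length(samples) * n_sites, coverage_mean),
                nrow = length(samples))
  pr <- pmin(edit_mat + error_rate, 1)
  alt <- matrix(stats::rbinom(length(cov), as.vector(cov), as.vector(pr)),
                nrow = length(samples))
  rna_counts <- data.frame(
    sample_id = rep(samples, times = n_sites),
    sequence_id = rep(sites$sequence_id, each = length(samples)),
    position = rep(sites$position, each = length(samples)),
    ref_reads = as.vector(cov - alt), alt_reads = as.vector(alt),
    stringsAsFactors = FALSE)

  set.seed(derive_seed(seed, "expression"))
  mean_editing <- rowMeans(edit_mat[, is_hot, drop = FALSE])
  expr <- link$a + link$b * mean_editing +
    stats::rnorm(length(samples), 0, link$sigma)
  expression <- data.frame(sample_id = samples, A3A = expr,
                           stringsAsFactors = FALSE)

  dna_calls <- data.frame(
    sample_id = rep(samples, times = n_sites),
    sequence_id = rep(sites$sequence_id, each = length(samples)),
    position = rep(sites$position, each = length(samples)),
    vaf = 0, stringsAsFactors = FALSE)

  list(rna_counts = rna_counts,
       cohorts = data.frame(sample_id = samples, cohort = cohort,
                            stringsAsFactors = FALSE),
       dna_calls = dna_calls,
       expression = expression,
       reference = seqs,
       truth = list(hotspots = hotspots, edit_mat = edit_mat,
                    sites = cbind(sites, is_hotspot = is_hot),
                    link = link, error_rate = error_rate,
                    seed = as.integer(seed)))
}

#' Simulate a two-channel droplet well at known concentrations
#'
#' Each of `n_droplets` droplets receives independent Poisson numbers of WT
#' and mutant templates with means `c_wt * v` and `c_mut * v`; a channel is
#' positive when its occupancy is at least 1.
#'
#' @param c_wt,c_mut true concentrations in copies per microliter.
#' @param n_droplets droplets generated (default 20000).
#' @param droplet_volume droplet volume in uL (default 0.00085).
#' @param seed integer seed.
#' @param well_id identifier.
#' @return list with `well` (one-row data.frame: `well_id`, `n_droplets`,
#'   `n_fam_pos`, `n_hex_pos`, `n_double_pos`, `droplet_volume`) and
#'   `truth`.
#' @export
simulate_droplet_well <- function(c_wt, c_mut, n_droplets = 20000L,
                                  droplet_volume = 0.00085, seed = 1L,
                                  well_id = "well") {
  if (n_droplets < 1L) stop_param("n_droplets must be >= 1")
  if (c_wt < 0 || c_mut < 0) stop_param("concentrations must be >= 0")
  set.seed(derive_seed(seed, "droplet"))
  ow <- stats::rpois(n_droplets, c_wt * droplet_volume)
  om <- stats::rpois(n_droplets, c_mut * droplet_volume)
  well <- data.frame(well_id = well_id,
                     n_droplets = as.integer(n_droplets),
                     n_fam_pos = sum(ow > 0L),
                     n_hex_pos = sum(om > 0L),
                     n_double_pos = sum(ow > 0L & om > 0L),
                     droplet_volume = droplet_volume,
                     stringsAsFactors = FALSE)
  list(well = well,
       truth = list(c_wt = c_wt, c_mut = c_mut,
                    lambda_wt = c_wt * droplet_volume,
                    lambda_mut = c_mut * droplet_volume,
                    seed = as.integer(seed)))
}
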