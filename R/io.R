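# Tabular dialect: TSV, header required, "." for missing values.

#' Read/write the package's canonical TSV dialect
#'
#' Tab-separated, header required, `.` for missing. Comment lines beginning
#' with `#` (the provenance header written by [write_tsv()]) are skipped on
#' read.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop_input(paste("file not found:", path))
  utils::read.delim(path, sep = "\t", na.strings = ".", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @param header optional character vector of `#`-prefixed provenance lines.
#' @export
write_tsv <- function(x, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-tumor somatic SNV catalog from VCF
#'
#' SNV records only: multiallelic records are split into one SNV per
#' alternate allele; indels and symbolic alleles are skipped (the skip count
#' is attached as attribute `n_skipped` and logged). VCF 1-based positions
#' are converted to the package's 0-based internal coordinates.
#'
#' @param path VCF file path.
#' @param reference see [as_reference()]; used to validate records.
#' @param tumor_id tumor identifier (default: file name without extension).
#' @return a [mutation_catalog()] with attribute `n_skipped`.
#' @export
read_vcf_catalog <- function(path, reference, tumor_id = NULL) {
  if (!file.exists(path)) stop_input(paste("file not found:", path))
  if (is.null(tumor_id)) tumor_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  skipped <- 0L
  rows <- list()
  if (nrow(fix) > 0L) {
    for (r in seq_len(nrow(fix))) {
      ref <- toupper(fix$REF[r])
      alts <- strsplit(toupper(fix$ALT[r]), ",", fixed = TRUE)[[1]]
      for (alt in alts) {
        if (nchar(ref) == 1L && nchar(alt) == 1L &&
            ref %in% .DNA_LETTERS && alt %in% .DNA_LETTERS) {
          rows[[length(rows) + 1L]] <- data.frame(
            sequence_id = fix$CHROM[r],
            position = as.integer(fix$POS[r]) - 1L,
            ref = ref, alt = alt, stringsAsFactors = FALSE)
        } else {
          skipped <- skipped + 1L
        }
      }
    }
  }
  snvs <- if (length(rows)) do.call(rbind, rows)
          else data.frame(sequence_id = character(), position = integer(),
                          ref = character(), alt = character(),
                          stringsAsFactors = FALSE)
  if (skipped > 0L)
    message(sprintf("read_vcf_catalog: skipped %d non-SNV allele(s) in %s",
                    skipped, basename(path)))
  cat_out <- if (nrow(snvs)) mutation_catalog(snvs, reference, tumor_id)
             else {
               empty <- data.frame(tumor_id = character(),
                                   sequence_id = character(),
                                   position = integer(), ref = character(),
                                   alt = character(), stringsAsFactors = FALSE)
               class(empty) <- c("mutation_catalog", "data.frame")
               empty
             }
  attr(cat_out, "n_skipped") <- skipped
  cat_out
}

#' Read a droplet-well CSV
#'
#' Expected columns: `well_id`, `sample_id`, `n_droplets`, `n_fam_pos`,
#' `n_hex_pos`; `n_double_pos` is optional.
#'
#' @param path CSV file path.
#' @return data.frame of wells.
#' @export
read_ddpcr_csv <- function(path) {
  if (!file.exists(path)) stop_input(paste("file not found:", path))
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "sample_id", "n_droplets", "n_fam_pos", "n_hex_pos")
  if (!all(need %in% names(w)))
    stop_input(paste("ddPCR CSV must have columns:",
                     paste(need, collapse = ", ")))
  bad <- w$n_fam_pos > w$n_droplets | w$n_hex_pos > w$n_droplets |
    w$n_fam_pos < 0 | w$n_hex_pos < 0
  if (any(bad))
    stop_input(sprintf("positive counts exceed droplet counts in well(s): %s",
                       paste(w$well_id[bad], collapse = ", ")))
  w
}

#' Default run configuration
#'
#' One flat list of every tunable the pipeline stages accept, with the
#' package defaults. [run_config()] merges user values over these and
#' rejects unknown keys.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    # hairpin model
    min_stem = 3L, max_stem = 12L, min_loop = 3L, max_loop = 11L,
    pair_score_gc = 3, pair_score_at = 2, pair_score_gu = 1,
    allow_GU = FALSE, window = 25L,
    # classification
    tau_burden = 0.10, tau_char = 0.6, tau_loop = 1.5, min_tpc = 10L,
    # editing-site discovery
    min_cov = 10L, min_alt = 2L, max_dna_vaf = 0, min_samples = 2L,
    fdr_q = 0.05, top_n = 50L, flank_k = 5L,
    # ddPCR
    droplet_volume = 0.00085, cutoff_droplets = 3L, cutoff_conc = 0.25,
    per_well = FALSE,
    # synthetic data
    n_seqs = 4L, seq_length = 8000L, n_per_class = 50L, n_mut = 500L,
    w_loop = 5, w_motif = 5, background_rate = 0.4,
    n_hotspots = 10L, n_null_sites = 190L, rna_n_per_class = 20L,
    coverage_mean = 50, error_rate = 0.001
  )
}

#' Resolve a run configuration
#'
#' @param config a named list, a YAML file path, or `NULL` (defaults only).
#' @return the fully-resolved configuration list; unknown keys are an
#'   error.
#' @export
run_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop_param(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  utils::modifyList(base, config)
}

config_hairpin_params <- function(cfg) {
  hairpin_params(cfg$min_stem, cfg$max_stem, cfg$min_loop, cfg$max_loop,
                 c(GC = cfg$pair_score_gc, AT = cfg$pair_score_at,
                   GU = cfg$pair_score_gu),
                 cfg$allow_GU)
}

# Polynomial rolling hash of the serialized config (paths excluded), for
# provenance headers.
config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  bytes <- utf8ToInt(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1)), collapse = ";"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(cfg, stage) {
  sprintf("apobecedit %s | stage=%s | config=%s",
          as.character(utils::packageVersion("apobecedit")),
          stage, config_hash(cfg))
}

#' Run pipeline stages end to end
#'
#' Executes the requested stages in dependency order on synthetic or
#' user-supplied inputs, writing every table as TSV (plus the resolved
#' configuration as YAML and a plain-text log of per-stage row counts) under
#' `out_dir`. Stages: `"simulate"` (tumor cohort + RNA cohort + truth),
#' `"classify"` (profiles + labels), `"editing"` (site discovery, logogram,
#' stratification, per-sample index, expression correlation), `"ddpcr"`
#' (well quantification; needs `wells`).
#'
#' @param config see [run_config()].
#' @param stages character vector of stage names (default all but ddpcr
#'   unless `wells` is given).
#' @param wells optional droplet-well data.frame or CSV path for the ddpcr
#'   stage.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = NULL, stages = NULL, wells = NULL) {
  cfg <- run_config(config)
  if (is.null(stages))
    stages <- c("simulate", "classify", "editing",
                if (!is.null(wells)) "ddpcr")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  log_line <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", sep = "", file = logf, append = TRUE)
    message(line)
  }
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.resolved.yaml"))
  log_line("config hash %s, seed %d", config_hash(cfg), cfg$seed)
  hp <- config_hairpin_params(cfg)
  res <- list(config = cfg)

  if (any(c("simulate", "classify", "editing") %in% stages)) {
    ref <- make_reference(cfg$n_seqs, cfg$seq_length, seed = cfg$seed)
    res$reference <- ref
    if ("simulate" %in% stages) {
      write_reference_fasta(ref$sequences,
                            file.path(cfg$out_dir, "reference.fasta"))
      write_tsv(ref$truth, file.path(cfg$out_dir, "reference_truth.tsv"),
                provenance_header(cfg, "simulate"))
      log_line("simulate: %d sequences, %d planted hairpins",
               length(ref$sequences), nrow(ref$truth))
    }
  }

  if ("classify" %in% stages) {
    cohort <- simulate_tumor_cohort(res$reference, cfg$n_per_class, cfg$n_mut,
                                    list(w_loop = cfg$w_loop,
                                         w_motif = cfg$w_motif,
                                         background_rate = cfg$background_rate),
                                    seed = cfg$seed)
    profiles <- profile_tumors(cohort$catalogs, cohort$reference, hp,
                               cfg$window, cohort$tpc_annotation)
    labeled <- classify_tumors(profiles,
                               classification_thresholds(cfg$tau_burden,
                                                         cfg$tau_char,
                                                         cfg$tau_loop,
                                                         cfg$min_tpc))
    acc <- mean(labeled$label ==
                cohort$truth$true_label[match(labeled$tumor_id,
                                              cohort$truth$tumor_id)])
    write_tsv(labeled, file.path(cfg$out_dir, "tumor_profiles.tsv"),
              provenance_header(cfg, "classify"))
    log_line("classify: %d tumors, label accuracy %.3f vs planted truth",
             nrow(labeled), acc)
    res$classification <- list(profiles = labeled, truth = cohort$truth,
                               accuracy = acc)
  }

  if ("editing" %in% stages) {
    rna <- simulate_rna_editing_cohort(res$reference, cfg$n_hotspots,
                                       cfg$n_null_sites, cfg$rna_n_per_class,
                                       cfg$coverage_mean, cfg$error_rate,
                                       seed = cfg$seed)
    sites <- call_editing_sites(rna$rna_counts, rna$cohorts, rna$dna_calls,
                                rna$reference,
                                list(min_cov = cfg$min_cov,
                                     min_alt = cfg$min_alt,
                                     max_dna_vaf = cfg$max_dna_vaf,
                                     min_samples = cfg$min_samples),
                                cfg$fdr_q)
    write_tsv(as.data.frame(sites),
              file.path(cfg$out_dir, "editing_sites.tsv"),
              provenance_header(cfg, "editing"))
    log_line("editing: %d sites pass q <= %.3g (of %d tested)",
             nrow(sites), cfg$fdr_q, nrow(attr(sites, "all_sites")))
    strat <- stratify_by_hairpin(sites, rna$reference)
    write_tsv(strat, file.path(cfg$out_dir, "editing_stratification.tsv"),
              provenance_header(cfg, "editing"))
    if (nrow(sites) > 0L) {
      logo <- suppressWarnings(
        build_logogram(sites, rna$reference,
                       min(cfg$top_n, nrow(sites)), cfg$flank_k))
      write_tsv(as.data.frame(unclass(logo)),
                file.path(cfg$out_dir, "logogram.tsv"),
                provenance_header(cfg, "editing"))
      idx <- editing_index(rna$rna_counts,
                           sites[, c("sequence_id", "position")])
      write_tsv(idx, file.path(cfg$out_dir, "editing_index.tsv"),
                provenance_header(cfg, "editing"))
      corr <- correlate_editing_with_expression(idx, rna$expression, "A3A")
      log_line("editing: index-expression Spearman rho %.3f (p %.3g, n %d)",
               corr$rho, corr$p, corr$n)
      res$editing <- list(sites = sites, stratification = strat,
                          logogram = logo, index = idx, correlation = corr,
                          truth = rna$truth)
    } else {
      res$editing <- list(sites = sites, stratification = strat,
                          truth = rna$truth)
    }
  }

  if ("ddpcr" %in% stages) {
    if (is.null(wells)) stop_input("ddpcr stage requires a wells table or CSV")
    if (is.character(wells)) wells <- read_ddpcr_csv(wells)
    quant <- ddpcr_quantify(wells, cfg$droplet_volume, cfg$cutoff_droplets,
                            cfg$cutoff_conc, cfg$per_well)
    write_tsv(quant, file.path(cfg$out_dir, "ddpcr_quant.tsv"),
              provenance_header(cfg, "ddpcr"))
    log_line("ddpcr: %d sample(s), %d positive", nrow(quant),
             sum(quant$positive))
    res$ddpcr <- quant
  }
  invisible(res)
}
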