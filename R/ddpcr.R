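#' Poisson inversion of a positive-droplet count
#'
#' Templates partition into droplets following a Poisson distribution, so
#' the per-droplet mean occupancy is `lambda = -ln(1 - k/n)` where `k/n` is
#' the positive-droplet fraction; dividing by the droplet volume gives
#' copies per microliter. The confidence interval propagates the Wilson
#' binomial interval of `k/n` through the same transform (monotone, so the
#' endpoints map directly).
#'
#' @param k_pos positive droplets in the channel.
#' @param n_droplets accepted droplets (>= 1).
#' @param droplet_volume droplet volume in microliters (default 0.00085,
#'   i.e. 0.85 nL, the standard volume for the usual 20,000-droplet
#'   instrument).
#' @param conf confidence level (default 0.95).
#' @return list with `lambda`, `conc` (copies/uL), `conc_lower`,
#'   `conc_upper`, `k_pos`, `n_droplets`.
#' @examples
#' poisson_concentration(10000, 20000)   # lambda = ln 2 ~ 815.5 copies/uL
#' @export
poisson_concentration <- function(k_pos, n_droplets, droplet_volume = 0.00085,
                                  conf = 0.95) {
  if (n_droplets < 1L) stop_param("n_droplets must be >= 1")
  if (k_pos < 0L || k_pos > n_droplets)
    stop_input("k_pos must lie in [0, n_droplets]")
  if (droplet_volume <= 0) stop_param("droplet_volume must be positive")
  if (k_pos == n_droplets)
    abort("all droplets positive: concentration not estimable (saturation)",
          "saturation_error")
  p <- k_pos / n_droplets
  lambda <- -log1p(-p)
  w <- wilson_interval(k_pos, n_droplets, conf)
  list(lambda = lambda,
       conc = lambda / droplet_volume,
       conc_lower = -log1p(-w$lower) / droplet_volume,
       conc_upper = -log1p(-pmin(w$upper, 1 - 1e-12)) / droplet_volume,
       k_pos = as.integer(k_pos), n_droplets = as.integer(n_droplets))
}

#' Quantify a two-channel droplet well
#'
#' Inverts both channels (FAM = wild type, HEX = mutant/edited) and derives
#' the fractional abundance of the edited template,
#' `conc_mut / (conc_mut + conc_wt)`, with a delta-method confidence
#' interval. Double-positive droplets count in both channels, consistent
#' with independent Poisson loading of the two templates.
#'
#' @param well list or one-row data.frame with `n_droplets`, `n_fam_pos`,
#'   `n_hex_pos` and optionally `well_id`, `droplet_volume`.
#' @param droplet_volume droplet volume in microliters, used when the well
#'   does not carry one.
#' @param conf confidence level.
#' @return object of class `quant_result`: `conc_wt`, `conc_mut` (each with
#'   CI), `fractional_abundance` (+ CI, `NA` when undefined), `n_hex_pos`,
#'   `n_fam_pos`, `n_droplets`.
#' @export
quantify_well <- function(well, droplet_volume = 0.00085, conf = 0.95) {
  v <- if (!is.null(well$droplet_volume)) well$droplet_volume else droplet_volume
  n <- well$n_droplets
  wt <- poisson_concentration(well$n_fam_pos, n, v, conf)
  mut <- poisson_concentration(well$n_hex_pos, n, v, conf)
  fa <- fractional_abundance_from_counts(well$n_hex_pos, well$n_fam_pos, n,
                                         conf, allow_undefined = TRUE)
  structure(list(well_id = well$well_id %||% NA_character_,
                 conc_wt = wt$conc, conc_wt_lower = wt$conc_lower,
                 conc_wt_upper = wt$conc_upper,
                 conc_mut = mut$conc, conc_mut_lower = mut$conc_lower,
                 conc_mut_upper = mut$conc_upper,
                 fractional_abundance = fa$fraction,
                 fa_lower = fa$lower, fa_upper = fa$upper,
                 n_hex_pos = as.integer(well$n_hex_pos),
                 n_fam_pos = as.integer(well$n_fam_pos),
                 n_droplets = as.integer(n),
                 droplet_volume = v),
            class = "quant_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fractional abundance of the mutant template in a well
#'
#' `conc_mut / (conc_mut + conc_wt)` after Poisson inversion of both
#' channels. Swapping the channels maps the fraction to its complement.
#' Both channels at zero is an error (undefined), distinct from a genuine
#' zero fraction (no mutant, some wild type).
#'
#' @inheritParams quantify_well
#' @return list with `fraction`, `lower`, `upper`.
#' @export
fractional_abundance <- function(well, droplet_volume = 0.00085, conf = 0.95) {
  fractional_abundance_from_counts(well$n_hex_pos, well$n_fam_pos,
                                   well$n_droplets, conf,
                                   allow_undefined = FALSE)
}

fractional_abundance_from_counts <- function(k_mut, k_wt, n, conf = 0.95,
                                             allow_undefined = FALSE) {
  if (k_mut == n || k_wt == n)
    abort("saturated channel: fractional abundance not estimable",
          "saturation_error")
  if (k_mut == 0L && k_wt == 0L) {
    if (allow_undefined)
      return(list(fraction = NA_real_, lower = NA_real_, upper = NA_real_))
    abort("both channels empty: fractional abundance undefined",
          "undefined_abundance_error")
  }
  pm <- k_mut / n; pw <- k_wt / n
  lm <- -log1p(-pm); lw <- -log1p(-pw)
  f <- lm / (lm + lw)
  # Delta method: var(lambda) = p / ((1 - p) n) from the binomial variance
  # of p transformed through -ln(1 - p).
  vm <- pm / ((1 - pm) * n)
  vw <- pw / ((1 - pw) * n)
  tot <- lm + lw
  se <- sqrt((lw / tot^2)^2 * vm + (lm / tot^2)^2 * vw)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(fraction = f,
       lower = max(0, f - z * se),
       upper = min(1, f + z * se))
}

#' Positivity call for an edited-template measurement
#'
#' A sample is called positive only when both printed cutoffs hold: at
#' least `cutoff_droplets` HEX (mutant) positive droplets AND a mutant
#' concentration of at least `cutoff_conc` copies per microliter. Both
#' comparisons are inclusive.
#'
#' @param result a [quantify_well()] / [merge_replicates()] result.
#' @param cutoff_droplets minimum HEX-positive droplets (default 3).
#' @param cutoff_conc minimum mutant copies/uL (default 0.25).
#' @return logical flag.
#' @export
call_positivity <- function(result, cutoff_droplets = 3L, cutoff_conc = 0.25) {
  result$n_hex_pos >= cutoff_droplets && result$conc_mut >= cutoff_conc
}

#' Merge replicate wells of one sample
#'
#' Pools droplet and positive counts across wells and inverts once; with a
#' single well this is the identity. Wells must share a droplet volume.
#'
#' @param wells data.frame with one row per well: `n_droplets`,
#'   `n_fam_pos`, `n_hex_pos`, optional `droplet_volume`, `well_id`.
#' @inheritParams quantify_well
#' @return a `quant_result` for the pooled counts.
#' @export
merge_replicates <- function(wells, droplet_volume = 0.00085, conf = 0.95) {
  if (nrow(wells) < 1L) stop_param("at least one well required")
  v <- if ("droplet_volume" %in% names(wells)) wells$droplet_volume
       else rep(droplet_volume, nrow(wells))
  if (length(unique(v)) > 1L)
    stop_param("replicate wells have mixed droplet volumes")
  pooled <- list(well_id = paste(wells$well_id %||% "pooled", collapse = "+"),
                 n_droplets = sum(wells$n_droplets),
                 n_fam_pos = sum(wells$n_fam_pos),
                 n_hex_pos = sum(wells$n_hex_pos),
                 droplet_volume = v[1])
  quantify_well(pooled, conf = conf)
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result>%s %d droplets\n",
              if (!is.na(x$well_id)) paste0(" well ", x$well_id, ",") else "",
              x$n_droplets))
  cat(sprintf("  WT : %8.3f copies/uL (95%% CI %.3f-%.3f), %d FAM+\n",
              x$conc_wt, x$conc_wt_lower, x$conc_wt_upper, x$n_fam_pos))
  cat(sprintf("  mut: %8.3f copies/uL (95%% CI %.3f-%.3f), %d HEX+\n",
              x$conc_mut, x$conc_mut_lower, x$conc_mut_upper, x$n_hex_pos))
  if (!is.na(x$fractional_abundance))
    cat(sprintf("  fractional abundance: %.4f (95%% CI %.4f-%.4f)\n",
                x$fractional_abundance, x$fa_lower, x$fa_upper))
  else cat("  fractional abundance: undefined (both channels empty)\n")
  invisible(x)
}

#' Quantify a table of droplet wells, merging replicates per sample
#'
#' @param wells data.frame with `well_id`, `sample_id`, `n_droplets`,
#'   `n_fam_pos`, `n_hex_pos` (e.g. from [read_ddpcr_csv()]).
#' @inheritParams quantify_well
#' @inheritParams call_positivity
#' @param per_well apply the positivity cutoffs per well instead of per
#'   merged sample (default FALSE: cutoffs act on the pooled counts).
#' @return data.frame with one row per sample: concentrations, fractional
#'   abundance, pooled `n_hex_pos`, and `positive` flag.
#' @export
ddpcr_quantify <- function(wells, droplet_volume = 0.00085,
                           cutoff_droplets = 3L, cutoff_conc = 0.25,
                           per_well = FALSE, conf = 0.95) {
  need <- c("sample_id", "n_droplets", "n_fam_pos", "n_hex_pos")
  if (!all(need %in% names(wells)))
    stop_input(paste("wells must have columns:", paste(need, collapse = ", ")))
  rows <- lapply(split(wells, wells$sample_id), function(w) {
    qr <- merge_replicates(w, droplet_volume, conf)
    pos <- if (per_well) {
      all(vapply(seq_len(nrow(w)), function(i) {
        call_positivity(quantify_well(w[i, ], droplet_volume, conf),
                        cutoff_droplets, cutoff_conc)
      }, logical(1)))
    } else {
      call_positivity(qr, cutoff_droplets, cutoff_conc)
    }
    data.frame(sample_id = w$sample_id[1],
               n_wells = nrow(w),
               n_droplets = qr$n_droplets,
               n_fam_pos = qr$n_fam_pos, n_hex_pos = qr$n_hex_pos,
               conc_wt = qr$conc_wt, conc_wt_lower = qr$conc_wt_lower,
               conc_wt_upper = qr$conc_wt_upper,
               conc_mut = qr$conc_mut, conc_mut_lower = qr$conc_mut_lower,
               conc_mut_upper = qr$conc_mut_upper,
               fractional_abundance = qr$fractional_abundance,
               fa_lower = qr$fa_lower, fa_upper = qr$fa_upper,
               positive = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
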