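# A tiny deterministic reference shared across these tests.
sig_ref <- local({
  set.seed(99)
  make_reference(n_seqs = 1, length = 3000, seed = 99)
})

test_that("apobec_burden counts TpC C>T/C>G on the pyrimidine strand", {
  ref <- c(chr = "AATCAAATCAAATCAAATCAAATCAGGGGGAA")
  # all ten SNVs C>T at a TCA context
  pos <- c(3, 8, 13, 18, 23)
  snvs <- data.frame(sequence_id = "chr", position = c(pos, pos),
                     ref = "C", alt = rep(c("T", "G"), each = 5))
  snvs <- snvs[!duplicated(paste(snvs$position, snvs$alt)), ]
  cc <- mutation_catalog(snvs, ref)
  b <- apobec_burden(cc, ref)
  expect_equal(b$tpc_fraction, 1.0)
  expect_equal(b$n_tpc, 10L)

  # zero C>T/C>G events
  snvs2 <- data.frame(sequence_id = "chr", position = c(0, 1),
                      ref = c("A", "A"), alt = c("G", "T"))
  expect_equal(apobec_burden(mutation_catalog(snvs2, ref), ref)$tpc_fraction, 0)

  # minus-strand TpC: G with 3' A reads as TpC on the reverse complement
  ref2 <- c(chr = "AAATGAAAAA")
  snv3 <- data.frame(sequence_id = "chr", position = 4, ref = "G", alt = "A")
  expect_equal(apobec_burden(mutation_catalog(snv3, ref2), ref2)$n_tpc, 1L)

  expect_error(apobec_burden(mutation_catalog(snvs2[0, ], ref), ref),
               class = "apobecedit_undefined_burden_error")
})

test_that("a constructed 120/200 TpC catalog gives burden 0.6", {
  ref <- c(chr = paste0(strrep("ATCAG", 200), strrep("AAGGA", 200)))
  tpc_pos <- seq(2, by = 5, length.out = 120)       # the C of each ATCAG
  non_pos <- 1000 + seq(0, by = 5, length.out = 80) # A's in the AAGGA half
  snvs <- rbind(
    data.frame(sequence_id = "chr", position = tpc_pos, ref = "C", alt = "T"),
    data.frame(sequence_id = "chr", position = non_pos, ref = "A", alt = "G"))
  b <- apobec_burden(mutation_catalog(snvs, ref), ref)
  expect_equal(b$n_snvs, 200L)
  expect_equal(b$tpc_fraction, 0.6)
})

test_that("mutation_catalog validates ref alleles against the reference", {
  ref <- c(chr = "AATCAA")
  expect_error(mutation_catalog(data.frame(sequence_id = "chr", position = 3,
                                           ref = "G", alt = "A"), ref),
               class = "apobecedit_input_error")
  expect_error(mutation_catalog(data.frame(sequence_id = "nope", position = 1,
                                           ref = "A", alt = "G"), ref),
               class = "apobecedit_missing_reference_error")
})

test_that("planted A3A and A3B catalogs show their expected character", {
  ann <- annotate_tpc_sites(sig_ref$sequences, max_sites = .Machine$integer.max)
  a3a <- simulate_mutation_catalog(sig_ref$sequences, "A3A", n_mut = 400,
                                   seed = 5, tpc_annotation = ann)$catalog
  a3b <- simulate_mutation_catalog(sig_ref$sequences, "A3B", n_mut = 400,
                                   seed = 6, tpc_annotation = ann)$catalog
  ca <- a3a_a3b_character(a3a, sig_ref$sequences, tpc_annotation = ann)
  cb <- a3a_a3b_character(a3b, sig_ref$sequences, tpc_annotation = ann)
  expect_gt(ca$ytca_fraction, ca$rtca_fraction)
  expect_gt(ca$loop_enrichment, 1)
  expect_gt(cb$rtca_fraction, cb$ytca_fraction)
  expect_lt(abs(cb$loop_enrichment - 1), 0.3)
})

test_that("a uniform sample of reference TpC sites has loop enrichment 1", {
  ann <- annotate_tpc_sites(sig_ref$sequences, max_sites = .Machine$integer.max)
  # use every TpC site as the catalog: numerator and denominator coincide
  plus <- ann[ann$strand == "+", ]
  snvs <- data.frame(sequence_id = plus$sequence_id, position = plus$position,
                     ref = "C", alt = "T")
  cc <- mutation_catalog(snvs, sig_ref$sequences)
  ch <- a3a_a3b_character(cc, sig_ref$sequences, tpc_annotation = ann)
  expect_equal(ch$loop_fraction, mean(plus$in_loop))
  expect_lt(abs(ch$loop_enrichment - 1), 0.1)
})

test_that("classification follows the threshold rule and partitions labels", {
  prof <- data.frame(
    tumor_id = c("low_burden", "loop_marked", "ytca", "rtca", "few_tpc"),
    n_snvs = 500, n_tpc = c(200, 200, 200, 200, 5),
    tpc_fraction = c(0.02, 0.4, 0.4, 0.4, 0.5),
    ytca_fraction = c(0.3, 0.2, 0.5, 0.1, 0.3),
    rtca_fraction = c(0.1, 0.2, 0.1, 0.5, 0.1),
    loop_fraction = 0.5,
    loop_enrichment = c(1.0, 2.0, 1.0, 1.0, 1.0))
  lab <- classify_tumors(prof)
  expect_equal(lab$label,
               c("APOBEC-", "A3A+", "A3A+", "A3B+", "APOBEC-"))
  expect_true(all(lab$label %in% c("A3A+", "A3B+", "APOBEC-")))
  expect_error(classify_tumors(prof, list(tau_burden = 1.5)),
               class = "apobecedit_parameter_error")
})

test_that("profiles are invariant to catalog row order", {
  ann <- annotate_tpc_sites(sig_ref$sequences, max_sites = .Machine$integer.max)
  cc <- simulate_mutation_catalog(sig_ref$sequences, "A3A", n_mut = 100,
                                  seed = 3, tpc_annotation = ann)$catalog
  p1 <- profile_tumors(cc, sig_ref$sequences, tpc_annotation = ann)
  shuffled <- cc[rev(seq_len(nrow(cc))), ]
  class(shuffled) <- class(cc)
  p2 <- profile_tumors(shuffled, sig_ref$sequences, tpc_annotation = ann)
  expect_equal(p1, p2)
})

test_that("profiles are invariant under reverse-complementing the reference", {
  ref <- sig_ref$sequences[1]
  L <- nchar(ref)
  ann <- annotate_tpc_sites(ref, max_sites = .Machine$integer.max)
  cc <- simulate_mutation_catalog(ref, "A3A", n_mut = 60, seed = 4,
                                  tpc_annotation = ann)$catalog
  p1 <- profile_tumors(cc, ref, tpc_annotation = ann)

  ref_rc <- ref
  ref_rc[1] <- revcomp(ref[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  snvs_rc <- data.frame(sequence_id = cc$sequence_id,
                        position = L - 1L - cc$position,
                        ref = unname(comp[cc$ref]),
                        alt = unname(comp[cc$alt]))
  cc_rc <- mutation_catalog(snvs_rc, ref_rc)
  ann_rc <- annotate_tpc_sites(ref_rc, max_sites = .Machine$integer.max)
  p2 <- profile_tumors(cc_rc, ref_rc, tpc_annotation = ann_rc)
  for (col in c("n_tpc", "tpc_fraction", "ytca_fraction", "rtca_fraction",
                "loop_fraction", "loop_enrichment")) {
    expect_equal(p1[[col]], p2[[col]], info = col)
  }
})

test_that("spearman machinery: identities, oracle agreement, error conditions", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)        # monotone link
  expect_equal(spearman_cor(x, -x)$rho, -1)

  set.seed(21)
  a <- rnorm(100); b <- a + rnorm(100, 0, 0.8)
  got <- spearman_cor(a, b)
  expect_equal(got$rho, oracle_spearman_rho(a, b), tolerance = 1e-12)
  expect_lt(got$p, 0.05)

  expect_error(spearman_cor(c(1, 2), c(3, 4)),
               class = "apobecedit_insufficient_data_error")
  expect_error(spearman_cor(rep(1, 10), rnorm(10)),
               class = "apobecedit_undefined_correlation_error")
})

test_that("burden-expression correlation joins on sample id", {
  prof <- data.frame(tumor_id = sprintf("t%d", 1:30),
                     tpc_fraction = seq(0.01, 0.30, by = 0.01))
  expr <- data.frame(sample_id = sprintf("t%d", 1:30),
                     A3A = seq(0.01, 0.30, by = 0.01)^2)
  r <- burden_expression_correlation(prof, expr, "A3A")
  expect_equal(r$rho, 1)
  expect_error(burden_expression_correlation(prof, expr, "A3B"),
               class = "apobecedit_input_error")
  expect_error(
    burden_expression_correlation(prof[1:2, ], expr[1:2, ], "A3A"),
    class = "apobecedit_insufficient_data_error")
})
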