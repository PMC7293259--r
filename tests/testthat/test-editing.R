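test_that("editing_fraction matches the Wilson interval and errors cleanly", {
  expect_equal(editing_fraction(0, 100)$fraction, 0)
  expect_equal(editing_fraction(50, 100)$fraction, 0.5)
  ef <- editing_fraction(8, 100)
  expect_equal(ef$fraction, 0.08)
  expect_gt(ef$lower, 0.03)
  expect_lt(ef$upper, 0.16)
  # frozen Wilson endpoints computed from the closed form by hand
  z <- qnorm(0.975); p <- 0.08; n <- 100
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(ef$lower, centre - half)
  expect_equal(ef$upper, centre + half)
  expect_error(editing_fraction(1, 0),
               class = "apobecedit_undefined_fraction_error")
  expect_error(editing_fraction(5, 4), class = "apobecedit_input_error")
})

test_that("a planted high-editing hotspot ranks first and DNA-mutated sites drop", {
  toy <- toy_rna_counts(list(
    list(seq_id = "tx", pos = 10, cov = 100, alt_a3a = 8, alt_null = 0),
    list(seq_id = "tx", pos = 30, cov = 100, alt_a3a = 4, alt_null = 0),
    list(seq_id = "tx", pos = 50, cov = 100, alt_a3a = 0, alt_null = 0),
    list(seq_id = "tx", pos = 70, cov = 100, alt_a3a = 40, alt_null = 38),
    list(seq_id = "tx", pos = 90, cov = 100, alt_a3a = 30, alt_null = 0)))
  # site 90 has a DNA mutation (VAF 0.5) in one sample: must be excluded
  dna <- data.frame(sample_id = "A01", sequence_id = "tx",
                    position = c(10, 30, 50, 70, 90),
                    vaf = c(0, 0, 0, 0, 0.5))
  sites <- call_editing_sites(toy$rna_counts, toy$cohorts, dna)
  expect_false(90 %in% sites$position)
  expect_false(70 %in% sites$position)  # equally edited in the null cohort
  expect_false(50 %in% sites$position)  # no edited reads
  expect_equal(sites$position[1], 10)   # ranked by A3A+ editing fraction
  expect_equal(sites$editing_a3a[1], 8 / 100)
  expect_true(all(sites$q <= 0.05))
})

test_that("site discovery demands a null cohort and unique rows", {
  toy <- toy_rna_counts(list(
    list(seq_id = "tx", pos = 10, cov = 50, alt_a3a = 5, alt_null = 0)))
  all_a3a <- toy$cohorts; all_a3a$cohort <- "A3A+"
  expect_error(call_editing_sites(toy$rna_counts, all_a3a),
               class = "apobecedit_no_null_cohort_error")
  dup <- rbind(toy$rna_counts, toy$rna_counts[1, ])
  expect_error(call_editing_sites(dup, toy$cohorts),
               class = "apobecedit_input_integrity_error")
})

test_that("lowering the FDR threshold never adds sites", {
  rna <- simulate_rna_editing_cohort(seed = 8)
  s1 <- call_editing_sites(rna$rna_counts, rna$cohorts, rna$dna_calls,
                           fdr_q = 0.05)
  s2 <- call_editing_sites(rna$rna_counts, rna$cohorts, rna$dna_calls,
                           fdr_q = 0.01)
  k1 <- paste(s1$sequence_id, s1$position)
  k2 <- paste(s2$sequence_id, s2$position)
  expect_true(all(k2 %in% k1))
})

test_that("logogram columns are normalized frequencies of the top-site flanks", {
  # all sites share a CATC flank ending at the edited C
  ref <- c(tx = paste0(strrep("G", 3), paste(rep("ACATCGG", 8), collapse = ""),
                       "AAA"))
  pos <- 3 + seq(0, by = 7, length.out = 8) + 4  # each planted C (0-based)
  tab <- data.frame(sequence_id = "tx", position = pos,
                    editing_a3a = seq(0.9, 0.2, length.out = 8))
  logo <- build_logogram(tab, ref, top_n = 8, flank_k = 3)
  expect_equal(unname(colSums(logo)), rep(1, 7), tolerance = 1e-9)
  expect_equal(unname(logo["C", "0"]), 1)
  expect_equal(unname(logo["C", "-3"]), 1)
  expect_equal(unname(logo["A", "-2"]), 1)
  expect_equal(unname(logo["U", "-1"]), 1)
  expect_warning(build_logogram(tab, ref, top_n = 20, flank_k = 3),
                 "only 8 sites")
  expect_error(build_logogram(tab, ref, top_n = 20, flank_k = 3,
                              strict = TRUE),
               class = "apobecedit_input_error")
})

test_that("logogram of random flanks is near-uniform with columns summing to 1", {
  set.seed(15)
  ref <- c(tx = random_seq(4000))
  ch <- strsplit(ref[[1]], "")[[1]]
  cpos <- which(ch == "C") - 1
  cpos <- cpos[cpos > 10 & cpos < 3990]
  pos <- sample(cpos, 50)
  tab <- data.frame(sequence_id = "tx", position = pos,
                    editing_a3a = runif(50))
  logo <- build_logogram(tab, ref, top_n = 50, flank_k = 5)
  expect_equal(unname(colSums(logo)), rep(1, 11), tolerance = 1e-9)
  expect_equal(unname(logo["C", "0"]), 1)       # centre is always the edited C
  off <- unclass(logo)[, colnames(logo) != "0"]
  expect_true(all(abs(off - 0.25) < 0.25))
})

test_that("hairpin stratification bins by loop size and position", {
  # structure-free sites collapse into a single 'none' bin
  ref <- c(tx = paste0(strrep("A", 30), "TC", strrep("A", 30)))
  tab <- data.frame(sequence_id = "tx", position = c(31, 31),
                    editing_a3a = c(0.1, 0.3))
  tab <- tab[1, ]
  s <- stratify_by_hairpin(tab, ref)
  expect_equal(s$loop_bin, "none")
  expect_equal(s$n_sites, 1L)

  # planted geometry: loop-4 site hotter than loop-3 site
  arm <- "GCGGCC"
  ref2 <- c(tx = paste0(strrep("A", 10), arm, "CATC", revcomp(arm),
                        strrep("A", 10), arm, "TTC", revcomp(arm),
                        strrep("A", 10)))
  p4 <- 10 + 6 + 3          # edited C of CATC
  p3 <- 10 + 6 + 4 + 6 + 10 + 6 + 2  # edited C of TTC
  tab2 <- data.frame(sequence_id = "tx", position = c(p4, p3),
                     editing_a3a = c(0.08, 0.05))
  s2 <- stratify_by_hairpin(tab2, ref2)
  expect_setequal(s2$loop_bin, c("3", "4"))
  best <- s2[which.max(s2$mean_editing), ]
  expect_equal(best$loop_bin, "4")
  expect_equal(best$site_loop_position, 4L)
})

test_that("editing index pools counts and is invariant to row splitting", {
  counts <- data.frame(
    sample_id = c("s1", "s1", "s2", "s3"),
    sequence_id = "tx", position = c(10, 20, 10, 10),
    ref_reads = c(90, 100, 100, 70), alt_reads = c(10, 0, 0, 30))
  panel <- data.frame(sequence_id = "tx", position = c(10, 20))
  idx <- editing_index(counts, panel)
  expect_equal(idx$index[idx$sample_id == "s1"], 0.05)  # (10+0)/(100+100)
  expect_equal(idx$index[idx$sample_id == "s2"], 0)
  expect_equal(idx$index[idx$sample_id == "s3"], 0.30)

  # splitting s1's site-10 counts across two rows changes nothing
  split <- rbind(counts[-1, ],
                 data.frame(sample_id = "s1", sequence_id = "tx",
                            position = 10, ref_reads = 45, alt_reads = 5),
                 data.frame(sample_id = "s1", sequence_id = "tx",
                            position = 10, ref_reads = 45, alt_reads = 5))
  idx2 <- editing_index(split, panel)
  expect_equal(sort(idx2$index), sort(idx$index))

  # row order invariance
  idx3 <- editing_index(counts[sample(1:4), ], panel)
  expect_equal(idx3[order(idx3$sample_id), "index"],
               idx[order(idx$sample_id), "index"])

  expect_error(editing_index(counts, panel[0, ]),
               class = "apobecedit_parameter_error")
})

test_that("editing-expression correlation is monotone-invariant", {
  idx <- data.frame(sample_id = sprintf("s%d", 1:20),
                    index = seq(0.01, 0.2, by = 0.01), defined = TRUE)
  expr <- data.frame(sample_id = sprintf("s%d", 1:20),
                     A3A = log(seq(0.01, 0.2, by = 0.01)))
  r <- correlate_editing_with_expression(idx, expr, "A3A")
  expect_equal(r$rho, 1)
  expect_lt(r$p, 1e-6)
})
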