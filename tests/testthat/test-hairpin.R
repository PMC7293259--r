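test_that("tetranucleotide context distinguishes YTCA from RTCA and flags TpC", {
  ytca <- tetranucleotide_context("AACTCAGG", 4)
  expect_equal(ytca$tetranucleotide, "CTCA")
  expect_equal(ytca$character, "YTCA-like")
  expect_true(ytca$is_tpc)
  expect_false(ytca$strand_normalized)

  rtca <- tetranucleotide_context("AAGTCAGG", 4)
  expect_equal(rtca$character, "RTCA-like")

  other <- tetranucleotide_context("AAGACAGG", 4)  # ACAG window: not TpC
  expect_equal(other$character, "other")
  expect_false(other$is_tpc)

  rna <- tetranucleotide_context("AACTCAGG", 4, alphabet = "RNA")
  expect_equal(rna$tetranucleotide, "CUCA")
})

test_that("G-strand sites are strand-normalized to the identical C-strand call", {
  s <- "AACTCAGGTT"
  fwd <- tetranucleotide_context(s, 4)
  rc <- revcomp(s)
  back <- tetranucleotide_context(rc, nchar(s) - 1 - 4)
  expect_equal(back$ref_base, "G")
  expect_true(back$strand_normalized)
  expect_equal(back$tetranucleotide, fwd$tetranucleotide)
  expect_equal(back$character, fwd$character)
})

test_that("context extraction errors on edges and non-C/G sites", {
  expect_error(tetranucleotide_context("TCAGGA", 1),
               class = "apobecedit_context_unavailable_error")
  expect_error(tetranucleotide_context("ACTC", 3),
               class = "apobecedit_context_unavailable_error")
  expect_error(tetranucleotide_context("AACTCAGG", 3),
               class = "apobecedit_invalid_site_error")
  expect_error(tetranucleotide_context("AACTCAGG", 99),
               class = "apobecedit_parameter_error")
})

test_that("stem strength sums per-pair scores", {
  expect_equal(stem_strength("GC", "GC"), 6)
  expect_equal(stem_strength("", ""), 0)
  # NUP93 7-bp stem: per-pair summation gives 4 G:C (x3) + 3 A:T (x2) = 18
  arm5 <- strsplit("GCAAGCT", "")[[1]]
  arm3 <- strsplit("AGCTTGC", "")[[1]]
  by_hand <- sum(vapply(1:7, function(i) {
    pr <- paste0(arm5[i], arm3[8 - i])
    if (pr %in% c("GC", "CG")) 3 else if (pr %in% c("AT", "TA")) 2 else 0
  }, numeric(1)))
  expect_equal(by_hand, 18)
  expect_equal(stem_strength("GCAAGCT", "AGCTTGC"), by_hand)
  # order independence: reversing both arms preserves the score
  expect_equal(stem_strength("TCGAAGC", "GCTTCGA"), by_hand)
  expect_error(stem_strength("GC", "GG"),
               class = "apobecedit_invalid_stem_error")
  expect_error(stem_strength("GCA", "GC"),
               class = "apobecedit_invalid_stem_error")
  # G:U only pairs when wobble is enabled
  expect_error(stem_strength("GGG", "UUU"),
               class = "apobecedit_invalid_stem_error")
  expect_equal(stem_strength("GGG", "UUU", allow_GU = TRUE), 3)
})

test_that("best_hairpin reproduces the printed oligos", {
  # NUP93 21-mer: 7-bp stem around a 4-nt GTTC loop, site C at the 3'-most
  # loop position
  nup <- best_hairpin("GCAAGCTGTTCAGCTTGCTGA", 10)
  expect_equal(nup$stem_length, 7L)
  expect_equal(nup$loop_length, 4L)
  expect_equal(nup$site_loop_position, 4L)
  expect_equal(nup$stem_strength, 18)
  expect_equal(nup$loop_start, 7L)
  expect_equal(nup$arm5_span, c(0L, 7L))
  expect_equal(nup$arm3_span, c(11L, 18L))

  # structure-free polyA-TC oligo
  poly <- best_hairpin("AAAAAAAAATCGGGAAAAAAA", 10)
  expect_equal(poly$stem_length, 0L)
  expect_true(is.na(poly$loop_length))
  expect_equal(poly$stem_strength, 0)
})

test_that("a CAUC 4-nt loop closed by a C:G stem calls the edited C 3'-most", {
  arm5 <- "GCGGC"
  hp <- best_hairpin(paste0(arm5, "CAUC", revcomp(arm5, rna = TRUE)), 8,
                     hairpin_params(allow_GU = TRUE))
  expect_equal(hp$loop_length, 4L)
  expect_equal(hp$site_loop_position, 4L)
  expect_equal(hp$stem_length, 5L)
})

test_that("hairpin parameters are validated", {
  expect_error(hairpin_params(min_stem = 0), class = "apobecedit_parameter_error")
  expect_error(hairpin_params(min_loop = 5, max_loop = 4),
               class = "apobecedit_parameter_error")
  expect_error(hairpin_params(pair_scores = c(GC = -1, AT = 2, GU = 1)),
               class = "apobecedit_parameter_error")
})

test_that("best_hairpin agrees with exhaustive enumeration on random sequences", {
  set.seed(42)
  for (i in 1:150) {
    n <- sample(15:40, 1)
    s <- random_seq(n)
    site <- sample(0:(n - 1), 1)
    gu <- i %% 3 == 0
    got <- best_hairpin(s, site, hairpin_params(allow_GU = gu))
    want <- oracle_best_hairpin(s, site, allow_GU = gu)
    if (is.null(want)) {
      expect_equal(got$stem_length, 0L, info = paste(s, site))
    } else {
      expect_equal(got$stem_length, want$stem_length, info = paste(s, site))
      expect_equal(got$loop_length, want$loop_length, info = paste(s, site))
      expect_equal(got$stem_strength, want$strength, info = paste(s, site))
      expect_equal(got$site_loop_position, want$site_loop_position,
                   info = paste(s, site))
    }
  }
})

test_that("swapping an A:T stem pair for G:C never decreases stem strength", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(3:8, 1)
    arm5 <- sample(c("A", "G"), k, replace = TRUE)
    arm3 <- rev(ifelse(arm5 == "A", "T", "C"))  # reverse complement, as vector
    s0 <- stem_strength(paste(arm5, collapse = ""), paste(arm3, collapse = ""))
    at <- which(arm5 == "A")
    if (!length(at)) next
    j <- at[1]
    arm5[j] <- "G"; arm3[k + 1 - j] <- "C"
    s1 <- stem_strength(paste(arm5, collapse = ""), paste(arm3, collapse = ""))
    expect_gte(s1, s0)
  }
})

test_that("best_hairpin is reverse-complement invariant with mirrored site", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(20:40, 1)
    s <- random_seq(n)
    site <- sample(0:(n - 1), 1)
    a <- best_hairpin(s, site)
    b <- best_hairpin(revcomp(s), n - 1 - site)
    expect_equal(a$stem_length, b$stem_length)
    expect_equal(a$stem_strength, b$stem_strength)
    if (a$stem_length > 0) {
      expect_equal(a$loop_length, b$loop_length)
      expect_equal(b$site_loop_position,
                   a$loop_length + 1L - a$site_loop_position)
    }
  }
})

test_that("homopolymers with an embedded TC are structure-free", {
  for (base in c("A", "C", "G", "T")) {
    s <- paste0(strrep(base, 12), "TC", strrep(base, 12))
    expect_equal(best_hairpin(s, 13)$stem_length, 0L)
  }
})

test_that("hairpin_annotate writes 1-based positions with context columns", {
  seqs <- c(hp = "GCAAGCTGTTCAGCTTGCTGA")
  ann <- hairpin_annotate(seqs, data.frame(sequence_id = "hp", position = 10))
  expect_equal(ann$position, 11L)
  expect_equal(ann$stem_length, 7L)
  expect_equal(ann$site_loop_position, 4L)
  expect_equal(ann$tetranucleotide, "TTCA")
  expect_equal(ann$character, "YTCA-like")
  expect_error(hairpin_annotate(seqs, data.frame(sequence_id = "nope",
                                                 position = 1)),
               class = "apobecedit_missing_reference_error")
})
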