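---
title: "Methods: models, parameters, and design choices in apobecedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in apobecedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apobecedit)
```

This vignette is the package's own account of its models: what each stage
assumes, which parameters matter and why they default to the values they
do, what the synthetic-data generators emulate (and what they deliberately
do not), and where a genuinely open design choice was made.

## The hairpin model

APOBEC3A deaminates cytosines exposed in the loops of DNA and RNA
stem-loops; APOBEC3B shows no such structural preference. `best_hairpin()`
therefore asks, for a query nucleotide: among all hairpin placements whose
loop contains the site, which has the strongest stem?

The model is intentionally combinatorial, not thermodynamic:

* **Perfect contiguous stems only.** Arms pair base by base with no bulges,
  internal loops, or mismatches. A hairpin is a triple (loop length
  3–11 nt, stem 3–12 bp, placement), and stems grow outward from the loop
  until the first non-pairing position. Truncating pairing runs longer
  than `max_stem` at the 12 pairs nearest the loop keeps the search
  bounded; stems of that depth are already far beyond what the scoring can
  distinguish.
* **Stem strength** is the sum of per-pair scores: G:C = 3, A:T/U = 2,
  G:U = 1 (wobble pairs participate only when `allow_GU = TRUE`, the
  sensible setting for RNA). The 3/2/1 ladder is a hydrogen-bond-count
  proxy for pairing stability — a deliberate simplification chosen for
  testability: every value the search returns can be re-derived by
  exhaustive enumeration, which the test suite does on hundreds of random
  sequences. It is not a free-energy model; see Limitations.
* **Deterministic tie-breaking**: maximize stem strength, then prefer the
  smaller loop, then the 5′-most arm. Equal-strength ties are common in
  short windows, and a fixed order makes every downstream table
  reproducible. On the two reference oligos used as worked examples — a
  natural NUP93 hairpin and a structure-free polyA control — strength-first
  and length-first orderings agree.
* **Windowing.** Profiling stages hand the search a ±25 nt window around
  each site. 25 nt accommodates the largest representable hairpin
  (12 + 11 + 12 = 35 nt, asymmetric placements included) while keeping the
  per-site search constant-time.

Loop positions are reported 1-based with 1 = 5′-most, so "the 3′-most
position of a 4-nt loop" — the optimal A3A geometry — is position 4. For
odd loops the editing-optimal geometry is stated in the literature as the
U of the UpC centered in the loop, which for a 4-nt CAUC loop coincides
with the edited C sitting 3′-most; the package reports raw positions and
leaves interpretation to the stratification table, so no convention for
"center" of an even loop is ever needed.

Internally all coordinates are 0-based half-open; 1-based coordinates
appear only at the VCF boundary and in human-facing TSV output. This is
asserted in the I/O tests.

## Tumor classification

Per tumor, three axes are computed from the somatic SNV catalog:

* **TpC burden** — the fraction of SNVs that are C→T or C→G with a T
  immediately 5′ on the pyrimidine strand. Both deamination outcomes
  count; no TCW restriction is applied (the context classifier already
  separates YTCA from RTCA, so further restriction would only discard
  signal).
* **Character** — among TpC mutations, the fractions in YTCA (A3A-like)
  and RTCA (A3B-like) tetranucleotide context, strand-normalized.
* **Loop enrichment** — the fraction of TpC mutations whose site sits in a
  hairpin loop, divided by the same fraction over the reference's own TpC
  sites (all of them, or a seeded uniform sample of 10,000 when the
  reference is large). Using the reference's own sites as background makes
  the statistic self-calibrating: a tumor whose mutations are a uniform
  draw from TpC sites has enrichment 1 by construction.

The label rule is a small decision list with explicit thresholds, defaults
`tau_burden = 0.10`, `min_tpc = 10`, `tau_char = 0.6`, `tau_loop = 1.5`:
below the burden thresholds a tumor is APOBEC−; otherwise A3A+ if the YTCA
share of combined character reaches 0.6 *or* loop enrichment reaches 1.5
(either A3A fingerprint suffices — the loop preference marks A3A even when
the motif balance is ambiguous); otherwise A3B+ by the mirrored character
test; remaining tumors take the larger character fraction, ties resolving
to A3B+ because loop enrichment has already had its chance to mark A3A.
The rule is deterministic given thresholds, and thresholds are plain
config values rather than fitted quantities: the aim is a reproducible,
tunable classifier whose planted-cohort behaviour can be tested exactly,
not a reconstruction of any particular clustering. On the default
synthetic cohort (150 tumors) it recovers planted labels at ~96%; the
residual errors are background tumors whose uniform mutations happen to
exceed the burden threshold — a real feature of a hard threshold on a
binomial fraction, not a bug.

## RNA-editing hotspot discovery

Candidate sites are transcript-strand cytosines. Three filters precede any
testing, defaults in parentheses:

* **DNA absence** (`max_dna_vaf = 0`): a site with DNA variant-allele
  fraction above the cutoff in *any* DNA-covered sample is discarded. The
  strict zero default encodes the defining property of editing — the
  mutation exists in RNA only; it is configurable for noisy DNA calls.
* **Support** (`min_cov = 10`, `min_alt = 2`, `min_samples = 2`): at least
  two A3A+ samples must individually show ≥ 2 edited reads at ≥ 10×
  coverage. This kills the dominant false-positive mode — a single sample
  contributing a stray error read to the pooled counts.
* Exact duplicate (sample, site) rows are an input-integrity error, not
  silently aggregated.

Surviving sites are tested with a one-sided Fisher exact test on the
cohort-aggregated 2×2 table (edited/reference reads, A3A+ vs APOBEC−) and
corrected with Benjamini–Hochberg across tested sites. The exact test was
chosen over a rate model for validity at the small edited-read counts the
few-percent editing regime produces. Aggregating counts across samples
before testing weights samples by coverage; the per-sample support filter
prevents one deep sample from carrying a site alone.

The per-sample **editing index** over a hotspot panel is the pooled ratio
Σalt/Σtotal, not the mean of per-site fractions — a low-coverage site
contributes little information and should contribute little weight.
Samples with zero panel coverage are flagged undefined rather than set
to 0. The index–expression association uses Spearman rank correlation
(exact p for n ≤ 9 without ties, t-approximation otherwise), shared with
the burden–expression check; rank correlation is the right invariance
class because the editing–expression link has no reason to be linear.

## ddPCR quantification

With templates Poisson-distributed over droplets, the only estimable
quantity per channel is the zero-class probability, giving
λ = −ln(1 − k/n) copies per droplet. The droplet volume defaults to
0.85 nL (0.00085 µL), the standard partition volume of the common
20,000-droplet instrument, and is exposed in config since instruments
differ. Double-positive droplets count in both channels, consistent with
independent Poisson loading of the two templates.

Interval choices favour closed forms that tests can verify: the binomial
Wilson score interval on k/n, mapped through the monotone transform
−ln(1 − p)/v for concentrations, and a delta-method interval for the
fractional abundance λm/(λm + λw). Simulation at the study scale
(200 wells × 20,000 droplets) shows coverage within a point or two of
nominal 95%. A fully positive channel is a saturation error — the
concentration is genuinely not estimable — and both channels empty makes
the fractional abundance undefined, which is deliberately distinct from a
true zero (no mutant but measurable wild type).

Positivity uses two cutoffs conjointly: ≥ 3 HEX-positive droplets *and*
≥ 0.25 mutant copies/µL, both inclusive. AND is the conservative reading
of a two-part cutoff and is configurable. Replicate wells are merged by
pooling raw droplet counts and inverting once — Poisson counts are
additive, so this is the sufficient-statistic aggregation and reduces to
the identity for a single well. By default the cutoffs apply to the merged
sample (per-well behaviour sits behind a flag): the droplet cutoff exists
to rule out isolated fluorescence artifacts, and pooled replicates are the
natural unit in which to count them.

## What the generators emulate — and what they do not

The synthetic cohort is the package's ground truth and its defaults are
fixed study conditions, not tuning knobs.

* **Reference** (`make_reference()`): 4 sequences × 8,000 nt of uniform
  random backbone with planted perfect hairpins per sequence — 3× (7-bp
  stem, CAUC loop), 2× (6-bp stem, UUC loop), 2× (6-bp stem, AAUCA loop),
  written in DNA letters. The loop set covers the 3/4/5-nt geometries with
  the editing-optimal CAUC motif present; AAUCA was chosen for the 5-nt
  class because its loop ends cannot pair with each other, so the planted
  geometry is also the structurally best call (a C...G loop would fold
  into a stronger 3-nt-loop hairpin and the "planted" truth would be
  wrong).
* **Mutation catalogs** (`simulate_mutation_catalog()`, 500 SNVs/tumor,
  50 tumors/class): A3A-like tumors draw 60% of mutations from TpC sites
  weighted 5× for YTCA context and 5× for loop residence
  (`w_motif = w_loop = 5`), A3B-like weight RTCA only, and the remaining
  40% (`background_rate = 0.4`) — and all of background tumors — are
  uniform SNVs. The 60/40 split puts signature-class burdens near 0.63,
  comfortably above threshold, while background burdens sit at the
  reference's marginal TpC rate (~0.08) — close enough to the 0.10
  threshold that classification is non-trivial, as it should be.
* **RNA cohort** (`simulate_rna_editing_cohort()`, 20 + 20 samples,
  10 hotspots among 200 sites): coverage ~ Poisson(50); editing fractions
  Beta-distributed across samples around geometry-graded means (4-nt
  loops 0.08, 3-nt 0.05, 5-nt 0.03, concentration 30) in A3A+ samples
  only; a 0.001 per-read error rate everywhere; expression =
  1 + 50 × (sample mean editing) + N(0, 0.4). The means encode the
  few-percent editing regime with the 4-nt-loop maximum; the Beta
  concentration produces the across-sample heterogeneity that makes
  per-sample indices informative.
* **Droplet wells**: per-droplet independent Poisson occupancy for each
  channel — exactly the model the inversion assumes.

Seeding is hierarchical: a master seed plus a named stream per generator
(`derive_seed()`), so each stage is bit-reproducible in isolation and
stages do not share random state.

Passing tests on these cohorts demonstrates that each pipeline stage
inverts its own generative model at realistic signal levels. They do not
demonstrate robustness to what the generators omit: alignment artifacts
and strand bias in RNA-seq counts, mapping errors near repetitive
hairpins, DNA contamination of RNA libraries, overdispersed coverage,
transcript-isoform mixtures, or fluorescence gating errors upstream of
droplet counts. Real-cohort behaviour depends on those nuisances;
conclusions here are about the computational machinery, not about any
patient dataset.

## Numerical and degenerate-input choices

* Wilson intervals are computed in closed form; endpoints are clamped to
  [0, 1] before transformation, and the concentration upper bound guards
  against an endpoint of exactly 1.
* Fisher tests run on aggregated counts (two-digit thousands at default
  scale), where `fisher.test` is exact and fast; BH is applied across the
  tested (filtered) sites only.
* Sites too close to a sequence end for a full tetranucleotide or
  logogram flank are reported with `NA` context / skipped with a warning
  rather than padded.
* Empty catalogs, zero-coverage fractions, constant correlation inputs,
  saturated channels, and both-channels-empty abundances are typed errors
  (`apobecedit_*_error` condition classes), never silent `NaN`s; the CLI
  maps input, parameter and runtime errors to distinct exit codes.

## Problem sizes

The shipped tests and the acceptance script use: 500 random ≤ 40-mers for
oracle equivalence; 200 wells × 20,000 droplets for ddPCR recovery;
150 tumors × 500 SNVs for classification; ten cohorts of 40 samples × 200
sites for hotspot recovery; and 100 samples for the expression
correlation. These sizes give every binomial or rank statistic a standard
error several times smaller than the margin being asserted, which is the
criterion by which they were chosen.

## Known limitations

* The hairpin model scores no bulged or mismatched stems and no
  pseudoknots, and the 3/2/1 pair ladder is not a thermodynamic
  potential; hairpins that fold only with a bulge are called
  structure-free.
* Classification thresholds are design constants, not fitted to any
  cohort; on real data they would warrant calibration against orthogonal
  labels.
* The discovery stage consumes per-site read counts; it performs no
  read-level processing, so artifacts that live below the count level are
  out of reach.
* Minus-strand transcripts must be supplied in transcript orientation;
  the package does not reorient them.
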