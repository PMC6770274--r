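---
title: "Models and methods in cfFragmentomics"
author: "cfFragmentomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cfFragmentomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfFragmentomics)
```

## The scientific setting

Cell-free DNA (cfDNA) in plasma is a mixture of fragments released by
dying cells across the body. In a tumor xenograft animal, the mixture has
a useful property: every fragment that maps uniquely to the graft (human)
genome is tumor-derived and every fragment mapping uniquely to the host
(mouse) genome comes from normal tissue, so species-of-origin
deconvolution separates circulating tumor DNA (ctDNA) from the normal
background exactly. cfFragmentomics implements the analyses built on that
design:

* fragment-size profiling of nuclear cfDNA, whose mono-nucleosome peak
  sits near 167 bp in healthy plasma, shifts shorter (~144 bp) in
  tumor-derived DNA, and carries a sub-nucleosomal ladder with ~10.6 bp
  spacing — the helical pitch of DNA on the nucleosome;
* fragment-size profiling of mitochondrial cfDNA (mt-cfDNA), which is not
  nucleosome-protected; tumor-derived mt-cfDNA is markedly shorter than
  its normal-tissue counterpart;
* estimation of the ctDNA fraction from the variant allele frequencies
  (VAF) of tumor-specific heterozygous SNVs;
* a rank-sum test for copy-number gain on fixed 5 kb bins;
* cohort statistics connecting mean mt-cfDNA length to tumor burden.

Because no public sequencing data accompany these analyses, the package
ships a first-class synthetic generator that emits paired-end alignments,
variant pileups and truth files with the statistical structure the
analyses assume. Every stage is therefore testable end to end, offline.

## The synthetic cfDNA generator

`simulateFragments()` draws a fragment population from a
`SimulationConfig`:

* Each nuclear fragment belongs to the graft genome with probability
  `tumorFraction` (θ). θ *is* the simulated ctDNA fraction; its demo
  default of 0.096 matches the regime of the worked VAF example below.
* Nuclear lengths follow a **nucleosomal-ladder model**: with probability
  `1 - ladderWeight` a Gaussian at the modal length (graft 144 bp, host
  169 bp, SD 3 bp), otherwise one of a comb of equally weighted Gaussians
  at `modal - k * 10.6` bp (k ≥ 1, truncated below 50 bp). The comb
  weight is 0.3 for the graft and 0.1 for the host, reflecting that the
  ladder is much weaker in the normal-tissue signal.
* Mitochondrial lengths follow a **gamma model** parameterized by mean
  and shape (graft mean 109 bp, host 143 bp, shape 8). Only mean
  mt-cfDNA lengths are established for this contrast; the gamma with
  shape 8 gives the broad, right-skewed, unimodal shape seen in
  mt-cfDNA histograms. The two means are taken from the human-cohort
  contrast (cancer 109.15 bp vs healthy 142.62 bp), the closest
  published anchor for the graft/host difference.
* All drawn lengths are rounded and restricted to [30, 1000] bp by
  resampling. This emulates the known library bias of paired-end cfDNA
  protocols (very short and very long fragments are under-represented)
  without modeling its shape.
* Placement is uniform along contigs, except inside the configured
  copy-gain region where graft nuclear placement intensity is multiplied
  by `fold` (demo: fold 2 across twenty 5 kb bins). Under uniform
  placement the per-bin counts are binomial, Poisson to excellent
  approximation, which is what the copy-gain test's calibration check
  relies on.
* A fraction `ambiguousFraction` (demo 1.5e-4, i.e. 0.015 %) of
  fragments is flagged cross-species ambiguous; `emitAlignments()`
  realizes the flag as a secondary alignment pair on the homologous
  contig of the other genome. Ambiguity is simulated by bookkeeping, not
  by sequence homology: the toy genomes are random sequence, and the
  classifier consumes alignments, not bases.
* Variant pileups draw each site's alternate count as
  Binomial(depth, θ/2) — every simulated somatic site is heterozygous and
  clonal — plus errors at `errorRate` on the remaining reads. The demo
  default is 28 sites at depth 10 000 with `errorRate = 0`; a nonzero
  error rate inflates every VAF by ≈ `errorRate` and with it the
  estimator, which is the expected behavior of the real assay, not a
  defect of the simulator.

The same configuration and seed reproduce byte-identical SAM, TSV, VCF
and JSON outputs; this determinism is itself under test.

What the generator does **not** emulate: base-level sequencing errors in
reads (pileups only), GC and mappability bias, duplicate reads (the
analyses operate post-deduplication), bisulfite conversion, and true
alignment ambiguity arising from homologous sequence. Tests passing on
this generator show the analyses are correct under the stated stochastic
model; they cannot certify behavior under artifacts the model omits.

## Fragment extraction and size profiles

`extractFragments()` counts each template once at its leftmost mate
(positive template-length field) and takes the fragment interval as the
outermost mate span — the standard insert-size convention. Defaults drop
non-proper pairs and mapping quality below 20. Templates carrying
secondary alignments on the other genome are relabeled `ambiguous` and
excluded from per-genome profiles and denominators, mirroring how
cross-species reads are reported separately.

`sizeHistogram()` produces exact integer counts over the [30, 1000] bp
window; the mode ties to the smallest length, and means (including the
mean mt-cfDNA length used throughout the cohort analyses) are computed
over the same window.

`normalizedMtAbundance()` divides mitochondrial by nuclear fragment
counts of the same genome, making graft and host mt yields comparable
despite very different nuclear totals.

## Ladder periodicity detection

`detectPeriodicity()` scores the spacing of local histogram maxima in
the 50–150 bp region with a search band of 8–14 bp:

1. counts are log-compressed (`log1p`);
2. the log signal is detrended by subtracting a centered moving average
   (window 21 bp, about two periods);
3. the normalized autocorrelation of the detrended signal is evaluated
   on a 0.1 bp lag grid, interpolating linearly for fractional lags;
4. the reported period is the lag of the maximum (smallest lag on ties),
   and the strength is that correlation clipped to [0, 1].

Two numerical choices matter. First, the log compression: the
mono-nucleosome peak lies inside the analysis region and is an order of
magnitude taller than the ladder teeth; on raw counts its autocorrelation
footprint drowns the comb and drags the detected lag off by 0.5–2.5 bp.
On log counts the teeth and the peak contribute comparably and the comb
dominates. Second, a fixed correlation support: the unshifted signal is
restricted once to lengths at most `max - bandMax`, so the set of
compared points does not change with the lag. Letting the overlap shrink
with the lag produces sawtooth discontinuities in the score curve (a
large peak entering or leaving the overlap) and spurious maxima. With
both choices the detector returns 10.6/10.0 bp exactly on constructed
combs and 10.4–10.7 bp across seeds on simulated ladder draws at n =
1e5. The 0.1 bp grid is the coarsest that separates 10.6 from 10.4 bp;
regions with fewer than 30 populated bins return a flagged, undefined
result rather than a guess.

## Species classification

`classifyTemplates()` calls a template `graft`/`host` when all its
passing alignments lie on one genome's contigs, `ambiguous` when both
genomes are hit, `unmapped` otherwise. Because whether the published
76 %/20 % partition counts unmapped reads in its denominator is
ambiguous, `summarizeClassification()` reports fractions on both bases
(all templates, and mapped templates only).

## ctDNA fraction from variant allele frequencies

For tumor-specific heterozygous clonal SNVs the expected cfDNA VAF is
half the ctDNA fraction, so the estimator is

f̄ = mean of site VAFs, ctDNA fraction = min(1, 2 · f̄).

`selectTumorSpecificSites()` keeps sites present in at least one tumor
lesion, absent in the matched normal (buffy coat), and supported in
cfDNA by ≥ 2 alternate reads at depth ≥ 10 — conventional somatic
support thresholds, both configurable, standing in for an unspecified
filtering step. The mean is unweighted (each site one vote) rather than
depth-weighted: "average allele frequency" is a site average, and
depth-weighting would let a single deep site dominate. A site-level
percentile bootstrap (default 2000 replicates) supplies a confidence
interval; the interval is an addition to the classical point estimator
and is labeled as such in output. With 28 sites the percentile interval
is mildly anticonservative (empirical coverage ≈ 92 % at 95 % nominal in
the suite's 100-replicate check), which is typical of the percentile
method at this n.

`mutationOverlap()` reports exact pairwise shared-site counts and
Jaccard indices between tissues keyed on (contig, pos, ref, alt), the
summary used to argue which lesions feed ctDNA.

## Copy-gain testing on 5 kb bins

`tileBins()` tiles each contig into non-overlapping 5 kb bins, dropping
the trailing partial bin so all counts share one exposure.
`countFragmentsInBins()` assigns each fragment to the single bin holding
its midpoint — a rule chosen to avoid double counting where fragments
straddle boundaries. `mannWhitneyGain()` then tests, one-sided, whether
region bins have higher counts than flanking bins (default: as many
immediately adjacent bins per side as the region holds; the flank extent
is configurable because no canonical choice exists).

The p-value strategy is tiered:

* **permutation enumeration** over all group assignments when
  `choose(N, nRegion)` ≤ 1e5 — exact, and correct under ties (tied
  cross-group pairs contribute 1/2 to U); identical constant counts give
  p = 1 by construction;
* **exact U-distribution tail** (`pwilcox`) for tie-free cases with up to
  400 region–flank pairs;
* otherwise a **normal approximation** with tie-corrected variance,
  continuity correction, and an Edgeworth term using the exact excess
  kurtosis of U, γ₂ = −(6/5)(m² + n² + mn + m + n)/(mn(N + 1)). The
  Edgeworth term is what keeps the approximation within 0.01 of the
  exact tail down to three bins per side (worst case 0.0098, verified
  exhaustively over the one-sided gain tail for all m, n ≥ 3 with
  m·n ≤ 400); the plain continuity-corrected normal misses that bound at
  small sizes.

## Cohort statistics

`welchTTest()` uses the unequal-variance Welch form throughout: the
cohorts compared are strongly unbalanced (46 vs 4; 16 vs 32), where the
pooled-variance t-test is anticonservative if the larger group has the
larger variance. `pearsonCorrelation()` uses pairwise-complete
observations because burden covariates are missing for a subset of
samples (the demo cohort reproduces this: ctDNA percentage present for
12 of 16 cancer samples). `dichotomizeByCtdna()` splits strictly above
5 % ctDNA and compares mean mt-cfDNA length between groups.
`trackPatient()` orders one patient's samples by timepoint and flags
direction reversals in mean mt-cfDNA length. No multiple-testing
correction is applied by default — the analyses report nominal p-values —
and none is needed for the single-comparison demos; `p.adjust` composes
naturally where users run many correlations.

`simulateCohort()` builds the demo cohort: 16 cancer samples whose mean
mt length decreases linearly with a uniform(1, 10) tumor size
(170.66 − 1.5·size + N(0, 3), giving a cancer mean ≈ 162.4 bp) against
32 healthy samples at 173.25 ± 5 bp, with ctDNA percentage increasing in
tumor size. The slope-to-noise ratio implies a true correlation near
−0.8, so a 16-sample cohort detects the inverse relation with high
power; burden units are deliberately unitless, as in reanalyzed cohorts
whose units are unreported.

## Problem sizes and reproducibility

The test suite and the acceptance script generate every input in code.
Headline checks run at the scale the analyses are designed for: 1e5
nuclear fragments for modal-length and periodicity recovery, 1e4
fragments per compartment across 20 seeds for the mito-length contrast,
28 sites at depth 10 000 across 20 seeds for estimator recovery and
interval coverage, 200 null simulations (2e4 fragments each) for
copy-gain calibration and 20 fold-2 simulations at 1e5 fragments for
power. Property checks that only exercise internal consistency
(bootstrap coverage, subsampling stability) run at reduced replicate
counts chosen to keep the default suite under a minute of simulation per
file.

## Known limitations

* The toy genomes are uniform random sequence; nothing here exercises a
  real aligner, and alignment-induced biases are out of scope by design.
* The ladder model places the comb only below the modal peak; di- and
  tri-nucleosome peaks are not modeled.
* The gamma mito model matches means and general shape but is not fit to
  any empirical mt-cfDNA histogram.
* The copy-gain test makes no GC or mappability correction and performs
  no genome-wide segmentation; it answers only the focused
  region-vs-flank question.
* The ctDNA estimator assumes clonal heterozygous diploid sites; subclonal
  sites or sites under copy-number change bias it downward/upward in the
  usual ways.
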