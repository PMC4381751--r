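---
title: "Methods: rare CNV detection from SNP-array intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare CNV detection from SNP-array intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecnv)
```

## The problem

Dense SNP arrays measure, at every marker, a total-intensity signal (the
Log-R ratio, LRR, approximately 0 for two copies, negative for deletions,
positive for duplications) and an allelic-ratio signal (the B-allele
frequency, BAF, whose band structure changes with copy number). Rare
copy-number variants (CNVs) can be segmented out of these two signals, but
at biobank scale the signals are dominated by nuisance structure: plate and
typing-centre offsets, GC-correlated "genomic waves", latent linear batch
components and heterogeneous per-sample noise. Without aggressive quality
control these artefacts masquerade as CNVs and produce spurious
case-control associations; with it, the burden odds ratio of a null cohort
converges to unity. `rarecnv` implements the full chain: marker and sample
QC, principal-component (PC) batch correction, a hidden-Markov-model (HMM)
caller, CNV-level QC, copy-number-variable-region (CNVR) construction, and
the association layer for case-control and family designs, together with a
simulator that generates all of the above artefact classes with truth
tables.

## Quality-control metrics

**Marker QC.** Samples and SNPs with genotype call rate strictly below 0.95
are removed (samples first, then SNP rates recomputed — the two-pass order
matters for markers that fail only through bad samples). Hardy-Weinberg
violations are tested with the exact conditional test on the heterozygote
count given allele counts; the default exclusion threshold (p < 1e-10,
computed on controls) is deliberately conservative because CNV-rich markers
legitimately distort genotype clusters. There is no minor-allele-frequency
filter: monomorphic markers still carry intensity information. After PC
correction, markers whose LRR still differs between nuisance groupings
(DNA source, phenotype-confounded cohort) are removed by a per-SNP Welch
t-test at a Bonferroni-corrected family level of 0.05.

**Sample QC.** Four intensity metrics drive exclusion, in a fixed order:

* *LRR mean*, fenced at 1.5 interquartile ranges beyond the quartiles
  (type-7 interpolated quantiles; values exactly on a fence are kept);
* *DLRS*, the derivative log-ratio spread: the sample SD of differences
  between successive markers divided by sqrt(2). Differences never cross
  chromosome boundaries (the join is an artificial jump) and skip missing
  values. For i.i.d. noise of SD sigma the statistic estimates sigma, which
  the simulator tests exploit. The fence sits 3.5 scale units above the
  cohort centre, applied per cohort because typing centres differ in
  baseline noise. Location and scale are the median and the
  normal-consistent MAD rather than mean and SD: a failing plate can put
  ~10% of a cohort at more than twice the baseline noise, which inflates
  mean and SD enough to mask every one of its own outliers, while the
  robust fence is unaffected and agrees with mean + 3.5 SD on clean
  cohorts;
* *wave factor*, the signed magnitude of long-range LRR oscillation:
  the unscaled median absolute deviation of per-window median LRR (1 Mb
  non-overlapping windows), signed by the Pearson correlation of window
  medians with window GC. The 1.4826 normal-consistency factor is *not*
  applied — the magnitude is reported as a raw MAD, a documented
  convention. The fence sits 3.5 robust scale units above the centre of
  |wave|, global across cohorts;
* *chromosome aberrations*: a chromosome whose mean deviates from the
  sample's autosomal mean by more than 5 cohort SDs, persistently across
  at least half of its 1 Mb windows, flags the sample (aneuploidy and
  mosaic-scale events break PC correction downstream). The z and
  persistence thresholds are package choices — calibrated so that focal
  multi-Mb CNVs do not trigger them — and are configurable.

Plates in which more than 40% of samples fail any of the above are excluded
wholesale. All fences can be *reused* on a second pass (`fences`
argument); this makes re-running QC on its own survivor set a no-op, which
recomputed Tukey/SD fences would not be (they keep peeling the tails of a
truncated distribution).

## PC batch correction

Sample scores are the leading left singular vectors of the column-centred
LRR matrix restricted to a masked, thinned marker subset: immunoglobulin,
telomeric, centromeric and MHC regions are excluded, and the remainder is
uniformly thinned to 15% (seeded). The thinning is what keeps genuine rare
CNV signal out of the components: a variant carried by <1% of samples at
<1% of markers contributes negligibly to the leading directions. Each
manifest SNP is then replaced by the residual of its least-squares
regression on the k = 24 scores *plus intercept*; removing the intercept
(per-SNP centring) also removes marker-level miscalibration, and perturbs
rare-variant signal negligibly. `k = 0` is the identity, so the correction
level can be swept. Common copy-number polymorphisms (CNPs) are expected to
be distorted by this step — the pipeline targets rare variants only.

## The HMM caller

Five states ordered by copy number (CN0, CN1, CN2, CN3, CN4; no
copy-neutral LOH state — LOH is out of scope). Emissions:

* LRR: Gaussian per state, defaults mean/SD (-3.5/1.3, -0.67/0.28, 0/0.16,
  0.40/0.21, 0.68/0.24) — the conventional parameterisation for
  Illumina-style arrays, exposed in `hmm_params()` because production use
  tunes them;
* BAF: a mixture over allelic bands at j/copies, weighted by
  Binomial(copies, PFB) where PFB is the population B-allele frequency of
  the marker; each band is a normal (SD 0.03) *clipped* to [0, 1], so
  observations exactly at 0 or 1 carry the clipped tail mass — this treats
  the point masses at the rails and the interior density in one coherent
  family (the simulator generates BAF the same way, by clipping). CN0 is
  uniform. A uniform outlier component (weight 0.01) absorbs stray values.
  Mixing a discrete mass with a density is dimensionally heterogeneous but
  standard practice for BAF models; it only matters at the rails, where
  every state is treated identically.

Transitions are distance-dependent: over a gap of d bp the chance of
leaving state i is (1 - exp(-d/D)) (1 - pi_i), distributed over target
states j proportionally to the diploid-dominant stationary prior pi
(default 0.99 on CN2), with D = 100 kb. Every row sums to one for every d,
and the model relaxes to the prior over large gaps. Decoding is Viterbi in
log space per chromosome (calls can therefore never span a chromosome
boundary); score ties prefer the lower copy number, then the earlier state
index, making decoding deterministic. Missing LRR or BAF at a marker simply
drops that term from the emission.

Maximal non-diploid runs become calls. Adjacent same-state calls are merged
when gap/(left + gap + right) < 0.2 (strict), left-to-right to a fixed
point — dense regions otherwise shatter long CNVs into fragments, inflating
counts and corrupting length distributions and de novo rates. Each call's
quality is the mean forward-backward posterior of its state over its
markers, a [0, 1] score thresholded at 0.95 downstream. There is no single
standard formula for array CNV call quality; the mean state posterior is
this package's likelihood-based score, chosen for its direct probabilistic
reading and its natural [0, 1] range under a 0.95 threshold.

## CNV-level QC and CNVRs

Calls with fewer than 6 supporting SNPs are dropped (a data-driven
relaxation of the common 10-SNP rule). Samples whose total, deletion or
duplication call count exceeds the cohort mean + 3 SD are removed — high
counts almost always mean residual contamination. Plates whose per-sample
CNV rate exceeds the global mean + 3 SD are removed. Calls overlapping
immunoglobulin/telomere/centromere masks by even 1 bp are dropped. Quality
below 0.95 only *flags* a call at this stage; quality-based dropping
happens at the CNVR stage so that region membership is decided before
members are discarded.

CNVRs use segment-group semantics: a sweep over (chrom, start)-sorted calls
of one class maintains the running common intersection of the open group; a
call joins iff it intersects that interval, otherwise the group closes and
the next opens with the incoming call plus any previous members that still
overlap it, so one call may belong to several CNVRs. Emitted groups that
are strict subsets of others are removed. On random instances this
reproduces exactly the brute-force "maximal sets of intervals sharing a
common point" oracle. Deletions and duplications are grouped separately,
and carriers are counted per sample (a sample with two member calls counts
once). Rarity is two-stage: calls are retained upstream up to 5% CNVR
frequency (so the boundary of a common variant cannot masquerade as a rare
region), and CNVRs above 1% frequency are removed at the analysis stage.
Member calls below quality 0.95 are dropped; CNVRs with more than 20% of
members failing are removed entirely.

## Association statistics

All 2x2 comparisons use the exact conditional machinery: two-sided p by the
minimum-likelihood convention, the sample (cross-product) odds ratio, and
the conditional MLE of the noncentral hypergeometric odds ratio obtained by
root-finding on the conditional expectation (precise to ~1e-8, verified
against enumeration). Confidence intervals are exact conditional tail
inversions; with a zero cell only the p-value is reported. Both OR
estimators are always reported because published tables mix the two
conventions. Burden is tested per class overall, per length stratum
(deletions 0-20/20-400/>400 kb; duplications 0-50/50-400/>400 kb, the
lower break differing because short duplications are scarcer; bins are
half-open (lo, hi] with a strict > top bin; Bonferroni m = 6), and per
annotation flag (genic/exonic/reference-overlap). Regional CNVR scans are
exact tests of carriers versus non-carriers with a fwe/m Bonferroni
threshold and QQ export; under the null the p-values are discrete and
conservative, so the meaningful uniformity check is one-sided (no
inflation).

Family analyses: transmissions are counted per locus as children times
carrier parents (the denominator), a child counting as transmitted-to when
one of its same-class calls overlaps a parental member call by at least
1 bp with 50% reciprocal overlap (the cross-individual "same CNV" rule is
not defined in the literature; this default is explicit and configurable).
The TDT is the exact binomial test of transmissions against 0.5 by
tail-doubling, capped at one — the affected-offspring p is reported beside
the unaffected rate because differential detection sensitivity depresses
both. De novo status requires *both* the absence of any overlapping
parental call and a negative parental-evidence re-test: the emission
log-likelihood ratio of the child's state versus diploid summed over the
call's markers on each parent's data, with any positive evidence
(threshold 0) counting as support — a deliberately relaxed re-test that
replaces joint trio decoding, because the dominant error mode is missing
the variant in a carrier parent, not inventing it. Parents without
intensity data make the call "unknown", excluded from the burden test.

Power grids report, per (odds ratio, carrier frequency) pair, the smallest
total sample size on a 10,000-sample grid achieving 80% power at
alpha = 5e-5 (a Bonferroni level for ~1000 regions), 1:1 case:control, via
the normal approximation on the log odds ratio; a Monte-Carlo exact-test
method is available as a cross-check and agrees within a factor of two at
desk scale.

## The simulator

`simulate_cohort()` draws LRR as

```
LRR(s, m) = mu_cohort + mu_plate + w_s g(m) + sum_k u_sk v_mk
            + delta_state(s, m) + eps_sm,   eps ~ N(0, sigma_s^2)
```

with g the standardised GC profile (so the wave-factor statistic's expected
magnitude is proportional to w_s), latent components u v of per-SNP SD
0.03, per-sample noise sigma_s = 0.15 with a 2% outlier class at 0.35, one
"bad plate" whose samples are half high-noise, 0.5% whole-chromosome
duplications, and spiked CNVs at 0.5 events per sample (the rare-CNV rate
reported for large case-control array studies), states 0/1/3/4 in
proportions 5/55/35/5%, geometric-type lengths with a 6-SNP minimum and a
30-SNP mean. BAF comes from genotypes drawn at each marker's PFB and is
transformed inside CNVs (haploid bands for CN1, uniform for CN0,
third-bands for CN3, quarter-bands for CN4), all as clipped normals —
matching the caller's emission family by design, so calibration properties
(sensitivity >= 0.85, precision >= 0.90 for >= 6-SNP events) are tested
under matched parameters; `state_shift` can be set away from the emission
means for robustness experiments. `simulate_trios()` adds Mendelian
genotypes, 50% transmission of parental CNVs, and configurable de novo
spikes. Every run flows from a single seed with a documented stream order
(sample attributes, latent loadings, genotypes/BAF, CNV truth, noise,
missingness), so outputs are bit-identical under a fixed seed.

What the simulator does *not* emulate: raw two-colour probe intensities
and genotype-calling error structure, mosaicism, sex chromosomes,
linkage-disequilibrium between markers, and ancestry stratification.
Passing calibration tests on simulated data therefore demonstrates the
pipeline's internal consistency under its own noise model, not performance
on any particular array product.

## Numerical choices and problem sizes

Exact-test enumerations are done in log space with max-subtraction;
forward-backward uses per-step scaling with per-row max-subtracted
emissions (posterior rows sum to 1 within 1e-9 and match path enumeration
on short windows). The Viterbi tie-break and the merge rule's strict
inequality are frozen conventions. Quantiles are R's type 7 everywhere.

The test suite exercises the full pipeline at 2,000 samples x 20,000
markers (the scale at which batch structure, plate exclusion and the QC
sweep are meaningful; it completes in minutes) and the null-burden
convergence property at 6,000 samples x 4,000 markers, where event counts
make the all-CNV odds ratio informative to within ±10%. Oracle comparisons
run at enumeration-feasible sizes (2x2 tables to N = 200, HMM windows to
8 markers, interval sets to 25 calls).

## Known limitations

Autosomes only by default; no GC-regression emission adjustment (PC
correction removes the wave, and residual-wave data should be excluded,
not adjusted); no CNP genotyping; no joint trio HMM (parental-evidence
vetting replaces it); the aberration screen's thresholds are heuristic;
exact TDT conventions differ across published tables and this package's
tail-doubling choice is one defensible convention among several.
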