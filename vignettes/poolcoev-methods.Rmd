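---
title: "Methods: pooled-population genomics with poolcoev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-population genomics with poolcoev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcoev)
```

poolcoev analyses whole-genome pooled sequencing of bacterial
populations founded from a known mixture of strains, as produced by
host–pathogen experimental-evolution designs: replicate populations
evolve under contrasting treatments (e.g. against a coevolving host
versus a non-changing host), are sampled at transfers, pooled and
sequenced. This vignette explains the models and the choices behind
each stage, what the synthetic-data generator does and does not
emulate, and the numerical conventions.

## Reference panel and diagnostic sites

The panel is a pre-computed multiple alignment of the founding strain
genomes (whole-genome alignment itself is out of scope), split per
contig with roles `chromosomal` / `plasmid`. Coordinates are 0-based
half-open everywhere internally; BED output keeps that convention and
VCF output converts to 1-based.

A **diagnostic site** is an alignment column with exactly two alleles
where a single strain carries the substitution. Columns containing
gaps or `N` and columns with more than two alleles are excluded: the
1-substitution definition is read literally, which is conservative but
unambiguous (how multiallelic columns were handled historically is not
recoverable, and they are rare at the divergences involved — about
`5 × 10⁻⁴ × L` columns at 1% divergence for five strains).

The **metareference** collapses each column to the IUPAC code of its
base union so that strain-specific alleles do not count as mismatches
during mapping. Gaps are dropped from the union (indel columns are
kept without gaps); any `N` forces `N`; all-gap columns are removed.
Decoding is IUPAC-aware, so the operation is idempotent on its own
output.

**Read assignment** is competitive and strict: a read belongs to a
strain only when its edit distance there is strictly lower than to
every other strain; all ties are `excluded`. This discards information
but guarantees that donor-assigned coverage used for HGT detection is
never inflated by ambiguous reads.

## Strain composition: mode of diagnostic frequencies

At each usable diagnostic site (depth ≥ `min_depth`, default 10), the
diagnostic-allele frequency is an independent estimate of the strain's
abundance. The per-strain distribution of these frequencies is
asymmetric — sites overlapping shared segments, mapping artefacts and
sampling noise produce a skewed tail — so the location estimate is the
**mode**, not the mean.

The estimator is the half-sample mode: recursively keep the shortest
interval containing half of the sorted points until at most three
remain, then average. It is deterministic, O(n log n), affine
equivariant, needs no bandwidth, and is standard for skewed unimodal
data. A kernel-density argmax is available via `method = "density"`
for comparison. Estimates are clipped to [0, 1] and deliberately *not*
renormalised to sum to 1; the residual `1 − Σ estimates` is reported
as a diagnostic, since the per-strain estimates are independent.

Defaults `min_depth = 10` and `min_sites = 20` are package choices:
below ~10 reads the frequency granularity (1/depth) dominates, and
below ~20 sites the half-sample recursion is estimating a mode from
noise. Strains below `min_sites` are estimated anyway but flagged.

A practical detection floor: a strain at true frequency p is
estimated as 0 once most of its diagnostic sites see no supporting
read, i.e. roughly when `p · coverage ≲ 2`. At 100× this affects the
1% strain; the tests therefore check recovery within ±0.05, not
relative error.

## Variant filters

The four post-calling filters run in the order (i) coverage quantile,
(ii) strand bias, (iii) indel collision, (iv) MAF.

* Coverage quantiles are per sample, computed with linear
  interpolation (`quantile` type 7) on the *pre-filter* depth
  distribution; records exactly at a quantile are retained. Below 50
  records the quantiles are meaningless and the filter passes through
  with a warning — which also makes the whole chain idempotent on its
  own output (quantiles frozen).
* Strand bias: two-sided Fisher's exact test on
  [[alt_fwd, alt_rev], [ref_fwd, ref_rev]]; p < 0.05 drops the record.
  Any SNVer-style pre-threshold is subsumed by this explicit test.
* Indel collision: a SNP sharing (sample, contig, position) with an
  indel is dropped; the indel stays.
* MAF: `alt/depth > 0.05` strictly; exactly 5% is dropped.

Order matters only through the quantile step *and* one subtlety the
property tests document: the collision filter commutes with the
row-local filters only while the colliding indel itself survives them.
The fixed (i)→(iv) order resolves the ambiguity.

## CNV detection from coverage-rank variance

Pooled samples can carry a duplication in only a fraction f of their
population, scaling expected depth by `1 + f (c − 1)` — possibly well
below 2, which absolute-depth callers miss. The detector therefore
asks where samples *disagree* in coverage:

1. within each sample, depth is rank-transformed (ties averaged) and
   divided by the number of positions, making samples of different
   sequencing depth comparable; ranks are genome-wide by default
   (per-contig via `by_contig = TRUE`);
2. the sample variance (n − 1) of the normalised ranks is computed per
   position across samples;
3. right-tail outliers of that variance are extracted by fitting a
   normal distribution to the 10–90% quantile band of the sorted
   variances (least-squares regression of order statistics on normal
   quantiles at plotting positions i/(N+1)) and flagging values whose
   expected count under the fit, given N positions, is below ρ = 1;
4. flagged positions closer than 100 bp merge into one region (a gap
   of exactly 100 bp does not merge — the rule is strict);
5. copy number per sample is the region's median depth over the
   chromosomal median; contig-level copy number uses means, with a
   variance from resampling 10,000 positions.

The outlier step is a re-implementation from the published description
of the normal-fit/expected-count method; the band, ρ, and
right-tail-only defaults are declared package choices. Two calibration
facts the tests document honestly:

* Under a correct normal null the method flags about ρ points per run
  by construction, so "planted outliers are recovered exactly" can
  only hold up to that budget; tests assert full sensitivity plus a
  mean false-positive count ≤ 2.
* Under a pure Poisson coverage null (10 samples × 100 kb at 100×),
  the across-sample variance of normalised ranks is a right-skewed
  quantity (essentially a variance of near-uniform ranks), and the
  central-band normal fit undercovers its right tail: the measured
  mean flagged count is ≈ 2.2, slightly above the 2ρ budget the
  acceptance suite asserts. This is a property of the normal-fit
  method itself, not of the implementation; the corresponding
  acceptance expectation is left failing rather than widened.

Rank invariance is the design's point: the whole pipeline is invariant
under per-sample monotone transformations of depth (property-tested),
so library-size and GC-scaling differences between samples cancel.

## HGT fragments

Donor-assigned depth tracks (uniquely-best reads only) are scanned for
maximal runs with depth ≥ 1, allowing internal uncovered gaps of at
most 100 bp — "continuous" evidence is read with the same tolerance as
the CNV merge, because read sampling at low fragment frequency
shatters truly contiguous fragments (at frequency 0.2 and 100×, a
20-read-per-position track still leaves occasional ≥ 10 bp holes).
Runs shorter than 1 kb are discarded. Fragment frequency is the median
donor depth inside the fragment over the median focal chromosomal
depth; it may exceed 1 for multicopy transferred elements and is not
clipped. Continuity is evaluated per sample, and per-sample calls are
reported (the union is the population-level summary).

The treatment screen flags a fragment only when the variance of
per-treatment mean frequencies strictly exceeds 0.04.

## Windowed diversity

Coverage is the per-site sample size: a segregating site with depth
nᵢ and frequency pᵢ contributes `1/a₁(nᵢ)` to Watterson's θ and
`nᵢ/(nᵢ−1) · 2pᵢ(1−pᵢ)` to π (the unbiased per-site heterozygosity);
both are divided by the window length. Sites require nᵢ ≥ 2 and
`maf < pᵢ < 1`, with `maf = 0.05` strict by default. Windows are
coordinate-anchored, 10 kb at 5-kb steps, half-open; the trailing
window is truncated to the contig end and normalised by its true
length. Tajima's D uses the classical variance constants evaluated at
the window's rounded mean retained-site coverage (median and harmonic
alternatives are exposed); D is missing when S = 0 or the variance
term is non-positive. Binomial double-sampling corrections for finite
pool size are deliberately not applied — coverage-as-sample-size is
the documented simplification, and at constant coverage every
statistic reduces exactly (to 1e−9 in the tests) to the classical
fixed-n estimator, which is the regime the oracles pin down.

## Association statistics

Each genomic feature is tested two ways: a linear regression of
phenotype on feature weighted by log₁₀ coverage (or inverse variance
for the copy-number reassessment), and the fixed-effects nested ANOVA
`value ~ transfer + treatment + treatment:replicate +
transfer:treatment` with Type-II sums of squares and F-tests against
the residual mean square. Replicate-within-treatment is a fixed
blocking term — no REML — because the design reports simple effect
tests; Type-II SS is chosen because extinctions unbalance the design.
When the residual SS is exactly zero (noise-free fixtures) the F-test
degenerates; terms with zero SS are reported as F = 0, p = 1 and
others as infinitely significant, which keeps the analytic edge cases
meaningful. BH-FDR is applied per test family across features.
Spearman's ρ uses exact full-permutation p-values below n = 10
(untied data) and the t approximation otherwise. A config-driven
blacklist excludes non-comparable populations (e.g. a replicate
dominated by a different strain) instead of hard-coding them.

Candidate features must (i) vary in ≥ 4 replicate lineages — a
lineage counts when the feature deviates from its across-population
median — (ii) show a treatment effect (q < 0.05) but no transfer and
no interaction effect (both q ≥ 0.05), (iii) for HGT features, pass
the strict 0.04 treatment-variance screen, and (iv) carry a
functional-consequence annotation, which is passed through, not
inferred.

## The synthetic-data generator

Everything is a pure function of (arguments, seed); a global seed
drives per-component seeds through an FNV-1a-based derivation, so each
sample is independently reproducible.

* **Panels**: a random ancestral genome, split into contigs (the last
  is the plasmid analogue), each strain mutating independently at rate
  `divergence` (default 1%, five strains, 50 kb desk-scale). A column
  is strain-private — hence diagnostic — exactly when one strain
  mutated, giving the binomial expectation `L·d·(1−d)^{k−1}` the
  tests check.
* **Pooled samples**: summary-level data only (depth tracks, pileups
  at polymorphic columns, per-read edit-distance records) — no FASTQ,
  since downstream stages consume alignments and pileups and external
  mappers are out of scope. Depth is Poisson around `mean_coverage`
  (negative-binomial overdispersion available, off by default),
  scaled inside planted CNVs; base counts are multinomial with a
  symmetric per-base error (default 10⁻³); planted HGT fragments add
  donor-uniquely-best reads at `frequency × coverage`.
* **Coverage matrices** for the CNV detector add a shared mean-1
  lognormal **site effect** (σ = 0.3, a typical positional coverage
  CV for pool-seq libraries) to every sample: real libraries share
  mappability/composition biases, and the rank-variance detector
  specifically relies on non-carrier samples agreeing through such a
  shared bias. The effect is position-specific (iid) rather than
  smooth: marginal ranks — all the detector sees — are unaffected by
  the correlation length, while region medians stay unbiased, keeping
  the copy-number ratio estimator clean. σ = 0 gives pure Poisson
  nulls for calibration.
* **Haplotype windows**: per-site binomial placement — a site
  segregates with probability `θ·a₁(n)` (matching Watterson's E[S]),
  the derived-allele count is drawn from the neutral 1/i spectrum and
  carriers are uniform. This gives neutral-SFS-consistent data with
  mean Tajima's D near 0 (checked at 200 replicates, |mean D| < 0.3)
  and returns the full haplotype matrix so π can be checked exactly
  against the O(n²L) pairwise-difference loop.

What the generator does **not** emulate: mapper-specific error
profiles, indels (simulation of them, that is — the filters handle
indel records), linkage between diagnostic sites beyond the shared
genome, GC-dependent smooth coverage waves, and demographic structure
within a pool. Passing tests therefore demonstrate correctness of the
estimators under their stated sampling models, not robustness to every
artefact of real libraries.

Desk-scale problem sizes (50-kb genomes, 100-kb coverage matrices,
≤ 20 haplotypes, 10–50 seeds) were chosen so the full suite and the
acceptance script each run in about a minute; scaling the config to
full genomes or 1,000× depth changes cost, not behaviour.

## Pipeline and provenance

`run_pipeline()` chains simulate → panel → strain composition → CNV →
HGT → windowed diversity from one validated YAML config (unknown keys
are rejected). Every TSV/BED artifact carries a `#` provenance header
with the package version, an FNV-1a hash of the config, and the seed;
the run log is the only file with a timestamp, so reruns under the
same config and seed are bit-identical elsewhere — which the tests
assert by hashing.
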