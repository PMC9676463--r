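---
title: "Methods: translational attenuation scoring and the RNA-oxidation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translational attenuation scoring and the RNA-oxidation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taindex)
```

# Scope

`taindex` quantifies how much a stress transcriptome resembles the
transcriptome of cytosolic translational arrest. Singlet oxygen oxidizes
guanosine in mRNA to 8-oxoguanosine; an oxidized guanosine stalls 80S
ribosomes, so photosensitizer stresses that leak oxidative damage into the
cytosol should reproduce features of a cycloheximide (CHX)-type arrest
response, while purely plastid-confined signalling should not. The package
operates entirely on DE summary tables (gene id, log2 fold change,
p-value); it does not download data, fit DE models, or process reads.

# Gene selection

Regulated sets use the conventional filter: at least 2-fold change
(inclusive, `|log2FC| >= 1` at the default threshold) and p < 0.05
(strict). Which p-value is tested is configurable: `p_column = "auto"`
(default) uses the BH-adjusted column when one is present and the raw
p-value otherwise, because adjusted values are the norm for RNA-seq tables
while many legacy microarray tables carry only raw values. Rows with
unparseable numerics are dropped and counted, never imputed. Gene
identifiers are normalized to the AGI locus convention (uppercase, isoform
suffix `.<digits>` stripped); duplicates after normalization collapse to
the record with the largest `|log2FC|`, since downstream analyses need one
representative per locus (an `"error"` policy is available).

# The Translational Attenuation Index

For an up-regulated query set scored against a reference arrest
transcriptome,

$$\mathrm{TAI} = \frac{\#\{\text{genes with reference } \log_2\mathrm{FC} > 0\}}{n},$$

with a reference fold change of exactly 0 counting as non-positive. Only
the *signs* of the reference fold changes matter, so TAI is invariant to
rescaling the reference. Two denominator policies are implemented because
genes absent from the reference have no sign:

* `"drop"` (default): restrict to matched genes, `n = n_matched`. Coverage
  `n_matched / n_query` is always reported so the restriction stays
  auditable. This is the default because cross-platform comparisons
  (microarray queries against an RNA-seq reference) routinely lose genes
  for technical rather than biological reasons.
* `"count_as_nonpositive"`: every query gene counts, `n = n_query`; a
  conservative lower bound, never above the drop-policy value.

The ranked waterfall (`waterfall_ranking()`, `autoplot()`) arranges matched
reference fold changes from largest to smallest; ties break
lexicographically by gene id so the ranking is reproducible.

No TAI cutoff is imposed for calling a response "cytosolic". Instead
`tai_null_test()` supplies an exact two-sided binomial test of the positive
count against a sign-symmetric null (probability 0.5): under the null that
query genes are unrelated to the arrest programme and the reference's
sign distribution is balanced, TAI fluctuates around 0.5. The package also
always lets you compute the reference's empirical positive-sign rate as the
null probability when the reference is not sign-balanced.

# Overlap statistics

`overlap_report()` computes, for every ordered pair of profiles, the 2×2
contingency table over a *universe*, overlap percentages in both
directions (the a-of-A and a-of-B denominators both matter because
published overlap percentages rarely state theirs), the Jaccard index, and
Fisher's exact two-sided test. The universe defaults to the genes measured
in **both** profiles: for cross-platform pairs the measured intersection is
the only defensible background, since a gene that one platform cannot
detect carries no overlap information. A `"union"` mode is available.
Selected sets are intersected with the universe before counting. The
reported odds ratio is the sample cross-product `(a·d)/(b·c)` (infinite
when `b·c = 0` with `a·d > 0`), not the conditional MLE, so it matches the
hand-computed value on printed tables. Fisher p-values are per-comparison;
`bh_adjust()` can be applied across a family on request but is not applied
silently.

# Signature correlation

`correlation_matrix()` reimplements the signature-correlation *concept*
generically: Pearson (default) or Spearman correlation of log2 fold-change
vectors over the genes shared between query and signature, requiring
`min_shared = 10` genes by default, dropping unshared genes pairwise, and
flagging (not dropping) failed pairs. The curated databases and exact
statistic of hosted ROS-signature services are not public, so no claim is
made of reproducing any particular service's numeric output; the shipped
panel under `inst/extdata/` is synthetic and exists only so examples and
tests run self-contained.

# The RNA-oxidation model

Standard curves for 8-oxoG (ng/mL) and guanosine (µg/mL) are ordinary
least-squares lines; the fit is exact on collinear calibration points and a
numerically-zero slope is flagged unusable. `quantify_oxog_ratio()` inverts
both curves, converts to molar units (default masses 299.2 and 283.2
g/mol, matching the protonated MRM precursors at 300.06 and 284.1 m/z),
and reports 8-oxoG per 10⁵ guanosines. Concentrations inverted below the
blank are clamped to zero with a flag; responses outside the calibrated
range warn.

`transcript_oxidation()` turns a rate *r* into a Poisson lesion load. The
central ambiguity is whether a rate quoted "per 10⁵ residues" applies per
guanosine or per nucleotide. With `per = "guanosine"` (default, consistent
with a measured 8-oxoG/G molar ratio) the expected load of a transcript of
length *L* with guanosine fraction *g* is λ = r·L·g; `per = "residue"`
gives λ = r·L. The default `g_fraction = 0.25` is the approximate G content
of an average transcript; at r = 20×10⁻⁵, L = 1500 and g = 0.25 it yields
λ = 0.075 — "one lesion in 7.5% of transcripts" in the linear
approximation that is standard for small loads, alongside the exact
Poisson `p_any = 1 − e^{−λ} = 0.0723`. Both interpretations are exposed
rather than asserting one. Translational competence is
`exp(−λ·(1 − a))` with per-lesion attenuation `a = 0` by default (a single
lesion fully blocks translation — the simplest model consistent with 8-oxoG
stalling 80S ribosomes); `a ∈ (0, 1)` models partial read-through.

# Synthetic data: what it emulates and what it does not

The generators exist so that every pipeline stage has inputs with known
ground truth.

**Reference simulator.** `simulate_reference_profile()` emulates an arrest
reference: an exact `round(frac_induced·n)` subset of genes is induced with
log2FC ~ N(2, 0.5²) (so essentially every induced gene is positive,
Φ(4) ≈ 0.99997) and small Beta(0.5, 20) p-values; background genes get
noise fold changes whose **signs are exactly balanced by construction**
(half positive, half negative magnitudes of N(0, 0.5²) draws) and uniform
p-values. The exact balance makes the TAI null of 0.5 analytically true in
simulation; real references need not satisfy it, which is why the pipeline
reports the empirical positive rate.

**Query mixtures.** `simulate_query_set()` draws `round(f·n_up)` genes from
the induced pool and the rest from the background, without replacement.
The expected TAI is `f·q₁ + (1−f)·q₀ ≈ f + (1−f)/2`, and
`recover_mixing_fraction()` inverts that linear model (clipped to [0, 1]).

**Mechanistic mode.** `simulate_mechanistic_derepression()` encodes the
repressor-turnover mechanism: oxidation load λ gives translational
competence `c = e^{−λ}`; a repressor with half-life t½ (decay rate
k = ln 2 / t½) relaxes to `ρ = c + (1−c)e^{−kt}` of baseline after
exposure t; its target gene reports `log2FC = −h·log2(ρ)` plus
N(0, `fc_noise_sd`²) noise, with Wald-type p-values monotone in `|log2FC|`.
This fold-change mapping is the package's own model — no quantitative
mapping from competence to fold change exists in the literature — and the
simulator's provenance note says so. Design choices, made once:

* Half-lives lie on a deterministic log-spaced grid over [0.25, 24] h (the
  equally-spaced quantiles of a log-uniform law). A grid rather than
  i.i.d. draws keeps the gene → half-life map identical across runs, so a
  panel generated at one oxidation load can be scored against a reference
  generated at another, and strict monotonicity of derepression in
  half-life is checkable gene-by-gene. The range reflects the span from
  rapidly turned-over regulatory proteins to stable housekeeping ones.
* `fc_noise_sd = 0.4` is a realistic replicate-level standard error for DE
  log2 fold-change estimates in small-replicate designs.
* `exposure_time = 6` h matches a light-stress time-course scale on which
  short-lived repressors have decayed but stable proteins have not.

What the generators deliberately do **not** emulate: count-level
(negative-binomial) noise, library-size effects, correlated co-regulation,
batch structure, or unbalanced reference sign distributions. Passing the
packaged simulation studies therefore demonstrates the correctness of the
estimators and their calibration under the stated model, not robustness to
every property of real RNA-seq data.

# Validation study sizes and numerical choices

The packaged studies (in `tests/testthat/`) use sizes chosen for
statistical resolution:

* Mixture recovery: reference of 10⁴ genes (10% induced), queries of
  1000 genes, 20 replicates per mixing fraction f ∈ {0, ¼, ½, ¾, 1};
  mean recovered f̂ is required within ±0.05 and mean TAI within ±0.03 of
  `f + (1−f)/2`.
* Null calibration: 500 null queries of 8000 genes from a 8×10⁵-gene
  reference. Two sizes matter here: the exact binomial p-value is a lattice
  with spacing ~1.6/√n, so uniformity on [0, 1] is only resolvable once n
  is a few thousand; and the background pool must dwarf the query so that
  without-replacement sampling is effectively binomial (variance deflation
  ≈ n/N ≈ 1%). Hence a large reference and n = 8000.
* Mechanistic monotonicity: mean TAI over 30 panels of 2×10⁴ genes per
  oxidation load λ ∈ {0, 0.05, 0.1, 0.3}, scored against a reference panel
  at λ = 1; selection uses raw p-values, since after BH adjustment a
  no-oxidation panel correctly has no discoveries at all, leaving nothing
  to score.
* Fisher's exact test is cross-checked against exhaustive hypergeometric
  enumeration on every 2×2 table with all margins ≤ 12; the BH adjustment
  and the binomial null test against literal step-up / mass-enumeration
  oracles.

Numerical conventions: probability ties in the two-sided Fisher and
binomial tests are resolved within 1e-7 relative tolerance; waterfall ties
break lexicographically; inverted calibration concentrations within
1e-12 of zero (relative to the calibrated range) snap to zero so blanks are
exactly zero; standard-curve slopes below 1e-10 of the response scale are
flagged unusable rather than inverted.

# Limitations

* TAI is a sign statistic: it discards reference effect sizes by design,
  so a query overlapping weakly-induced reference genes scores as high as
  one overlapping the strongest arrest markers; the waterfall plot is the
  intended diagnostic for that distinction.
* The drop-policy TAI is undefined for queries disjoint from the reference
  (an explicit error, never 0/0).
* The denominator convention behind any externally published overlap
  percentage may differ; both directions are always reported.
* Signature correlation here is a generic reimplementation and will not
  numerically match any specific hosted tool.
* The mechanistic simulator's competence → fold-change mapping is a
  modelling choice; its outputs are labelled as such in their provenance
  notes.
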