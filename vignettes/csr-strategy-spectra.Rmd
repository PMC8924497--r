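---
title: "From leaf traits to ecological strategy spectra and their diversity correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From leaf traits to ecological strategy spectra and their diversity correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csrspectra)
```

## The model

Grime's CSR scheme describes vascular plants as compromises among three
selection regimes: competition (C), abiotic stress (S) and disturbance
(R). Because the three percentages sum to 100, a species is a point in a
ternary simplex. The StrateFy protocol (Pierce et al. 2017, *Functional
Ecology*) positions a species in that simplex from three leaf traits that
capture the global spectrum of plant form and function:

* **LA** (leaf area, mm²) — organ size; large values pull toward C.
* **LDMC** (leaf dry matter content, %) — tissue density and resource
  conservatism; high values pull toward S.
* **SLA** (specific leaf area, mm² mg⁻¹) — acquisitive leaf economics;
  high values pull toward R.

`csr_score()` applies, per axis: a trait transform (100·√(LA/LA_max) with
LA_max the global calibration maximum of 894,205 mm²; logit(LDMC/100);
ln SLA), a fitted regression curve onto the raw axis, a rescale by the
calibration's recorded (minimum, range) to a 0–100 value (the SLA axis is
recorded on a descending raw scale and therefore inverted), clamping to
[0, 100], and a final normalization of the three values to sum 100. The
curve coefficients and rescale constants are not estimated by this
package; they ship as a versioned, checksummable CSV
(`stratefy_calibration_v1.csv`, version string `stratefy-global-v1`)
transcribed from the published global calibration, and
`read_calibration()` validates the structural contract (three axes, each
bound to its trait, positive ranges). The regression curves are only
meaningful inside the calibration data's trait space, so leaf areas above
LA_max are clamped with a warning rather than extrapolated. A triple in
the extreme corner where all three rescaled values are zero (tiny,
low-SLA, low-LDMC leaves — outside anything in the calibration data) has
no defined strategy and raises an explicit degenerate-score error naming
the species.

Two numerical details are deliberate. Ties at exactly 50% belong to the
central group, so the three corner regions are open sets — a convention
that also makes the partition well-defined on the shared midlines. And the
final percentages are clamped to [0, 100] after normalization purely to
absorb floating-point round-off at the simplex boundary (a pure-S species
can otherwise score 100 + 1e-14).

## The four-group partition and the spectrum

Connecting the midpoints of the triangle's axes yields four sub-triangles:
a species with any component above 50% sits in that corner's group
(C-, S- or R-group), otherwise it is an intermediate (Int-group)
strategist. `classify_csr()` implements this with the strict-inequality
rule; the test suite checks it against an independent geometric
point-in-sub-triangle oracle on the full 1°-spaced grid of the simplex
(5,151 points), including the boundary convention.

The **ecological strategy spectrum** of a community unit is the proportion
of its species in each group. It is presence-based — each species counts
once, reflecting that the spectrum describes the composition of the
species pool, not the stand structure. An abundance-weighted variant is
available (`weighted = TRUE` in `plot_spectra()`) for sensitivity
analysis, but it is not the default and not used by the pipeline outputs
unless requested. Spectra are produced at two levels: per plot (the rows
of the response matrix for ordination) and per forest type (the pooled
site species list, each species counted once). The two levels answer
different questions and are both exported; plot-level rows are the unit of
all inference here.

## Diversity indices and collinearity

Per plot we compute species richness, stem abundance and the
Shannon–Wiener index H = −Σ pᵢ ln pᵢ (natural log by default; the log base
is exposed because conventions differ, and H in bits or dits rescales all
downstream SRCs by a constant). Shannon values are delegated to
`vegan::diversity()`. Because the three indices are mathematically
entangled (H is built from richness and abundance), `vif()` reports
variance inflation factors (1/(1−R²ⱼ), flagging > 10) before they are used
jointly; under the synthetic defaults richness is indeed flagged (VIF ≈
16), which is worth knowing when reading the joint RDA — the marginal
permutation tests and the variance partitioning are the collinearity-aware
summaries.

## Inference chain

* **SRC models.** For each of the 4 groups × 3 indices we fit ordinary
  least squares on plot-level proportions and report the standardized
  coefficient (slope × sd(x)/sd(y); equal to Pearson's r for a single
  predictor) with the two-sided slope test. Group proportions with zero
  variance (e.g. an R-group absent outside one forest type) return a
  flagged `"no variance"` row rather than an error. A site fixed-effect
  adjustment is available (`adjust_site = TRUE`) for within-site
  associations. We chose plain linear fits over a mixed model because the
  standardized-coefficient summary is defined for them and no
  random-effects structure is implied by the design; a practitioner
  wanting shrinkage can refit with `lme4` on the exported tables.
* **Group comparison.** A one-way F statistic (explicit sums of squares)
  across the four group-proportion distributions, tested by label
  permutation.
* **RDA.** The plot spectra are Hellinger-transformed
  (`vegan::decostand()`), column-centered, and regressed on the z-scored
  indices; the SVD of the fitted values gives constrained eigenvalues,
  site/response/predictor scores, R² and the Ezekiel-adjusted R²
  (1 − (1−R²)(n−1)/(n−k−1)). Significance uses unrestricted row
  permutation of the predictors, seeded, with
  p = (1 + #{F\* ≥ F}) / (1 + n_perm), so p is bounded below by
  1/(n_perm + 1). A numerically perfect fit reports F = ∞ rather than a
  round-off-sign artifact. Axis percentages are reported both as shares
  of total and of constrained variance, since both conventions are common.
  The implementation is plain normal-equations linear algebra and is
  cross-checked in the tests against both a brute-force oracle (explicit
  projection matrix + eigendecomposition) and `vegan::rda()`.
* **Retention and variance partitioning.** Predictors keep their place if
  their marginal single-predictor RDA has permutation P < α (default
  0.05). `varpart3()` computes adjusted R² for all seven predictor
  subsets and decomposes the full-model adjusted R² by
  inclusion–exclusion into unique (a, b, c), pairwise-shared (d, e, f)
  and three-way-shared (g) fractions; individual fractions can be
  negative, as usual for adjusted-R² partitions. The "independent
  contribution" quoted for a predictor is its singleton-model adjusted
  R², the quantity a Venn diagram displays.

## The synthetic landscape generator

The generator exists so that every stage — and the chain's ability to
recover a known signal — can be tested without field data. Its committed
defaults emulate a four-zone survey design: 4 forest types × 50 plots
(0.04 ha, stems with DBH ≥ 1 cm), per-site species pools sized to the
surveyed counts (243, 171, 115, 7), per-plot richness uniform in
site-specific ranges (20–60, 12–40, 8–30, 2–7), and Fisher log-series
stem abundances (x = 0.95, the textbook species-abundance model for such
censuses). Traits are drawn from four strategy *archetypes* — log-normal
LA and SLA, scaled-beta LDMC — mixed in site-specific shares, and each
species' latent group is its *scored* classification under the shipped
calibration, so the scoring engine remains untouched ground truth. The
archetype parameters and shares were fixed once so that the scored pools
reproduce the qualitative zonal ranking (an S-heavy, species-rich
tropical pool; Int-heavy mid-latitude pools; ruderals only in the
subtropical pool; a species-poor pure-S cold-temperate pool).

The diversity–strategy coupling is implemented at the *sampling* level:
when a plot of richness k draws its species, C- and Int-classified
species are weighted by exp(γ·(k − mean richness) + δ), with γ the
coupling strength (default 0.06 per species of richness) and δ a
plot-level N(0, 0.4²) tilt shared by the C/Int pool. The δ term emulates
compositional overdispersion among plots — real plots differ in
composition beyond binomial sampling noise — and keeps the plot-level
proportion variance from being dominated by the 1/k sampling term. Traits
are never edited by the coupling, so recovered associations are
attributable to community assembly, not to trait drift.

**What the generator does not emulate:** spatial structure and
autocorrelation among plots, phylogenetic trait conservatism, intraspecific
trait variation across plots, and observational error in the census.
Passing recovery tests therefore show that the chain detects
assembly-level coupling under idealized sampling; they do not certify
behavior under spatially or phylogenetically structured noise.

## Null configuration and what the tests claim

A type-I error rate is only defined where the null hypothesis is true.
With site-structured pools, a landscape with γ = 0 still has a real
association between diversity and spectrum composition (the species-poor
pure-S site guarantees it), so calibration of the SRC slope test is
checked under an *exchangeable-plots* configuration (`null_config()`): one
homogeneous site, one pool with all four groups, a common 20–60 richness
range, γ = 0. There the expected group proportion of a plot is independent
of its richness by construction. Residual proportions are still mildly
heteroscedastic (binomial variance ∝ 1/k), which is why the null
configuration uses the moderate richness range and the overdispersion
term; an analytic variance calculation during design indicated the OLS
slope test is then calibrated to within a few thousandths, and the
replicated check (500 landscapes) agrees (empirical rate ≈ 0.046 at seed
1).

Problem sizes used by the validation suite were chosen to keep the full
run comfortably interactive: 10⁵ random triples for the scoring bounds,
the complete 5,151-point grid for the partition, 100 coupled and 500 null
landscapes (200 plots each) for recovery and calibration, and 999
permutations wherever a permutation p is reported.

## Known limitations

* The calibration is a transcription of the published global leaf-trait
  calibration; re-deriving it (the PCA behind the curves) is out of scope,
  and traits outside its domain are clamped, not modeled.
* The 19-category StrateFy class labels are not computed; only the
  four-group midpoint scheme is first-class.
* No mixed-effects estimation, forward selection beyond the single
  α-retention rule, rarefaction, or spatially explicit analysis.
* Site-level spectra pool species lists; if sampling effort differs
  strongly among sites, the pooled spectrum inherits that bias.
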