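---
title: "Methods: toxicity, diversity and co-occurrence networks in PAH-polluted saline soils"
author: "pahnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: toxicity, diversity and co-occurrence networks in PAH-polluted saline soils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahnet)
```

## The scientific setting

`pahnet` analyzes soils from aged, PAH-contaminated sites along a coastal
salinity gradient, where vegetated and bare patches alternate. The questions
the pipeline addresses are the classic ones for such surveys: how toxic is
the residual PAH burden and how is it classified; how do bacterial diversity
and community structure respond to salinity (electrical conductivity, EC)
and vegetation; how abundant are the degradation genes (PAH-RHD&alpha;,
C12O) relative to total bacteria (16S rRNA); which soil variables explain
community variation; and whether co-occurrence networks in vegetated soils
are more connected and modular than in bare soils.

Because surveys of this kind rarely deposit raw sequence data, the package
ships a synthetic-study generator that reproduces the statistical structure
every downstream stage assumes. All tests and the acceptance script run
against generated data; no download is required.

## PAH toxicity scoring

Per-sample profiles of the 16 priority congeners are summarized three ways.

* **Molecular-weight fractions.** LMW = the six 2–3-ring congeners
  (NAP, ACY, ACE, FLU, PHE, ANT); HMW = the remaining ten 4–6-ring
  congeners; TPAH = LMW + HMW, exactly. An ingestion checker flags summary
  tables whose printed LMW + HMW differs from the printed TPAH by more than
  0.01 mg kg⁻¹ — a data warning rather than an error, because published
  summary tables do occasionally carry internally inconsistent rows.
* **Toxic equivalents.** TEQ_BaP = Σᵢ cᵢ·TEFᵢ. The default TEF set follows
  the Nisbet & LaGoy convention (BaP = DahA = 1; BaA, BbF, BkF, IndP = 0.1;
  ANT, CHR, BghiP = 0.01; the rest 0.001); any published set can be loaded
  from CSV. A congener present in the profile but absent from the TEF table
  is an error — silent zero-weighting of a toxic congener is the one failure
  mode this interface refuses.
* **Contamination classes.** The four-tier agronomic scheme with boundaries
  0.2 / 0.6 / 1.0 mg kg⁻¹; "heavily polluted" is strictly above
  1.00 mg kg⁻¹, so a sample at exactly 1.00 is not heavy. A two-tier mode
  collapses the lower tiers into "slightly polluted".

## Diversity and ordination

Alpha diversity uses observed richness, the **bias-corrected Chao1**
estimator S_obs + F₁(F₁−1)/(2(F₂+1)) — chosen over the classic form because
it is defined when no doubletons are observed — and the **Shannon index** in
natural log (the log base is a parameter; nats are the default because the
upstream platform is rarely explicit about its base). Chao1 refuses relative
abundances: it is undefined without integer counts. Rarefaction to an even
depth is available but off by default, since the emulated survey design does
not state rarefying.

Between-sample structure uses **Bray–Curtis dissimilarity** (via
`vegan::vegdist`) and **NMDS** (via `vegan::monoMDS`, global monotone model,
primary tie treatment), wrapped in seeded random restarts (default 20) with
the lowest-stress solution returned and coordinates centered. The package
also exposes an independent stress-1 recomputation
(`kruskal_stress1`) used by the test-suite to confirm the reported stress to
1e-8.

## qPCR quantification

Standard curves are ordinary least squares of Ct on log₁₀ copies;
amplification efficiency is 10^(−1/slope) − 1. Quantification inverts the
curve: copies = 10^((Ct − intercept)/slope) × extraction factor. The
extraction factor deliberately collapses soil mass, elution volume and
template dilution into a single user-supplied multiplier (default 1, with a
reminder message), because surveys rarely publish the individual
normalization constants. Ct values outside the fitted dilution range are
flagged as extrapolated rather than rejected. No 16S copy-number-per-genome
correction is applied.

## Association statistics

* **Correlation grids** are Spearman by default: mid-ranks for ties, Pearson
  on ranks, two-sided p from the t approximation on n − 2 df. No
  multiple-testing correction by default — raw per-pair significance is the
  convention for environment–community panels — with Benjamini–Hochberg
  behind a flag.
* **Mantel tests** correlate the aligned upper-triangle vectors of two
  distance matrices (Spearman by default, matching the panel convention) and
  permute one matrix's rows and columns jointly. The one-sided p-value is
  (1 + #{permuted r ≥ observed})/(1 + n_perm) with 999 permutations by
  default; sampled permutations exclude the identity, which the +1 already
  counts. For n ≤ 8 an exhaustive mode enumerates all permutations, making
  the p-value exact.
* **RDA** reports marginal explained fractions: each explanatory variable is
  fitted alone and scored as trace(Ŷᵥ)/trace(Y)×100 on the centered
  (optionally standardized) response, ranked descending. Marginal rather
  than forward-selected fractions are reported because the target analysis
  is a simple ranking; collinear predictors are dropped with a warning, and
  constant response columns (e.g. saturated richness in deeply sequenced
  simulations) are likewise dropped rather than fatal.
* **Group comparisons** are one-way ANOVA with Tukey HSD on the studentized
  range, lettered by the insert-and-absorb compact-letter-display algorithm:
  groups sharing a letter are not significantly different at α.

## Co-occurrence networks

Construction follows the standard genus-level recipe: on relative
abundances, drop genera whose cumulative abundance is below 0.5% of the
table total or that occur in fewer than 3 samples; compute all pairwise
Spearman correlations; keep an edge when |r| > 0.6 and p < 0.01. The
threshold is read as a magnitude — networks of this kind display negative
(green) edges, so sign is kept as an edge attribute, not a filter. Edge
p-values are raw by default (BH behind a flag). A filtered relative table is
a sub-composition whose columns sum to less than one by design; correlations
are computed on the unrenormalized values. By default the network's nodes
are the genera incident to at least one edge (the convention of
graph-visualization workflows); isolated genera can be retained with a flag.
An optional top-N-by-mean-abundance pre-selection exists but is off by
default, since node counts reported by such workflows usually reflect the
post-filter edge-incident set rather than a hard input cap.

Topology metrics: average degree 2m/n; mean local clustering with
degree-<2 nodes contributing 0; average path length on the largest connected
component (undefined otherwise, and reported as missing for edgeless
graphs); modularity Q from Louvain on the unsigned, unweighted graph, best
of 10 seeded restarts at resolution 1. "Major" modules hold ≥ 5% of nodes —
a configurable convention, since the term is used in the field without a
definition. Keystone taxa are ranked by exact unweighted betweenness
centrality, optionally excluding genera unresolved at genus rank
(uncultured/unidentified), mirroring common reporting practice.

The null model is Erdős–Rényi G(n, m): uniform simple graphs with exactly
the real network's node and edge counts. The small-world/modularity verdict
compares clustering, path length and modularity against the ensemble with
z-scores; the verdict is positive when clustering and modularity exceed the
null and Q > 0.4. **Average degree is reported as identical by
construction** — with n and m fixed, 2m/n cannot differ between a network
and its G(n, m) ensemble, so any apparent difference in that metric is
non-informative and the assessment says so instead of reproducing it.

## The synthetic-study generator

`study_config()` defines the emulated survey: 3 regions (GA, GB, GC) with
bare-soil EC means 1.25, 2.06 and 7.23 mS cm⁻¹ and per-region vegetated
multipliers (≈0.99, 0.96, 0.41 — vegetation lowers salinity most where
salinity is highest); bare TPAH means 2.30, 2.04, 1.77 mg kg⁻¹ with
vegetated multipliers ≈0.49, 0.44, 0.45; catalase elevated and TPH reduced
under vegetation; 10 samples per region × cover cell by default. Per-sample
TPAH is lognormal with a unit-mean multiplier, so configured region means
are matched in expectation, and congener weights jitter around fixed
LMW/HMW profiles so concentrations always sum to TPAH exactly.

Genus abundances are lognormal with latent guild factors rather than a
plain Dirichlet-multinomial: log-abundance = baseline + niche slope ×
centered EC + guild loading × (per-guild, per-sample standard-normal
factor) + noise, softmax-transformed and drawn multinomially at a fixed
depth of 60,000 reads (a realistic mid-range library size; fixed for
simplicity, configurable). The guild factors exist precisely so that
above-threshold Spearman correlations are plantable — a network stage tested
only on independent noise would never build an edge. Guild loadings are
per-cover (vegetated 0.9, bare 0.4), which is what makes vegetated networks
denser.

Two generator details deserve justification:

* **The halotolerant guild.** 7% of genera carry a strong positive EC slope
  (+0.6 log units per mS cm⁻¹) from a moderately low fixed baseline. At high
  salinity they surge to dominance, which is the mechanism by which evenness
  — and therefore Shannon diversity — declines along the EC gradient, just
  as halophilic genera dominate the saltiest samples of real surveys. The
  surge is kept moderate and consistent (fixed baselines) deliberately:
  compositional closure means any large EC-driven reallocation correlates
  *all* genera across the bare stratum's wide EC range and would flood the
  bare network with gradient-driven edges. The default calibration holds
  both configured signs — negative EC–Shannon association and denser
  vegetated networks — in ≥95% of 100 seeds at 30 samples per cell.
* **Unit-mean gene effects.** Gene copy numbers apply EC, vegetation and
  noise effects as a multiplier normalized to unit arithmetic mean across
  the cohort, so the configured gene means (16S 4.02×10⁸, PAH-RHDα
  1.37×10⁶, C12O 2.26×10⁵ copies g⁻¹) are the realized cohort means
  exactly — the quantity such surveys actually report. The generator also
  emits Ct values and the 7-point dilution series that produced them, so the
  qPCR module can be round-trip tested.

Setting `noise_sd_log = 0` silences *every* stochastic draw, turning the
generator into a deterministic mean-only mode used by the null-effect tests.

Reproducibility: one study seed is expanded into per-stage child seeds by a
fixed offset scheme (`pahnet:::pahnet_seed_offsets`), so each stage is
independently reproducible and the run manifest records every child seed.

What the generator does **not** emulate: read-level errors or chimeras,
spatial autocorrelation between sites, compositionality-aware correlation
structure (no SparCC-style inference is attempted), or higher moments of the
survey's group distributions — only means and spreads are matched, since the
emulated design reports means ± SD. Passing tests therefore demonstrate the
pipeline's statistical behavior under a faithful but idealized data model,
not performance on any particular real survey.

## Numerical choices and degenerate inputs

* Spearman p-values use the t approximation everywhere (including edges), so
  small-sample exactness is traded for consistency with the stated edge
  rule; the oracle tests pin the implementation to the formula at 1e-12.
* NMDS ties are handled by the primary approach; restarts default to 20.
  Stress is Kruskal stress-1 in [0, 1].
* Perfect correlations (|r| = 1 within 1e-15) are assigned p = 0 to avoid
  sign flips from floating-point noise at the t-statistic's pole.
* All-zero sample pairs get Bray–Curtis distance 0 with a warning; all-zero
  samples cannot be normalized to relative abundances (error naming the
  sample); constant genera are excluded from network pairing with a warning.
* Boundary Ct values at the edge of the fitted dilution range are not
  flagged as extrapolated (1e-9 relative tolerance).
* Problem sizes in the test-suite: oracle fixtures use ≤ 10 genera and ≤ 14
  samples; calibration suites use 100–1000 replicates; the parameter-recovery
  suite runs 100 studies at 30 samples per cell. These sizes give stable
  pass/fail behavior at sub-minute runtimes per suite.

## Known limitations

* Correlation-based edges on relative abundances inherit compositional bias;
  the package states this rather than correcting it (no SparCC/SPIEC-EASI).
* The Erdős–Rényi null preserves only (n, m), not the degree sequence; a
  degree-preserving rewiring null is out of scope.
* The TEF set actually used by any given survey may differ from the default;
  TEQ values are therefore comparable only under a stated TEF table.
* Tukey letters use the studentized-range p-values from `TukeyHSD`; the
  multivariate-t adjustment of `multcomp` can differ in borderline cases
  (the tests compare partitions on clearly separated fixtures).
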