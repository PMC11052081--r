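---
title: "Models and methods behind hadalCLPP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hadalCLPP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadalCLPP)
```

hadalCLPP analyses two views of a deep-sea microbial community: its carbon
metabolism, read off a Biolog EcoPlate over a long incubation, and its
composition and co-occurrence structure, read off a 16S ASV table. This
vignette explains the models implemented, the parameters that matter, and the
choices made where convention left the design open.

## 1. Plate model and turbidity correction

An EcoPlate carries 31 carbon substrates in triplicate plus three water
blanks. Wells are read at 590 nm (tetrazolium violet colour, the metabolic
signal) and 750 nm (turbidity — particles and fungal growth absorb here
without reporting substrate oxidation). `correctPlateSeries()` computes per
well and timepoint

> corrected = (OD590 − OD750) − mean over the 3 control wells of (OD590 −
> OD750), clipped at 0.

Three decisions were open and are fixed as follows:

* **Control aggregation.** The control term is the *mean* of the three
  blanks at the same timepoint. A single designated blank would be noisier;
  the mean halves the control's read-noise contribution without changing the
  expectation.
* **Negative clipping.** Negative corrected values (turbidity exceeding
  colour, or control drift) are physically meaningless as colour development
  and would deflate plate means, so they are clipped to 0.
* **Time grids.** The two wavelengths must be read on identical time grids;
  no interpolation is attempted. Plate readers record both channels in one
  session, so a mismatch indicates a corrupt export rather than a timing
  difference worth modelling.

Two invariances follow and are property-tested: the correction is unchanged
by row order of the input file, and adding any constant to *both* channels of
every well cancels exactly.

## 2. Physiological statistics

**AWCD.** The average well colour development at time *t* is the mean of the
control-corrected substrate ODs, replicates averaged per substrate first, and
*n* equal to the substrate count of the set being averaged — all 31, or one
carbon category's substrates for per-category utilization. Replicate
averaging before any index computation is the default policy; per-replicate
computation is possible by subsetting the `PlateSeries` rows directly.

**Richness.** The oxidised-substrate count: substrates whose
replicate-averaged corrected OD reaches 0.5 at two *consecutive* reads. The
consecutive-read requirement guards against single-timepoint read spikes.
Field usage is split between a count of substrates and a sum of their ODs;
the count is the default (it is reported as a substrate-number index) and the
OD-sum is available via `statistic = "sum"`.

**Simpson and Shannon.** Both are computed from the substrate proportions
`Pi = ODi / Σ ODi` at a reference timepoint. The Simpson index follows the
plate-profiling convention `D = −ln Σ Pi²` — *not* the classical
Gini–Simpson `1 − Σ Pi²`. This is deliberate: the convention is what the
plate literature reports, and both indices are 0 for a single dominant
substrate and maximal (ln N, (N−1)/N respectively) at uniformity, so they
rank communities identically. `giniSimpson()` exists for comparison but no
pipeline default uses it. Shannon is `H = −Σ Pi ln Pi` with zero proportions
contributing zero; the identical routine backs the ASV-table Shannon so the
two arms cannot drift apart.

**Reference timepoint.** Nothing in standard practice fixes *when* the
indices are read. The default is the detected start of the stable phase —
the indices then describe the community at functional saturation — falling
back to the final timepoint when no stable phase is found. Any explicit
timepoint can be passed instead. A plate with zero total colour development
at the reference time gets `NA` indices, never zeros: an inactive plate has
undefined composition, not zero diversity.

**Phase detection.** `detectPhases()` scans forward slopes of the AWCD curve
over a window of sampling intervals (default 3). The exponential phase
starts when the slope first exceeds `slopeEps`; the stable phase starts at
the first later time from which the slope stays below `slopeEps` to the end
of the incubation. The default `slopeEps` is 2% of the final AWCD per 24 h:
scale-free in OD (plates with strong and weak colour get comparable calls)
and tied to the 24 h sampling cadence. On a noise-free logistic curve the
detected stable start lands within one sampling interval of the analytic
99%-saturation time `t0 + ln(99)/r`, which is the property the tests pin.

## 3. Community statistics

Relative abundance, Shannon and Pielou evenness (`E = H / ln S_obs`,
undefined for single-ASV samples) are standard. Bray–Curtis dissimilarities
are computed on relative abundances (community *profiles*, not library
sizes) through `vegan::vegdist`.

ANOSIM is implemented in-package because two details needed pinning: ranks
use midranks for ties, and the Monte Carlo p-value uses the add-one
estimator `p = (1 + #{R* ≥ R}) / (1 + nperm)`, which cannot return 0 and is
exact under exchangeability. For small designs (n ≤ 9) `exact = TRUE`
enumerates every label permutation; the test suite checks the Monte Carlo
and exact paths against an independently coded brute-force oracle and the R
statistic against vegan's implementation.

## 4. Co-occurrence networks

The network stage follows the standard amplicon workflow: restrict to the
top 200 ASVs by total relative abundance (ties broken lexicographically so
the selection is deterministic), compute pairwise Spearman ρ, convert to
two-sided p-values via the t approximation with n−2 degrees of freedom,
BH-adjust over the strict upper triangle, and keep edges passing *both*
gates: `|ρ| > 0.6` and adjusted `p < 0.05`. The t approximation is the
pragmatic choice at the 5–20 samples typical of cruise data; an exact
permutation p is available for n ≤ 8. Zero-variance ASVs have no defined
rank correlation and are excluded with a report rather than silently
dropped.

Modules come from Louvain with a mandatory seed; modularity is Newman's Q on
the **unweighted, sign-agnostic** edge set. Treating the gated edge set as a
plain graph matches how plate-to-publication workflows built on Gephi-style
tooling report Q; |ρ|-weighted clustering is available as an option but is
not the default. Q of an edgeless network is undefined (`NA`), not 0. For
graphs of ≤ 10 nodes the tests bound Louvain's Q by an exhaustive maximum
over all partitions (restricted-growth-string enumeration), and the
two-triangle graph pins the closed-form Q = 0.5.

Edge-sign summaries report the positive fraction overall, within archaea,
within bacteria, between domains, and per unordered phylum pair; strata with
no edges are omitted rather than reported as 0/0.

A caveat carried in the documentation: plain Spearman on relative abundances
is not compositionality-aware. Proportions must sum to one, so strong
blooms induce spurious negative correlations among the remaining taxa;
SparCC-style inference is out of scope because the implemented workflow is
the field-standard Spearman/FDR one.

## 5. The synthetic-data generator

The generator exists so that every stage is testable end to end without
cruise data; it emulates the statistical structure the analyses assume, not
any particular dataset.

**Plates.** 590 nm = logistic colour (per-substrate asymptote K, rate r,
midpoint t0, scaled by the sample's substrate affinity) + turbidity + shared
baseline drift + read noise; 750 nm = the same turbidity + noise; control
wells carry the baseline only. Defaults: readings every 24 h for 100 days;
K ∈ U(0.6, 1.8), r ∈ U(0.005, 0.02) per hour, t0 ∈ U(240, 960) h — midpoints
between day 10 and 40, bracketing stable-phase onsets of 20–40 days;
turbidity 0.05 ± 0.01 OD, read noise 0.01 OD, baseline drift 0.02 OD over
the run. The noise magnitudes are order-of-magnitude plate-reader values;
no public dispersion data exists for long marine incubations, so they are
documented guesses held fixed. Logistic kinetics are the simplest family
producing the observed exponential-then-stable AWCD narrative.

**ASV tables.** Each of g guilds has a latent Gaussian factor per sample;
member ASV i gets `z_i = sqrt(ρ)·f_guild + sqrt(1−ρ)·ε_i`, so the latent
within-guild correlation is exactly ρ. Abundances are log-normal
(`exp(base_i + σ·z_i)`, base ~ N(5, 0.5), σ = 1 — mean counts around 250
per ASV, i.e. ~20k reads per 80-ASV sample, a realistic amplicon depth),
and counts are Poisson draws. Two design points deserve emphasis:

* **Factor orthogonalisation.** The guild factors are orthogonalised across
  samples (QR decomposition, rescaled to unit variance). Independently drawn
  factors can correlate by chance at 20 samples — strongly enough that two
  "planted" guilds share most of their rank structure and merge into one
  network module. Orthogonalisation makes the planted between-guild
  correlation exactly zero, so g planted guilds really are g distinct
  guilds; recovered module counts then equal g reliably across seeds.
* **Rank attenuation.** Poisson rounding attenuates the realised Spearman
  below the planted latent ρ (≈ 0.90 realised for ρ = 0.95 at the default
  depth). The generator's statistical contract — mean within-guild Spearman
  within 0.1 of ρ across 50 seeds — is tested at defaults.

Counts use a log-normal latent with Poisson rounding rather than a
Dirichlet-multinomial: the downstream statistics are rank-based, so matching
marginal count dispersion exactly buys nothing, and the latent-factor
parameterisation makes the planted correlation explicit.

**Metadata.** Depth profiles are qualitative shape emulations, not fits:
temperature decays exponentially from ~19.9 °C at the surface to ~1.1 °C at
5000 m (both endpoints inside the ranges reported for trench water columns);
salinity dips to a minimum at 800 m — the lower boundary of the twilight
zone — then rises slightly; nitrate+nitrite and phosphate increase with
depth; ammonium peaks at the surface. Samples split between water-column
depths {0, 200, 800, 2000, 5000 m} and deeper benthic-boundary-layer
stations.

**What passing tests do and do not show.** The generator produces clean
logistic kinetics, exactly orthogonal guilds, Poisson counts and noiseless
metadata. Real plates have correlated well noise, condensation artefacts and
replicate disagreement; real ASV tables have compositional coupling,
overdispersion beyond Poisson, and guilds that overlap. Green tests
demonstrate that the *computations* are correct and the planted structure is
recoverable — not that the pipeline's thresholds are optimal for any real
cruise dataset.

## 6. Problem sizes and determinism

The test and acceptance workloads use 80-ASV × 20-sample tables, 101-point
plate series, 999-permutation ANOSIMs and 20-seed replication — sizes chosen
so the full suite runs in minutes on one core while still exercising every
code path at realistic shape. Every stochastic step (generators, ANOSIM
permutations, Louvain) takes an explicit seed, and the pipeline manifest
records all of them: re-running a manifest reproduces byte-identical
outputs, and no stage reads the wall clock for anything numeric.

## 7. Known limitations

* Spearman/FDR networks are not compositionality-aware (see §4).
* The plate arm does not fit kinetic parameters to observed wells; logistic
  curves live only in the generator. Estimating in-situ mineralisation rates
  from plate kinetics would need isotope tracing, not colorimetric assays.
* Pielou's J is assumed wherever "evenness" is reported; other evenness
  measures are not implemented.
* nMDS ordination and figure rendering are intentionally absent; the
  Bray–Curtis matrix export is the hand-off to ordination tooling.
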