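# hadalCLPP

Community-level physiological profiling (CLPP) and co-occurrence network
analysis for stratified marine microbial communities, of the kind sampled in
deep-sea water columns (WC) and benthic boundary layers (BBL).

Heterotrophic microbes in the deep ocean are profiled two complementary ways:
functionally, by how they oxidise the 31 carbon substrates of a Biolog
EcoPlate during long incubations, and compositionally, from 16S amplicon
sequence variant (ASV) tables. This package implements both arms as one
tested pipeline for microbial ecologists:

* **Plate kinetics.** The 96-well EcoPlate is read at 590 nm (tetrazolium
  colour) and 750 nm (turbidity) every 24 h over 100-day incubations. Per
  well and timepoint the corrected colour is
  `(OD590 − OD750) − mean(control wells)`, clipped at 0. From the corrected
  series, the package computes the average well colour development

      AWCD(t) = Σᵢ (Rᵢ − C) / n

  over all 31 substrates or per carbon category (carbohydrates, polymers,
  phenolic, carboxylic acids, amino acids, amines), the substrate richness
  *R* (substrates with corrected OD ≥ 0.5 at two consecutive reads), the
  substrate proportions `Pᵢ = ODᵢ / Σ ODᵢ`, the Simpson index in the
  plate-profiling convention `D = −ln Σ Pᵢ²`, the Shannon index
  `H = −Σ Pᵢ ln Pᵢ`, and the start of the exponential and stable growth
  phases from the AWCD slope.

* **Community statistics.** Relative abundance, per-sample Shannon/Pielou
  evenness, Bray–Curtis dissimilarity `d = Σ|x−y| / Σ(x+y)`, and a
  permutation ANOSIM (`R = (r̄_between − r̄_within)/(M/2)` on midranks, with
  exact enumeration available at small n).

* **Co-occurrence networks.** Top-200 ASVs by relative abundance, pairwise
  Spearman ρ with t-approximation p-values, Benjamini–Hochberg FDR, edges
  where `|ρ| > 0.6` **and** FDR-adjusted `p < 0.05`, Louvain modules with
  Newman modularity Q (`Q > 0.4` read as modular structure), and
  positive-edge proportions overall and per taxonomy stratum
  (archaea–archaea, bacteria–bacteria, archaea–bacteria, phylum pairs).

* **Synthetic data.** A first-class generator for both inputs: logistic
  per-substrate colour development with turbidity and control baselines, and
  ASV tables with planted correlated guilds over a realistic depth gradient,
  so every stage is testable without cruise data.

## Worked example

```r
library(hadalCLPP)

# --- plate arm: simulate, correct, profile -------------------------------
lay <- ecoPlateLayout()                       # bundled 31-substrate map
sim <- simulatePlate(plateSimConfig(seed = 42), sampleId = "surface-0m")
ps  <- correctPlateSeries(sim$readings, lay)
clppProfile(ps)
#> ClppProfile for sample surface-0m
#>   reference time: 840 h; AWCD: 0.7703
#>   richness: 27  Simpson D: 3.266  Shannon H: 3.343
#>   phases: exponential from 168 h, stable from 840 h

# --- community arm: diversity, ANOSIM, network ---------------------------
asv <- simulateAsvTable(communitySimConfig(seed = 42))
an  <- anosimTest(brayCurtis(asv), colData(asv)$layer, nPerm = 999, seed = 1)
sprintf("ANOSIM R = %.3f, p = %.3f", an$statistic, an$p_value)
#> "ANOSIM R = 0.002, p = 0.407"

cooccurrenceNetwork(asv, seed = 1)
#> CoocNetwork: 80 nodes, 764 edges (|rho| > 0.6 , FDR < 0.05 )
#>   modules: 4  modularity Q: 0.745
#>   positive edges: 99.5%
```

Reading the numbers: after 840 h (35 days) the simulated surface community
has oxidised 27 of 31 substrates with mean colour development 0.77; its
functional diversity is near the ln 31 ≈ 3.43 ceiling, i.e. colour is spread
evenly across substrates. The simulated ASV table splits its samples between
water column and benthic boundary layer; with no planted layer effect the
ANOSIM R is near 0. Its four planted guilds come back as exactly four
network modules with Q = 0.745 — far above the 0.4 modularity bar for
calling a network modular.

The whole chain also runs as one orchestrated pipeline with a reproducibility
manifest:

```r
man <- runPipeline(system.file("extdata", "demo_pipeline.yaml",
                               package = "hadalCLPP"), outDir = "run1")
pipelineReport(man)
```

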