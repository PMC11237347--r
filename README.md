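# occufreq

Scale-dependent occupancy-frequency analysis for metacommunities, with
dispersal-trait grouping of taxa.

An occupancy frequency distribution (OFD) records how many species occupy
few, some, or most sites in a region. Its shape is diagnostic of community
structure: a **bimodal** OFD (many rare "satellite" species plus a second
mode of widespread "core" species) suggests strong site connectivity or a
core–satellite dynamic, a **unimodal** satellite-dominated OFD suggests
dispersal limitation, and a flat ("random") OFD suggests weak structuring.
Because the OFD shape changes with the spatial extent over which occupancy
is measured, and because species with different dispersal abilities respond
differently, `occufreq` analyses OFDs *per spatial extent* and *per
dispersal group*.

The package implements the full pipeline:

1. **Trait handling** — fuzzy-coded dispersal trait affinities (codes 0–3)
   are merged across sources (maximum rule), standardized to per-trait
   proportions, and missing profiles imputed from family then superfamily
   means (`merge_categories`, `standardize_affinities`, `impute_missing`).
2. **Dispersal grouping** — Gower dissimilarity between taxa
   (`gower_dissimilarity`), Ward clustering (`ward_cluster`, ward.D2),
   cluster-count diagnostics (`wss_curve`), group separation by ANOSIM
   (`anosim`), and trait–group association by multilevel pattern analysis
   over all group combinations (`multilevel_pattern`).
3. **Hierarchical resampling** — an *assemblage resampling unit* (ARS) pools
   one sample unit per season from one reach (`draw_ars`); a *site random
   sample* (SRS) combines 16/15/16/16 ARSs at the reach / subbasin / basin /
   region extents with fixed per-reach quotas (`draw_srs`,
   `generate_ensemble`). ARSs below a richness threshold are redrawn.
4. **RSOC model inference** — each SRS yields a ranked species occupancy
   curve (RSOC; occupancy against occupancy rank). Five candidate models are
   fitted by Levenberg–Marquardt least squares (`fit_rsoc_models`):

   | model | equation | OFD pattern |
   |---|---|---|
   | exponential (concave) | O = y₀ + a·e^(−bR) | unimodal |
   | power × exponential | O = a·R^b·e^(−cR) | bimodal if b̂ > 0 else unimodal |
   | sigmoidal, symmetric | O = a / (1 + e^(−bR + c)) | bimodal |
   | sigmoidal, asymmetric | O = a·(1 − e^(−bR^c)) | bimodal |
   | linear | O = a + bR | random |

   Model support uses small-sample AIC, AICc = n·ln(RSS/n) + 2k +
   2k(k+1)/(n−k−1) with k = (number of curve parameters) + 1, and Akaike
   weights; weights are summed into bimodal / unimodal / random pattern
   probabilities (`classify_patterns`).
5. **Aggregation** — per-extent, per-group means, 2.5–97.5 % percentile
   intervals, evidence ratios, taxa numbers, and 5-class OFD histograms
   (`summarize_ensemble`, `ofd_histogram`).
6. **Synthetic communities** — a mechanistic core–satellite generator
   (`sim_config`, `generate_traits`, `generate_community`) with three
   dispersal archetypes (actively dispersing long-lived, actively dispersing
   short-lived, passively dispersing) and two documented reference regimes
   (`regime_presets`): `bimodal_reach` and `unimodal_region`.

`run_pipeline(run_config(...))` runs everything end to end and writes a CSV/
JSON/Newick artifact bundle.

## Worked example

```r
library(occufreq)

cfg    <- sim_config(seed = 42)                 # synthetic study design
traits <- generate_traits(cfg)
std    <- impute_missing(standardize_affinities(traits))
D      <- gower_dissimilarity(std)
groups <- ward_cluster(D, k = 3)
groups
#> dispersal_groups: k = 3 ( ward.D2 )
#>
#> DG1 DG2 DG3
#>  42  58  41

anosim(D, groups, n_perm = 999, seed = 1)
#> ANOSIM: R = 1.000, p = 0.001 (999 permutations)

comm <- generate_community(cfg)
comm
#> community_data: 134 taxa, 8 reaches, 4 seasons, 640 sample units

ens <- generate_ensemble(comm, "reach", resampling_config(n_srs = 200, seed = 1))
rec <- analyze_ensemble(ens, comm, groups = groups$labels)
s   <- summarize_ensemble(rec)
s[, c("extent", "group", "mean_w_bimodal", "mean_w_unimodal",
      "mean_w_random", "er_bi_uni", "mean_taxa_number")]
#>   extent group mean_w_bimodal mean_w_unimodal mean_w_random er_bi_uni
#> 1  reach   DG1          0.999        0.000259      0.000496      3862
#> 2  reach   DG2          1.000        0.000234      0.000141      4265
#> 3  reach   DG3          0.960        0.008833      0.031171       109
#>   mean_taxa_number
#> 1             23.3
#> 2             27.3
#> 3             11.9
```

At the reach extent this core-rich synthetic community is overwhelmingly
bimodal in every dispersal group; the satellite-heavy
`regime_presets()$unimodal_region` community instead gives a regional mean
unimodal weight near 1 (0.9986 for seed 1 at 500 SRSs per extent).

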