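# ciliarank

Automated quantification and rank-based scoring of two-channel
immunofluorescence (IF) staining of ciliated airway epithelium.

## The problem

IF staining of nasal-brushing slides is a first-line, pre-genetic screen
for primary ciliary dyskinesia (PCD): a test antibody against an axonemal
protein (DNAH5, DNALI1, RSPH4A, RSPH9, GAS8, CCDC39, CCDC40, SPEF2 — red
channel) is co-stained with a stable acetylated-α-tubulin axoneme marker
(green channel). Absence or mislocalization of the red signal from cilia
is diagnostic — but poor slide storage between collection and staining
produces the *same* pattern artifactually: the ciliary red signal weakens
and a nonspecific diffuse signal appears in the cytoplasm. Laboratories
comparing storage protocols (or antibodies) therefore need an objective,
automated measure of staining specificity.

`ciliarank` provides that measure as a reusable R pipeline, for
cytology/diagnostics labs and image-analysis methodologists:

1. **Segmentation** of stained objects, independently per channel
   (Gaussian smoothing → global threshold → 8-connected components →
   size window).
2. **Object parameters** — area (px and µm², with the linear pixel size,
   default 0.1136 µm/px, squared for areas), eccentricity
   `sqrt(1 − λ2/λ1)` from central second moments, radial-variance
   compactness `2π·MSD/area` (disc = 1), and intensity mass displacement
   `‖c_weighted − c_geometric‖`.
3. **Colocalization** — the directional rank-weighted colocalization
   coefficient RWC ∈ [0, 1] (midranked intensities; pixel weights
   `(Rmax − |Δrank|)/Rmax`; weight-discounted share of primary intensity
   on doubly-foreground pixels) in both directions, plus Pearson
   correlation.
4. **Pairing** — each red object is matched to the green object of
   maximal pixel overlap; analyses use only green objects with exactly
   one red child (unique pairs), and the centroid distance of each pair
   is reported in µm.
5. **Scoring** — per-slide means are screened across storage conditions
   (Kruskal–Wallis, p < 0.001), then each parameter ranks the conditions
   (or antibodies) in its better-direction, and the per-parameter ranks
   are averaged into one **overall performance rank** (1 = best).
6. **Synthetic data** — a generator of two-channel slides with known
   ground truth, where a degradation fraction δ moves red signal mass
   (exactly mass-preservingly) from the ciliary tuft into an apical
   cytoplasmic pool, emulating storage damage across a full donors ×
   conditions × antibodies study.

## Worked example

Averaging the per-parameter rank rows of a reference condition-ranking
table into the overall performance metric:

```r
library(ciliarank)
ranks <- readr::read_csv(system.file("extdata", "reference_condition_ranks.csv",
                                     package = "ciliarank"))
overall_performance(as.data.frame(ranks))
#> # A tibble: 7 × 3
#>   entity     mean_rank overall_rank
#>   <chr>          <dbl>        <dbl>
#> 1 -80_28d         1             1
#> 2 -20_28d         2.17          2.2
#> 3 -20/RT/-80      3.5           3.5
#> 4 -20_8w          4             4
#> 5 4/RT/-80        4.33          4.3
#> 6 RT/RT/-80       6.33          6.3
#> 7 RT_28d          6.67          6.7
```

Continuous frozen storage (−80 °C or −20 °C for 28 days) ranks best;
28 days at room temperature ranks worst (6.7 of 7).

A complete simulated mini-study — three donors, three storage conditions,
the two sensitivity-extreme antibodies — from image synthesis to scores:

```r
cfg <- pipeline_config(list(
  paths = list(study = file.path(tempdir(), "demo_study"),
               out   = file.path(tempdir(), "demo_out")),
  simulate = list(donors = 3, conditions = c("-80_28d", "4/RT/-80", "RT_28d"),
                  antibodies = c("RSPH4A", "CCDC39"), images_per_slide = 4,
                  seed = 42)))
pipeline_simulate(cfg)          # writes 18 slides x 4 images x 3 channels
res <- pipeline_measure(cfg)    # segmentation, features, pairing, coloc
pairing_summary(res$pairs)
#>   n_red_total n_paired percent_paired
#> 1         178      175             98

sc <- pipeline_score(cfg, res)  # aggregate -> screen -> rank -> report
sc$overall_condition
#>   entity   mean_rank overall_rank
#> 1 -80_28d       1.33          1.3
#> 2 4/RT/-80      2.33          2.3
#> 3 RT_28d        2.33          2.3
```

98% of the red objects overlap a marker object, and the best storage
condition is recovered from the images alone. (At this toy size the two
degraded conditions tie; the acceptance-scale study below separates all
seven.) `autoplot()` on a rank matrix and `plot_parameter_heatmap()` on
the parameter table give ggplot2 heatmaps; `tidy()`/`glance()` methods
return the underlying tibbles.

A command-line wrapper with `simulate` / `measure` / `score` subcommands
over a YAML config ships in `inst/cli/ciliarank.R`.

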