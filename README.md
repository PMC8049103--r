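# tcellrest

Phenotyping the redirection of CAR T cells from exhaustion to a memory-like
state by transient "rest".

Tonic (antigen-independent) signaling of some chimeric antigen receptors
(CARs) drives human T cells into exhaustion — inhibitory receptors PD-1,
TIM-3, LAG-3, CTLA-4, BTLA, 2B4 and CD39 rise while memory markers CD45RA,
IL-7R, CD27 and CD197 fall. Transiently switching the CAR off ("rest")
redirects cells toward a memory-like fate and can reverse exhaustion that
has already set in. `tcellrest` is a tested R implementation of the
computational pipeline behind that claim, for analysts working with
mass-cytometry, bulk RNA-seq and TCR clonotype data from such studies:

- **Cytometry scoring** — arcsinh preprocessing (`asinh(x / c)`, cofactor
  5), rule-based CAR+/CD8+ gating, pooled 1st–99th-percentile min–max
  normalization, and per-cell **exhaustion / memory scores** defined as the
  normalized mean expression over the 7-marker exhaustion and 4-marker
  memory panels.
- **Trajectory mapping** — a temporal kNN graph (within-day edges plus
  cross-day "grey" edges between adjacent days), Fruchterman–Reingold
  force-directed layouts, k-means detection of terminal-day regions
  (Region 1 the most exhausted, CD39-high; Region 4 the most memory-like,
  IL7R/CD45RA-high), arm-composition percentages and per-region score
  quartiles.
- **Score kinetics** — tricube-weighted local polynomial regression of
  score on day with a case-resampling bootstrap 95% band, and a
  permutation test on the least-squares slope,
  `p = (1 + #{|slope_perm| >= |slope_obs|}) / (n_perm + 1)`.
- **Transcriptome reversal** — log2-CPM normalization, z-scored
  up/down exhaustion-signature kinetics, terminal-day PCA with
  top-500 |PC1-loading| gene clustering (average linkage, 1 − Pearson
  distance), and a **reprogramming index**
  `clamp01((d(R,ON) − d(R,OFF)) / d(ON,OFF))` on PC1 centroids (1 =
  complete reversal to the always-off state).
- **Repertoire controls** — clonotype richness, Shannon, inverse Simpson
  and Pielou evenness with Monte-Carlo rarefaction and a bootstrap
  equivalence comparison, the control that rest acts population-wide
  rather than by clonal outgrowth.
- **Synthetic data** — generators for all three data streams with known
  latent truth (Beta-distributed exhaustion/memory programs, lognormal
  zero-inflated CyTOF-like intensities, negative-binomial counts,
  power-law clonotypes), so every stage has a parameter-recovery test
  surface.

See the methods vignette (`vignettes/rest-phenotyping.Rmd`) for the models,
assumptions and numerical choices.

## Worked example

Simulate the default two-arm study (continuous tonic signaling vs rest
from day 7), score cells, and quantify fate redirection:

```r
library(tcellrest)

sim    <- simulate_cytometry(sim_config(n_cells_per_arm_day = 2000, seed = 1))
events <- arcsinh_transform(sim$events, cofactor = 5)
events <- gate_events(events, default_gate_rules())
#> gate removed 3165 of 16000 cells
scored <- compute_scores(normalize_markers(events))
scored
#> scored_events: 12835 cells x 22 normalized markers
#> scores set (exhaustion mean 0.470, memory mean 0.402)

regions <- detect_regions(scored, R = 4, seed = 1)
region_composition(regions)
#>            arm region   n       pct
#> 1    ALWAYS_ON      1 674 42.151345
#> 2    ALWAYS_ON      2 742 46.404003
#> 3    ALWAYS_ON      3 108  6.754221
#> 4    ALWAYS_ON      4  75  4.690432
#> 5 RESTED_D7_11      1  71  4.443054
#> 6 RESTED_D7_11      2 111  6.946183
#> 7 RESTED_D7_11      3 717 44.868586
#> 8 RESTED_D7_11      4 699 43.742178

kin <- score_kinetics(scored, n_boot = 100, seed = 1)
kin$trends
#>            arm score_kind        slope p_perm
#> 1    ALWAYS_ON exhaustion  0.025816753  0.001
#> 2    ALWAYS_ON     memory -0.010179911  0.001
#> 3 RESTED_D7_11 exhaustion -0.002678078  0.001
#> 4 RESTED_D7_11     memory  0.019690920  0.001
```

Reading the output: ~89% of always-on terminal cells fall in the exhausted
region pair (1–2) and ~89% of rested cells in the memory pair (3–4); the
always-on arm's exhaustion score climbs ~0.026 per day (permutation
p = 0.001) while the rested arm's memory score climbs ~0.020 per day — the
fate redirection the pipeline is built to quantify.

The full pipeline (simulation → scoring → trajectory → kinetics →
transcriptome → repertoire, with a provenance manifest) runs from one
config:

```r
run_pipeline(demo_config("demo_out", seed = 1))
```

or from the shell via the thin CLI:

```sh
Rscript inst/cli/tcellrest demo --out-dir demo_out --seed 1
Rscript inst/cli/tcellrest run  --config my_study.yaml
```

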