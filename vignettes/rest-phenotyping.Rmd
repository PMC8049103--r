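---
title: "Methods: phenotyping the redirection of CAR T cells by transient rest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping the redirection of CAR T cells by transient rest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Tonic (antigen-independent) signaling of some chimeric antigen receptors
drives human T cells into exhaustion: inhibitory receptors rise (PD-1,
TIM-3, LAG-3, CTLA-4, BTLA, 2B4, CD39), memory markers fall (CD45RA, IL-7R,
CD27, CD197), cytokine secretion collapses. Transiently switching the CAR
off ("rest") — by drug-controlled receptor degradation or kinase inhibition
— can redirect cells toward a memory-like fate and reverse exhaustion that
has already set in. `tcellrest` implements the computational pipeline that
quantifies this redirection from three data streams:

1. **Mass cytometry**: per-cell exhaustion and memory scores, temporal
   kNN/force-directed trajectory maps, and terminal-day region
   quantification.
2. **Bulk RNA-seq**: exhaustion-signature kinetics, PCA of terminal
   samples with top-PC1-loading gene clustering, and a scalar
   reprogramming index.
3. **TCR clonotypes**: diversity and rarefaction controls showing the
   redirection is population-wide rather than clonal outgrowth.

Because no per-cell data ships with the package, every stage is exercised
against a synthetic-data generator with known ground truth, turning each
analysis into a parameter-recovery problem.

## Cytometry scores

Raw ion counts are arcsinh-transformed, `x -> asinh(x / cofactor)` with
cofactor 5 (the mass-cytometry convention; configurable). Gating is by
explicit threshold rules on the transformed scale (default CAR > 1.5 and
CD8 > 1.5); no automatic gate fitting is attempted. Each marker is then
min–max scaled between its pooled 1st and 99th percentiles (quantile
type 7, linear interpolation) and clipped to [0, 1]. Pooling across all
arms and days is deliberate: it is what makes scores comparable between
conditions, the property every between-arm comparison relies on. A
degenerate constant channel maps to 0.5 with a warning rather than
failing.

The per-cell **exhaustion score** is the arithmetic mean of the seven
normalized exhaustion markers; the **memory score** is the mean of the four
memory markers. Both lie in [0, 1] exactly, are invariant to marker order,
and are monotone in every panel marker.

Where the upstream experiment left choices unstated, the package fixes
them as documented assumptions: scores are computed on the arcsinh scale,
normalization is pooled (not per-donor), and stratified subsampling (the
"2,000 sampled cells" style analysis set) allocates proportionally over
(arm, day) strata with largest-remainder rounding under a fixed seed.

## Trajectory map and regions

Cells are embedded in normalized-marker space (all non-gating channels by
default). The temporal graph connects each cell to its `k_within = 15`
nearest same-day neighbours and `k_between = 5` nearest neighbours in each
adjacent day — the "grey edges" that stitch timepoints into trajectories.
Distance ties break by ascending cell index so construction is
order-stable. The 2-D layout is Fruchterman–Reingold with a seeded
circular initialization; *exact coordinates are not a contract* (they vary
legitimately across algorithms), only geometric properties are: separated
populations stay separated (tested by silhouette), disconnected components
are laid out per component and placed on a grid at 4x the largest
component span, and coordinates are centered at the origin.

Terminal-day regions are detected by k-means with `R = 4` centers on the
same features — a reproducible surrogate for the manual region drawing a
human analyst would do on the layout; this is an explicit design decision,
not an inference about how the original regions were delineated. Cells
are canonically ordered by `cell_id` before clustering, which makes
membership invariant to input row order. Regions are relabeled in
descending mean exhaustion score, so Region 1 is always the most
exhausted and the CD39-high sub-population lands there, while Region 4
is the IL7R/CD45RA-high memory pole. Composition tables report the
percentage of each arm's terminal cells per region (rows sum to 100);
score summaries report Q1/median/Q3 (type-7 quantiles, recorded in output
metadata) and the mean — the quantities a violin-with-quartiles plot
shows.

## Score kinetics

Score-versus-day curves are fit by a tricube-weighted local polynomial
regression (degree 1 by default, span 0.75), evaluated on a grid spanning
the day range. The implementation evaluates the local fit only at grid
points, which makes the case-resampling bootstrap affordable; on shared
inputs it agrees with `stats::loess` (direct surface) to machine
precision, and the test suite keeps that cross-check. The 95% band is the
2.5/97.5 percentile envelope of `n_boot = 500` bootstrap refits, clipped
outward to contain the point estimate (a pure percentile band can narrowly
exclude it at finite `n_boot`). At the window boundary the farthest points
carry zero tricube weight; if the positive-weight points span too few
distinct days for the polynomial, the fit falls back to the local weighted
mean, which is the correct boundary estimate. A span too small to cover
any polynomial window is an error suggesting a minimum.

The qualitative claim "scores increase with time" is quantified by a
permutation test on the least-squares slope of score on day: day labels
are permuted (`n_perm = 999`),
`p = (1 + #{|slope_perm| >= |slope_obs|}) / (n_perm + 1)`. The test is
exactly calibrated by construction; the suite checks its type-I error
empirically and its power on the default drift (exhaustion program rising
0.3 over days 1–11 with 2,000 scored cells). The "2,000 sampled cells"
count is applied per arm; the pipeline exposes it as
`score.n_subsample_per_arm`.

## Transcriptome reversal

Counts are normalized to `log2(CPM + 1)`. Signature kinetics z-score each
gene across all samples (constant genes guard to zero with a warning),
average over the up- or down-signature set per sample, then summarize per
(arm, day) as mean ± SEM across donors. The full signature lists are
study inputs; the eight canonical genes named in the literature (PDCD1,
ENTPD1, BATF, NR4A1 up; IL7R, LEF1, KLF2, BACH2 down) ship as a demo set,
and the synthetic generator extends them to 50 + 50 by default.

Terminal-day PCA uses the singular value decomposition of the
gene-centered matrix. The PC1 sign is fixed so the ALWAYS_ON centroid is
positive — signs are arbitrary in any decomposition, and pinning one makes
downstream indices stable. Genes are ranked by |PC1 loading|; the top 500
are clustered hierarchically with average linkage on 1 − Pearson
correlation distance (all recorded in output metadata).

The **reprogramming index** summarizes reversal on PC1:
`clamp01((d(R, ON) − d(R, OFF)) / d(ON, OFF))` over arm centroids — 1 when
rested samples sit at the always-off centroid (complete reversal), 0 at or
beyond always-on. Under a no-effect null its clamped distribution is
symmetric around 1/2 by geometry, which the suite verifies.

## Repertoire controls

Diversity metrics are richness, Shannon entropy (nats), inverse Simpson
and Pielou evenness (`H / ln richness`, reported as `NA` for a single
clone where it is 0/0). Shannon and inverse Simpson are computed through
`vegan`; rarefaction is Monte-Carlo (without-replacement subsamples at a
common depth, averaged over `n_boot` draws) and is validated against the
hypergeometric closed form (`vegan::rarefy`). Because no single index was
specified upstream, all four are reported and comparisons default to
Shannon. The two-arm comparison bootstraps clones within samples
(multinomial at observed depth), forms a percentile CI for the difference
of arm means, and flags "similar" only when the whole CI fits inside a
user-supplied equivalence margin — the margin has no default because
"similar diversity" is a claim the analyst must quantify. The pipeline
disables rarefaction when samples are within 2-fold depth of one another
(logged).

## The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions.

**Cytometry.** Each cell carries latent program weights `e` (exhaustion)
and `m` (memory) in [0, 1]. On pre-terminal days these are Beta-drawn
around arm-specific day means with concentration `kappa = 6` — broad,
heterogeneous populations. On each arm's terminal day, cells commit to one
of four sub-mode attractors (concentration `terminal_kappa = 80`): two
exhausted (sub-mode 1 CD39-high, the most exhausted) and two memory
(sub-mode 4 IL7R/CD45RA-high, the most memory-like), with arm-specific
mixing (90/10 toward the program-matched pair). This
broad-then-committed structure mirrors progressive fate commitment and is
what makes terminal-day regions phenotypically distinct. Marker intensity
for cell i, channel j is zero with probability `dropout = 0.1`, else
lognormal with log-mean `baseline_j + load_e_j e_i + load_m_j m_i` and
log-SD `sigma = 0.3`. Score markers carry loading 8 (natural-log units per
unit program — negative-to-bright over the CyTOF dynamic range) and seven
context markers carry loading 5, encoding the programs redundantly as
real panels do. The lognormal/zero-inflation choice is a stand-in: the
marginal intensity distribution of the real instrument is not known here,
so conclusions from passing tests transfer to real data only insofar as
arcsinh intensities are roughly linear in the underlying programs.
Default arms: ALWAYS_ON (exhaustion program rising 0.35 to ~0.66 over days
1, 7, 9, 11) and RESTED_D7_11 (tracks to day 7, then reverses while memory
rises to ~0.66).

**Bulk counts.** `mu_g(arm, day) = baseline_g 2^(beta_g p(arm, day))` with
`p` the arm's program level; `beta = +1` for 50 up-signature genes, `-1`
for 50 down genes, 0 for 1,900 background genes; NB size 40 (~16%
biological CV, tight in vitro replicates); library factors uniform on
[0.5, 1.5]. The rested arm's program returns to 0 at day 15 — complete
transcriptomic reversal to baseline, which is the modeled endpoint.

**Clonotypes.** Clone probabilities proportional to `rank^-alpha`
(`alpha = 1`, 1,000 clones, depth 50,000 per arm), multinomial counts,
identical probability vectors across arms so true diversity is matched;
a clonal-outgrowth alternative is one argument away
(`n_clones = c(1000, 10)`).

Every simulator is bit-reproducible under a fixed seed.

## Numerical and design choices

- Quantile rule: type 7 everywhere, recorded in outputs.
- kNN ties: ascending cell index; layout: seeded circular init, 500
  iterations.
- k-means: 10 restarts, canonical cell order, relabeled by mean
  exhaustion.
- Bootstrap bands: percentile, clipped to contain the estimate.
- Master seed: per-stage seeds derive by a stable polynomial byte-hash of
  (seed, stage name), documented so ports can match streams; all derived
  seeds stay below 2^31.
- Strict config: unknown YAML keys are errors; range violations aggregate
  into one report.
- FCS support is a minimal FCS 3.0 float reader/writer (list mode); cell
  metadata travels in a sample sheet since FCS stores channels only.

## Problem sizes used by the checks

The test suite and acceptance script run the default conditions at 5,000
cells per arm and day for score recovery and region detection, 2,000
cells for trend power (200 replicates), 1,000 null replicates for test
calibration, 200 replicates of 200-bootstrap bands for coverage, 100
simulated bulk studies for the PC1 reversal rate, and 200 replicate
repertoire comparisons. These sizes were chosen so each property is
estimated with sampling error well below its acceptance margin.

## Known limitations

- The generator's marginal intensity model (lognormal with constant-rate
  zero inflation) is a stand-in; real CyTOF zero inflation is
  abundance-dependent.
- No bead normalization, debarcoding, doublet removal, spillover
  compensation, or automated gating; inputs are assumed pre-cleaned.
- Kinetics pool cells across donors by default; no mixed-effects donor
  modeling, and no between-curve comparison test.
- Region detection by k-means is a surrogate for manual gating of layout
  regions; with non-convex regions the correspondence can degrade.
- No differential-expression testing and no V(D)J clonotype calling from
  reads; expression matrices and clonotype tables are consumed
  pre-computed.

## A minimal run

```{r}
library(tcellrest)

sim <- simulate_cytometry(sim_config(n_cells_per_arm_day = 2000, seed = 1))
events <- arcsinh_transform(sim$events, cofactor = 5)
events <- gate_events(events, default_gate_rules())
scored <- compute_scores(normalize_markers(events))

kin <- score_kinetics(scored, seed = 1)
graph <- layout_graph(build_temporal_knn(scored), seed = 1)
regions <- detect_regions(scored, R = 4, seed = 1)
region_composition(regions)

# or end to end from one config:
run_pipeline(demo_config("demo_out", seed = 1))
```
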