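# migrquant

Quantitative analysis of confined amoeboid migration of leukemic B cells,
and of the polarity of their endocytic-vesicle signal.

Leukemic B cells (CLL and MCL lines, primary cells) crawl under agarose in
an amoeboid fashion. Nucleus-stain movies are tracked and summarized per
trajectory; membrane-stain stills of single cells are scored for how
dispersed their punctate vesicle signal is. A recurring pitfall motivates
the package: non-motile cells with strong protrusive activity rattle their
nucleus in place, which inflates track length D and median speed while the
cell goes nowhere. Metrics that integrate the path (D, speed) therefore
disagree with metrics that measure range (maximum distance, MSD) exactly
where the biology is most interesting, and the confinement ratio collapses
for oscillators. `migrquant` implements the full metric panel so the
dissociation is measurable rather than a confound.

## What it computes

**Per-track migration statistics**, for tracks of positions p_0..p_T
(micrometers, frame interval Δt):

- total distance traveled `D = Σ_t |p_t − p_{t−1}|` and net displacement
  `d = |p_T − p_0|`;
- confinement ratio `CR = d / D` (1 = straight, →0 = confined), its decay
  curve `CR(t) = |p_t − p_0| / Σ_{k≤t} |p_k − p_{k−1}|`, whose final value
  is the track's CR;
- maximum distance traveled `max_{i<j} |p_i − p_j|` (all-pairs; a
  from-origin mode is also provided);
- median instantaneous speed;
- time-averaged MSD with overlapping intervals,
  `MSD(nΔt) = mean_i |p_{i+n} − p_i|²`, and the Fürth
  persistent-random-walk fit `MSD(t) = 4D_c (t − P(1 − e^{−t/P}))`.

**Replicate-aware statistics** in the SuperPlot convention: statistical
testing uses only the median value of each biological replicate (one-way
ANOVA plus Tukey–Kramer post hoc), never pooled per-cell values. Transwell
counts are normalized as percent of input and as the migration index
`MI(c) = count(c) / count(reference)`, so the unstimulated reference has
MI = 1.

**Tracking**: a self-contained Laplacian-of-Gaussian spot detector with
sub-pixel refinement, optimal frame-to-frame assignment, and gap closing,
with the published parameter set as defaults (object diameter 10 µm,
quality threshold 0.2, linking max distance 10 µm, gap closing 15 µm over
at most 2 frames), plus the complete-track filter (only trajectories
present at all 60 timepoints are analyzed).

**Vesicle dispersion**, two scoring procedures that both end in the
per-cell median of all mutual locus distances: the cell is segmented
(contrast stretch, Gaussian blur σ = 2, Huang fuzzy threshold, largest
component), then either (a) the mask is tiled into 3×3-px squares
(0.238 µm² at 0.1626 µm/px), squares whose median intensity reaches twice
the per-cell minimum square median count as vesicle-positive and their
centroids are the loci; or (b) loci are local maxima with prominence
above 200 intensity counts.

**Synthetic data** with ground truth for every stage: an exactly
discretized Ornstein–Uhlenbeck persistent random walk (its ensemble MSD is
the Fürth curve with no time-step bias), an anchored anti-persistent
oscillator, ballistic fixtures, nucleus-movie rendering, and single-cell
vesicle scenes with polarized (uropod-cap) or dispersed puncta.

## Worked example

```r
library(migrquant)
# migratory vs oscillatory cells, 3 replicates of 30 tracks each
values <- do.call(rbind, lapply(1:3, function(r) {
  rbind(
    data.frame(condition = "migratory", replicate = paste0("rep", r),
               value = metrics_table(simulate_track_set(30, "prw", seed = r))$max_distance),
    data.frame(condition = "oscillatory", replicate = paste0("rep", r),
               value = metrics_table(simulate_track_set(30, "oscillatory", seed = r + 100))$max_distance))
}))
superplot_summary(values)
#> <superplot_summary>
#>     condition mean_of_medians sd_of_medians n_replicates
#> 1   migratory       29.101101     2.2438882            3
#> 2 oscillatory        5.272472     0.0165928            3
#> one-way ANOVA on replicate medians: F(1,4) = 338.3, p = 5.141e-05
#> Tukey post hoc:
#>              comparison      diff        p_adj
#> 1 oscillatory-migratory -23.82863 5.862454e-05
```

Migratory cells range ~29 µm from any point of their track to another;
oscillatory cells stay within ~5 µm although their total path length is
similar — the dissociation described above. The ANOVA runs on the three
replicate medians per condition (n = 3 each), not on the 90 cells.

Movies go through the same interface:

```r
truth <- simulate_movie_scene(n_cells = 20, seed = 1)
movie <- render_movie(truth, render_params(), seed = 1)
ts <- track_movie(movie$stack)           # LoG detection + linking + gaps
ts <- filter_complete(ts, 60)            # keep 60/60 trajectories
metrics_table(ts)
```

and single-cell vesicle crops through `segment_cell()`,
`grid_dispersion_score()`, `maxima_dispersion_score()` or `batch_score()`;
`run_migration_analysis()` / `run_vesicle_analysis()` orchestrate whole
condition × replicate layouts from a YAML config (a thin CLI wrapper lives
in `inst/scripts/migrquant-cli.R`).

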