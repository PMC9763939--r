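---
title: "Quantifying confined amoeboid migration and vesicle polarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying confined amoeboid migration and vesicle polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrquant)
```

# The analysis problem

Leukemic B cells migrating under mechanical confinement are imaged as
nucleus-stain movies (60 frames, one frame per 10 s, so the last frame
falls at t = 590 s) and summarized per trajectory. Two families of
statistics behave very differently on the same data:

* path-integrating statistics — total distance traveled
  $D=\sum_t \lVert p_t-p_{t-1}\rVert$ and median step speed — accumulate
  every nuclear movement, including the rapid jitter of anchored cells
  with high protrusive activity;
* range statistics — the maximum distance between any two timepoints and
  the mean square displacement — only grow when the cell actually leaves
  its spot.

An anchored, protrusively active ("oscillatory") cell therefore shows a
large $D$ and speed but a tiny range, and its confinement ratio
$CR = d/D$ (net displacement over path length) collapses toward 0. The
package computes the whole panel so this dissociation can be measured,
and its synthetic-data module generates both phenotypes with known
parameters so every claim about the metrics is testable.

# Per-track metrics

All metrics operate on time-ordered positions in micrometers. Tracks need
at least two spots; metric computation refuses shorter tracks rather than
returning a default. For a perfectly stationary track $D=0$ and the
confinement ratio is undefined: it is carried as `NA`, flagged in
`metrics_table()` (`cr_defined`), and excluded from aggregation — 0/0 has
no defensible value and forcing 1 (or 0) would bias condition means.

The CR decay curve evaluates $d(t)/D(t)$ per timepoint; timepoints with
$D(t)=0$ are likewise `NA`. Its final value equals the scalar CR, which
the tests assert as an identity.

MSD uses overlapping intervals,
$\mathrm{MSD}(n\Delta t)=\operatorname{mean}_i \lVert p_{i+n}-p_i\rVert^2$,
for all lags $1..T-1$, matching the spreadsheet-macro convention used for
such data. Estimates at the longest lags average very few intervals;
tables carry the full range, while `curves_table(..., max_lag_fraction)`
lets population plots cap the lag range (plots conventionally stop at a
fraction of the track duration; the default table keeps everything).

`max_distance_traveled()` defaults to the all-pairs definition — the
maximal distance between any two timepoints. Some tracking tools' feature
of the same name measures distance from the starting point instead; both
modes are exposed (`mode = "from_origin"`) because exported feature
tables rarely say which convention produced them. The all-pairs mode is
the default because it is the stated definition of the quantity in the
protocol this package follows; for any track
$d \le \max_{i<j}\lVert p_i-p_j\rVert \le D$, which the suite checks as
an invariant.

# Replicate-aware statistics

Per-cell distributions are heavily pseudo-replicated (hundreds of cells
per dish), so all hypothesis testing runs on one number per biological
replicate: the replicate median. Condition summaries are the mean and
sample SD (n − 1 denominator; small replicate counts make the sample SD
the standard choice) of those medians. Testing is classical one-way
fixed-effects ANOVA followed by Tukey's studentized-range post hoc in the
Tukey–Kramer form, which supports the unequal replicate counts (n = 4
and n = 5) that occur in practice. Both are delegated to base R
(`aov`, `TukeyHSD`); the test suite validates them against a
from-first-principles sum-of-squares and `ptukey` computation, and checks
the $F=t^2$ identity at two groups. Beyond Tukey no further
multiple-testing correction is applied, matching the reporting convention
of the field. A degenerate design in which every group is the same
constant yields $F=0,\ p=1$ rather than 0/0.

Median convention everywhere: the midpoint average for even-length
vectors (R's default).

Transwell normalization: percent of input is
$100 \cdot \mathrm{migrated}/\mathrm{input}$ with the input well
representing complete transmigration; the migration index divides each
condition's count by the unstimulated reference, so the reference is 1
by construction. A reference count of 0 (lines that barely transmigrate)
makes MI undefined for the whole table; the result is flagged
`not_computable` instead of producing infinities.

# Tracking

The detector computes the scale-normalized negated Laplacian of Gaussian
at $\sigma = \mathrm{diameter}/(2\sqrt2)$ (in pixels), takes 3×3-strict
local maxima, and refines positions by a per-axis quadratic fit (offsets
clamped to ±0.5 px). Quality is the response scaled to the brightest
maximum of the stack: the upstream tool's 0.2 threshold is unitless and
tool-internal, so a relative quality is the reproducible counterpart; the
0.2 default carries over. Pixel centers sit at $(i-0.5)\cdot$pixel size,
and renderer and detector share this convention (verified by sub-pixel
recovery tests).

Frame-to-frame linking solves the assignment problem exactly (an $O(n^3)$
shortest-augmenting-path solver, validated against exhaustive permutation
search) on squared distances, with links forbidden beyond the linking
radius; the cost construction prefers linking whenever a link is
admissible. Gap closing joins tracklet ends to later starts greedily by
ascending distance when the frame difference is 2..max gap and the
distance is within the gap-closing radius; adjacent-frame joins are the
linker's job. This is a simplification of the full two-pass LAP tracker,
adequate at the cell densities considered here and validated end to end:
the suite requires ≥ 95% complete-track recovery at sub-half-pixel error
on the default 20-cell movie. Bridged frames stay absent by default, so
gap-closed tracks fail the 60/60 complete-track filter unless
`interpolate = TRUE` fills them linearly — whether the original analyses
interpolated is not recorded, so the stricter behavior is the default.
No drift-correction stage exists: synthetic movies are drift-free, and
stage-stabilization of real movies is treated as upstream preprocessing.

# Vesicle dispersion scoring

Segmentation works on a working copy: linear contrast stretch saturating
0.35% of pixels (the common display-stretch default; configurable),
Gaussian blur σ = 2 px, Huang fuzzy thresholding, largest connected
component. Scoring always reads the raw intensities. Masks touching the
image border are flagged and excluded by `batch_score()`, as are crops
that fail to segment; exclusions stay in the output with a reason.

The Huang threshold minimizes the Shannon entropy of fuzzy memberships
$u(g) = 1/(1+|g-\mu_{\mathrm{side}}|/C)$ over all cuts with two non-empty
sides, exhaustively; ties go to the lower level. On a two-level histogram
every cut between the levels is equivalent, so the reported threshold is
the lowest such cut and foreground is strictly above it.

The grid method tiles the mask's bounding box into `square_px` squares
(default 3 px; at the default 0.1626 µm/px a square covers 0.238 µm²).
The positivity threshold is twice the minimum square median *within that
cell* — a per-cell adaptive rule that tolerates cell-to-cell brightness
differences. Two conventions of the original (unpublished) subdivision
script are surfaced as configuration:

* *inclusion*: which squares belong to the cell. The default keeps
  squares lying entirely inside the mask. A center-pixel rule is also
  available, but with it, boundary squares straddling the cell edge have
  background-dominated medians; the per-cell minimum then collapses to
  background level and twice-the-minimum falls below the diffuse
  cytoplasmic signal, marking essentially the whole cell positive — the
  score degenerates to a cell-size measure. Full inclusion keeps the
  minimum anchored to the dimmest *cellular* region, which is the premise
  of the 2× rule.
* *centroid*: a square's locus is its geometric center converted to
  micrometers.

The maxima method takes local maxima inside the mask with prominence —
height above the highest saddle toward any higher maximum — exceeding a
cutoff (default 200 counts, defined on the 16-bit scale of the
acquisitions the default was tuned on; 8-bit data needs a proportionally
smaller cutoff). Prominence is computed by descending-level union–find
(a persistence computation); the highest peak of a region is referenced
to the region's minimum; summit plateaus yield one locus at their
centroid. An exhaustive saddle-search oracle validates the implementation
on small images.

Both methods end identically: the per-cell score is the median of all
pairwise distances between loci, in micrometers; fewer than 2 loci give
status `too_few_loci` and no score.

# What the synthetic data emulates — and what it does not

The migratory phenotype is a persistent random walk: per-axis
Ornstein–Uhlenbeck velocity with correlation time $P$ (default 60 s) and
stationary speed scale set by `mean_speed` (default 0.1 µm/s; the
per-axis velocity SD is $\mathrm{mean\_speed}/\sqrt{\pi/2}$, the 2-D
Rayleigh relation). Velocity and its position integral are discretized
*exactly* (jointly Gaussian update with the closed-form covariance), so
the ensemble MSD is the Fürth curve at every lag with no time-step bias —
this is what makes the persistence-recovery test sharp. `speed_sd`
(default 0) adds between-cell speed heterogeneity when wanted; the
default keeps the ensemble homogeneous so closed forms hold exactly.

The oscillatory phenotype is an anti-persistent AR(1) around a fixed
anchor with stationary per-axis SD `anchor_sd_a` (default 1 µm); its lag-1
coefficient is chosen so the mean per-frame step equals `step_scale`
(default 2 µm/frame), which at the defaults makes the process
anti-correlated ($\phi \approx -0.27$) — a nucleus rattling in place.
Monte-Carlo under these defaults puts the 99% quantile of the maximal
mutual distance below 7.5× the stationary SD; the suite asserts that
verified bound. With 60 frames the oscillator's median path length
exceeds five times its median range while the walker's ratio sits near 2
— the quantitative form of the dissociation, asserted at a fixed seed
with 200 tracks per arm. That bound is tight for the walker: the
population value of the ratio under the default parameters lies just
below 2, so individual 200-track draws scatter around it.

Movie rendering draws each nucleus as a 2-D Gaussian (default σ = 4 px at
0.65 µm/px, amplitude 1000 over a 200-count background, noise SD 100 —
peak SNR 10) on a 512-px field; `simulate_movie_scene()` redraws tracks
until all cells stay in-field and mutually separated at every frame, so
the default scene is resolvable by design. Vesicle scenes render an
elliptical cell (6 µm major semi-axis, axis ratio 0.75) of diffuse
intensity 250 over a 150-count background with Gaussian puncta
(amplitude 800, σ = 1.3 px) placed uniformly over the cytoplasm or over a
polar cap holding 20% of the cell area. The background default is
deliberately high relative to the diffuse signal: shallow widefield
contrast is the regime in which per-cell adaptive thresholds are needed
at all, and with background above half the cytoplasmic level the 2×
minimum rule lands between diffuse signal and puncta wherever the
minimum comes from. The cell boundary renders sharply (sub-pixel
softening only), emulating a filled stain plateau; the 3×3 medians are
then robust to the mask over- or undershooting the true edge by a pixel.

Not emulated: stage drift and illumination gradients, cell collisions and
contact, shape dynamics (cells are discs/ellipses), membrane-rim
brightness structure, photobleaching, and any mechanistic response to
confinement or inhibitors. Passing tests therefore demonstrate
correctness of the measurement pipeline on data satisfying its geometric
assumptions, not robustness to every real-world artifact — real movies
additionally need the upstream stabilization and quality control steps.

# Numerical choices and problem sizes

Exact identities (round trips, oracle equivalences, rigid-motion
invariance) are asserted at 1e-9..1e-12; stochastic properties use fixed
seeds and tolerances derived from the check itself (5% for the
random-walk MSD mean over 1000 tracks, 20% for persistence recovery from
a 1000-track ensemble, 15% for maxima-vs-truth scores on well-separated
puncta). The test suite runs movies of 20 cells × 60 frames (512 px) in
the acceptance checks and smaller scenes (3–6 cells, 10–30 frames,
128–224 px) in module tests; dispersion discrimination uses 50 polarized
and 50 dispersed cells organized as 5 replicates per arm. These sizes
keep the whole suite in the minutes range on one CPU while leaving the
statistical checks well-powered.

# Known limitations

* The linker is single-particle per frame with no splitting/merging; cell
  divisions or touching nuclei will produce identity errors.
* Gap-closed tracks without interpolation cannot pass the complete-track
  filter; analyses that interpolated upstream should enable
  `interpolate = TRUE` to match.
* The grid score's translation invariance is only up to one grid
  quantization step (square size × pixel size), and segmentation may flip
  single threshold-grazing mask pixels between otherwise identical
  crops.
* Prominence defaults assume 16-bit intensities; 8-bit inputs need the
  cutoff rescaled.
* All analysis is 2-D; z-drift appears as intensity/size change, not as
  displacement.
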