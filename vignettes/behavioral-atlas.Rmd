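---
title: "Methods: behavioral classification of T cell tracks in organoid co-culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral classification of T cell tracks in organoid co-culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotrack)
```

This vignette documents the models, parameters and numerical choices
behind the package, in the order the pipeline runs them. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The data model

The pipeline consumes long-format tables exported by tracking software:
one row per tracked object per frame. T cell rows carry position (µm),
speed (µm min⁻¹), square displacement (µm², relative to the track
origin), dead-cell dye intensity, distance to the nearest organoid and
distance to the nearest other T cell. Organoid rows carry position,
area, volume and mean dead-cell dye intensity. Time is always minutes;
two imaging cadences are typical, 2-min frames (few wells, high temporal
resolution) and 30-min frames (dozens of wells in parallel). Frames need
not start at zero but must sit on one uniform grid per well; violations
are integrity errors, never silently repaired.

Vendor-specific "one statistic per file" exports are supported through a
configurable alias table (`imaris_alias_table()`) because export column
names vary between installations; the canonical on-disk format is a
single long CSV with fixed names so downstream steps are decoupled from
any vendor layout.

## Preprocessing

Tracks lose frames to segmentation dropouts. Interior gaps (between a
cell's first and last observation) are filled by linear interpolation of
the *numeric* source channels — including the distance channels that are
later binarized — never of binary channels directly, and never by
extrapolation at the track ends. Binarization then applies three
thresholds:

* organoid contact: `dist_organoid <= 5` µm (surface-to-surface);
* T cell interaction: `dist_tcell <= 10` µm (center-to-center);
* death: dye intensity `>= 20` a.u., after which the channel is held at
  1 — death is biologically absorbing, and the dye is noisy enough that
  a single crossing is the more robust event definition.

All three are configuration with documented defaults: in real data these
thresholds are determined visually per imaging setup, so none of them is
a measured constant. A two-threshold marker gate
(`gate_marker(low, high)`) supports prelabelling experiments where only
confidently negative/positive cells should be called; values between the
gates are `indeterminate`.

Tracks are cut to a fixed window of `window_h = 3.3` hours —
`L = floor(window_h * 60 / dt) + 1` frames (100 at 2-min cadence, 7 at
30-min) — anchored at the track start. Anchoring at the start is
deterministic and captures early behavior; tracks shorter than `L` are
discarded and counted rather than padded, since padding would fabricate
behavior.

## The atlas: DTW, embedding, clustering, naming

Similarity between two equal-length multivariate series is the
*dependent* (joint-channel) dynamic-time-warping distance: the local
cost between frame vectors is their Euclidean distance, and dynamic
programming minimizes the cumulative cost over all monotone warping
paths on the full L×L grid, with no warping band. Dependent DTW is the
standard multivariate reading when a single cross-distance matrix is
wanted; warping whole frame vectors keeps the channels synchronized
within a cell.

Channel scaling matters because the local cost is a plain Euclidean
norm. Numeric channels are z-normalized globally (one mean/sd per
channel across all series); binary channels stay 0/1 so a contact
mismatch costs about one unit, commensurate with a ~1-sd speed
difference. Square displacement is additionally log1p-transformed before
normalization: displacement magnitudes are heavy-tailed across cells
(fast scanners disperse super-diffusively, reaching 10⁴–10⁵ µm² while
static cells stay near 10 µm²), and without variance stabilization this
single channel dominates the joint cost and stretches fast-moving
archetypes into elongated manifolds. The transform is a package design
choice, exposed as `log_channels`.

The DTW kernel is implemented in C++ (row-major packed frames, O(L²)
per pair) because the reference build computes ~1.5×10⁵ pairwise
alignments; the 540-series atlas takes seconds rather than minutes. DTW
is not a metric — the triangle inequality can fail — so the test suite
asserts exact agreement with an exhaustive warping-path enumeration on
short series instead of metric axioms.

The cross-distance matrix is embedded in 2-D with UMAP
(`n_neighbors = 30`, `min_dist = 0.1`, fixed seed; classical MDS is
available as a deterministic alternative) and k-means is run on the
embedding coordinates. `k = "auto"` selects k over 4..14 by maximal mean
silhouette width on the embedding; `k = 9` reproduces the reference
atlas size directly. Series farther than `mean + 3·sd` from their
centroid (within-cluster distances) are flagged as outliers but keep
their nearest-centroid label, so composition percentages still sum
to 100.

Cluster naming works on the *relative* feature summary: per cluster and
channel, the mean over member series of the track-mean value, min-max
rescaled across clusters to [0, 1]. Rules apply in order: `CD ≥ 0.8` →
dying; `OC ≥ 0.8 ∧ Dis ≤ 0.3` → super engager; `OC ≥ 0.5` → engager;
`OC ≥ 0.15` → tickler; remaining clusters are ranked by speed into
static → lazy → slow/medium/super scanner (overflow clusters become
`scanner-N`). The tickler gate sits at 0.15 rather than a rounder 0.2
because a tickler touching organoids ~15% of frames lands at relative
OC ≈ 0.19 when super engagers (~80% contact) anchor the scale; a gate
above that value would misname the canonical archetype.

## Classification of new experiments

Each track reduces to descriptive statistics: mean, median, 90th
percentile (linear-interpolation quantile, the standard reading of "top
90% of the distribution") and standard deviation for speed and square
displacement; mean, mean-of-cumulative-sum and max-of-cumulative-sum for
the binary channels (contact and death by default). The cumulative
summaries distinguish *how long* a state was occupied and *when* —
prolonged early contact scores differently from the same total contact
late. T cell interaction features are optional (`include_interaction`)
and excluded by default so that experiments at a lower
effector-to-target ratio, where encounter frequency shifts for purely
compositional reasons, remain classifiable by the same model.

The random forest uses 100 trees and a stratified 95/5 split —
stratification guarantees all nine signatures in training, which a plain
random split does not at class sizes near 20. Held-out accuracy and the
per-signature confusion matrix are stored on the model. Composition
statistics use Pearson's chi-squared without continuity correction on
the condition × signature count table, Welch's t on replicate-level
(per-well) percentages for two-condition contrasts, and Pearson
correlation for relating signature sizes to per-condition scalars.
Mixed-effects variants are out of scope by design; per-well percentages
are the replicate unit.

## Killing kinetics and engagement correlation

Dead-cell dye is min-max rescaled to 0–100 within each experiment to
remove between-experiment intensity variation. An organoid is *dying*
from the first frame its rescaled dye reaches `die_thresh = 50` — the
midpoint of the normalized range; no measured threshold exists, so the
value is configuration and the curve function accepts any threshold (an
`cumulative = FALSE` variant reports per-frame fractions instead).
Killing curves are cumulative and therefore monotone; control correction
is pointwise `max(0, treatment − control)` with the control interpolated
onto the treatment grid — clamping encodes that a control response
larger than treatment means "no attributable killing", not negative
killing. Initial-size dependence compares first-frame areas of organoids
killed vs alive at 10 h with a two-sided Wilcoxon rank-sum test plus
Cohen's d.

For engagement coupling, every labelled T cell frame is assigned to its
nearest organoid within a contact radius; per-organoid, per-signature
contact counts accumulate over time. The sliding-window Pearson
correlation uses a *trailing* 3-h window ending at each frame — trailing
windows only use information available at their timestamp — between the
window's cumulative contacts and its dye *increase* (first difference of
rescaled dye, floored at 0 to suppress bleaching noise). Windows where
either variable is constant yield `NA`, excluded from the per-time-point
mean across organoids.

## Probability mapping over pseudotime

Imaging and transcriptomics are bridged by engagement states
(no-target control, nonengaged-enriched, nonengaged, engaged, super
engaged). From imaging, `estimate_signature_priors()` gives p(B|E) —
empirical signature frequencies per state, optionally per CD4/CD8
subset. For sequenced cells, each clustering run gives empirical p(E|U)
per cluster, and the transitivity product
`p(B|U) = Σ_E p(B|E) p(E|U)` assigns every cell a signature
distribution; vectors are averaged over runs (seven runs at different
resolutions is the convention the cell-state simulator reproduces).
Row-stochasticity is preserved exactly through the product, and the test
suite asserts sums of 1 within 1e-9 and agreement with an independent
matrix-product recomputation within 1e-12. Cells from no-organoid
control wells are assigned a dedicated "no-target control"
pseudo-signature deterministically. Quantile capping of extreme
probabilities (`cap_quantile`) is off by default — it is a display
refinement, and leaving it off keeps the mapping exact; when enabled it
caps per-signature values at the given quantile and renormalizes.

The in-silico engagement-state rules (contact fraction ≥ 0.75 over the
final 2 h → super engaged; contact at harvest or ≥ 30 cumulative
minutes → engaged; any shorter contact → nonengaged; none →
nonengaged-enriched) are explicit configuration: the experimental sort
has no published numeric definition, so these defaults are stated
guesses, not reconstructions.

Stage partitioning bins pseudotime (50 bins), computes each bin's
dominant merged signature group (control / merged nonengaged signatures,
which share a probability map / tickler+engager / super engager),
smooths dominance with a centered 3-bin majority vote, and maps groups
to the four targeting stages (baseline, environmental stimuli, short
engagement, prolonged engagement). If dominance regresses after
smoothing the first crossings are used and a warning is raised. Gene
dynamics are smoothed with cubic smoothing splines over
pseudotime-ordered cells on a 100-point grid, z-scored, and k-means
clustered into `k_patterns = 8` groups; zero-variance genes are labelled
`flat` outside k-means rather than distorting a cluster.

## The synthetic co-culture

The generator defines the conditions under which the pipeline is
validated. Each archetype is parameterized by speed (truncated
Gaussian), a target square-displacement scale (converted to the
persistence of a 2-D persistent random walk via
`MSD ≈ n (v dt)² (1+ρ)/(1−ρ)`), a stationary organoid-contact fraction
with a mean bout length (two-state Markov chain, started in its
stationary distribution), a T cell interaction rate (also bout-like:
encounters at 1:25–1:30 effector-to-target ratios are sparse, discrete
events), and a per-hour death rate driving an absorbing death state and
a sigmoidal dye rise. The super engager's contact fraction is 0.8 —
exactly 48 contact-minutes per hour, the defining measurement of that
signature — with 40-min bouts and low displacement; the engager steps
down to 0.5 with 15-min bouts; the tickler to 0.15 with 4-min bouts; the
scanner family spans speeds 0.25–9 µm min⁻¹ at zero contact. Within-
archetype speed noise (~0.1–0.6 µm min⁻¹) is sized as realistic
measurement-plus-biological variability; it also determines how compact
each archetype is in DTW space, and the library satisfies the
separability requirement (between-archetype median DTW distance exceeds
within-archetype spread), which the test suite asserts.

Organoid killing uses a per-frame hazard `baseline + Σ multiplier ×
contacts`, with multipliers ordered super engager ≫ engager ≫ tickler
(0.02 / 0.005 / 0.001 per contacting cell per frame). After death the
dye rises sigmoidally with a 2-h midpoint and 40-min scale: organoid
cells die progressively, so killed organoids are still in their rising
phase during a 3-4-h observation — which is what couples cumulative
contact to dye increase in the sliding-window correlation. Cells are
placed on the +x axis of their assigned organoid at exactly their
emitted organoid distance, so nearest-organoid assignment recovers the
generator's contact channel; organoid centers are spaced 600 µm apart,
far beyond any contact radius.

The cell-state simulator draws engagement states from an explicit pool
composition (balanced by default), assigns per-run clusters by Bayes
inversion of each run's p(state|cluster) matrix, and returns the
analytic per-cell probability vector alongside, so the mapping can be
checked against a closed form. Cluster matrices lean towards a "home"
state by default, as real expression clusters do; fully uninformative
matrices are available with `informative = FALSE`.

What the generator does *not* emulate: 3-D migration mechanics and
morphology, track identity switches and drift, organoid growth/merging,
dye bleaching trends, batch effects, or any transcriptomic counts
(pseudotime and cluster assignments are consumed as given). Passing
tests therefore demonstrate correctness of the computations under known
dynamics, not robustness to every artifact of real microscopy data.

## Problem sizes, determinism, limitations

The reference validation uses 60 tracks per archetype (540 series of
length 100), where the full DTW + UMAP + k-means build runs in well
under a minute; classifier checks reuse that scale, probability-mapping
checks use up to a few thousand cells, and null-calibration of the
size-dependence test uses 1000 simulated experiments of 40 organoids.
All randomness flows through explicit integer seeds: generators,
embedding, k-means and forests are bit-reproducible given the same seed
on the same platform.

Known limitations: silhouette-based selection of k is near-marginal
between 8 and 10 on nine-archetype data — tight behavioral continua
(engager vs super engager) and UMAP's stochastic layout can tip the
optimum by one for some generator seeds, which is why `k = 9` exists as
an explicit override; DTW distances are not metric and the embedding is
a visualization-grade, not isometry-grade, representation; the
engagement-state rules and all binarization thresholds are conventions
that must be recalibrated per imaging setup; and group-level inference
uses replicate-level simple tests rather than mixed models.
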