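# cotrack

Behavioral classification of engineered T cell tracks in tumor-organoid
co-cultures.

Engineered T cells (CAR, TCR-transduced, or metabolome-sensing γδTCR
products) attack patient-derived organoids (PDOs) in very different ways:
some cells never touch a target, some scan past many organoids, and a
small subpopulation engages one organoid for most of an hour and kills
its cells serially. Time-lapse 3-D imaging with single-cell tracking
captures this heterogeneity, but turns it into large per-cell-per-frame
tables that need quantitative structure. `cotrack` provides that
structure for the tracking exports themselves — segmentation and
tracking happen upstream in the imaging software.

## What it computes

Given per-cell time series of speed, square displacement, distance to
the nearest organoid, distance to the nearest other T cell and dead-cell
dye intensity, the package:

1. **Builds a behavioral atlas.** Tracks are gap-interpolated, cut to a
   common 3.3-h window, and binarized into five channels per frame
   (speed *Sp*, square displacement *Dis*, organoid contact *OC*, T cell
   interaction *TI*, cell death *CD*). Pairwise similarity is the
   dependent multivariate dynamic-time-warping (DTW) distance

   `D(a, b) = min over monotone warping paths π of Σ_(i,j)∈π ‖a_i − b_j‖₂`

   computed over z-normalized channels. The cross-distance matrix is
   embedded in 2-D (UMAP), k-means-clustered with silhouette-based
   selection of k and outlier flagging, and clusters are named by a
   deterministic rule set into the nine canonical signatures: dying,
   static, lazy, slow/medium/super scanner, tickler, engager, super
   engager.
2. **Classifies new experiments.** Each track is reduced to descriptive
   statistics (mean, median, 90th percentile, s.d. of numeric channels;
   mean and cumulative-sum summaries of binary channels) and classified
   into the atlas signatures with a 100-tree random forest (stratified
   95/5 split).
3. **Quantifies killing.** Per-organoid dead-cell dye is rescaled 0–100
   per experiment; the cumulative percentage of dying organoids over
   time is computed, control-corrected, and related to initial organoid
   size.
4. **Couples killing to behavior.** Cumulative per-signature organoid
   contacts are correlated with the increase in dead-cell dye through a
   3-h sliding-window Pearson correlation, per organoid and averaged.
5. **Maps signatures onto transcriptomes.** For sequenced cells with
   engagement-state labels and repeated cluster assignments, the
   per-cell signature distribution follows by probability transitivity,
   `p(B|U) = Σ_E p(B|E) · p(E|U)`, averaged over clustering runs;
   pseudotime is partitioned into targeting stages and gene dynamics are
   smoothed and pattern-clustered.
6. **Simulates co-cultures.** A seeded generator produces
   archetype-structured tracks (two-state contact-bout chains,
   persistent random walks, absorbing death), organoid dye trajectories
   whose death hazard is coupled to engager contact, and cell-state
   tables with known analytic probabilities — ground truth for every
   stage above.

## Worked example

```r
library(cotrack)

# reference build: nine archetypes, 60 tracks each, 2-min frames
mix <- setNames(rep(60L, 9), signature_levels())
sim <- simulate_tcell_tracks(mix, dt = 2, duration_h = 3.4, seed = 42)
ref <- run_reference_build(sim$tracks, dt = 2, k = "auto", seed = 42)
ref$atlas
#> <behavior_atlas>
#>   series:    540
#>   clusters:  9
#>   outliers:  2
#>   signatures: lazy, dying, medium scanner, slow scanner, super scanner,
#>               tickler, engager, static, super engager
generics::glance(ref$classifier)$heldout_accuracy
#> [1] 1
```

Silhouette selection over k ∈ 4..14 recovers the nine simulated
behaviors, and the random forest separates them perfectly on the held-out
5%. Applying the model to a fresh co-culture with organoids:

```r
mix2 <- c("super engager" = 20, tickler = 20, lazy = 20)
new  <- simulate_tcell_tracks(mix2, dt = 2, duration_h = 3.4, seed = 7)
labs <- dplyr::rename(new$truth, signature = archetype)
kill <- simulate_organoid_killing(60, new$tracks, labs, killing_model(),
                                  seed = 8)
pred <- run_prediction(ref, kill$tracks, organoids = kill$organoids,
                       condition = "high-killing PDO", dt = 2)
pred$composition
#>   condition        signature         n   pct
#> 1 high-killing PDO dying             2  3.33
#> 2 high-killing PDO lazy             20 33.3
#> 3 high-killing PDO super engager    19 31.7
#> 4 high-killing PDO tickler          19 31.7
pred$correlation
#>   signature       mean_r
#> 1 dying           0.219
#> 2 lazy          NaN
#> 3 super engager   0.235
#> 4 tickler         0.0157
tail(pred$kinetics$pct_dying, 1)
#> [1] 25
```

The composition recovers the simulated mix (one super engager and one
tickler stray into neighboring signatures). The sliding-window
correlation separates the engagement hierarchy: organoids contacted by
super engagers couple to dye increase (mean r ≈ 0.24), tickler contact
barely does (≈ 0.02), and lazy cells never touch an organoid so their
correlation is undefined. A quarter of the organoids cross the dying
threshold within the 3.4-h observation.

`autoplot()` methods exist for the atlas, compositions, killing curves,
correlation traces and gene-dynamics patterns; `tidy()`/`glance()`
return tibbles for all fitted objects.

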