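# bodybubbles

Tools for asking *which body parts carry the information observers use to
recognize bodily expressions of emotion*, and *how body parts and emotions
are coded in body-selective cortex* — the two arms of a Bubbles
reverse-correlation + representational-similarity (RSA) study, implemented
as a reusable, tested R pipeline.  A synthetic-data module generates body
images with labeled parts, simulated observers, and covariance-structured
voxel patterns, so the whole pipeline runs at desk scale with no external
data.

Who it is for: visual psychophysicists running (or simulating) Bubbles
experiments, and neuroimaging researchers comparing candidate
representational geometries against ROI voxel patterns.

## The methods in brief

**Bubbles arm.**  Stimuli are decomposed into five one-octave
spatial-frequency bands (cut-offs 22.4 … 0.7 c/deg for a 245-px, 5.47°
image) and revealed through random Gaussian apertures whose size yields 3
cycles per bubble (σ = 0.13 … 2.14°).  A per-expression multiplicative
staircase holds accuracy at 75%.  Classification images are pixelwise
proportions p(x) = correct(x) / (correct(x) + error(x)) per band,
variance-stabilized, smoothed (σ = 8 px) and z-scored, and tested with a
cluster-extent test (z > 2.7, α = 0.05) whose max-extent null is simulated
from the map's exactly-known smoothness.  Diagnostic proportions summarize
significant pixels per band and per body part.

**RSA arm.**  True RDMs are 1 − r (Pearson) between the voxel patterns of
the 12 conditions (3 expressions × 4 body parts).  Seven candidate models
(categorical body/emotion models, two ranked "pattern2" models,
rank-normalized to [0, 1], and a seeded random model) are compared by
Kendall's τ_A (no tie correction), with one-sided exact signed-rank
relatedness tests, two-sided pairwise signed-rank tests, and
Benjamini–Hochberg FDR at q = 0.05 / 0.01.  Classical MDS, single-linkage
dendrograms and the Sørensen–Dice overlap R = 2·V∩/(V1+V2) round out the
toolkit.  Behavioral indices include Wagner's unbiased hit rate
H_u = n(s,s)² / (row total × column total) and a two-way repeated-measures
ANOVA with Greenhouse–Geisser correction.

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults and numerical choices.

## Worked example

Simulate a Bubbles experiment and recover the planted diagnostic region:

```r
library(bodybubbles)

bodies   <- make_body_set(n_actors = 4, seed = 1)   # 12 bodies, 3 expressions
observer <- make_observer(bodies)                   # template matcher
session  <- run_session(bodies, observer, n_trials = 1920,
                        spec = band_spec(),
                        state = density_state(attr(bodies, "expressions")),
                        seed = 303)
session
#> Bubbles session: 1920 trials, 12 bodies, 5 bands
#> overall accuracy 0.748; final densities: anger=82, fear=67, neutral=74

ci <- classification_image(session,
                           subset = session$log$expression != "neutral")
round(diagnostic_proportion_by_part(ci$clusters, bodies[[1]]$part_masks), 3)
#>            head torso_with_arms            legs
#>           0.000           0.237           0.000
round(diagnostic_proportion_by_band(ci$clusters), 4)
#>  band1  band2  band3  band4  band5
#> 0.0000 0.0356 0.0000 0.0000 0.0000
```

The staircase has settled near the 75% criterion (final densities are
total bubble counts per expression), and the cluster test localizes the
diagnostic information to the torso-with-arms (23.7% of its pixels
significant, other parts 0) in the spatial-frequency band where the
emotion-specific texture was planted (3.6% of band-2 pixels).  The
significance mask overlaps the planted region at Dice 0.88:

```r
pooled <- Reduce(`|`, ci$clusters$sig)
dice_overlap(pooled, bodies[[1]]$diagnostic_mask)$r_overlap
#> [1] 0.8844139
```

For the RSA arm, simulate patterns under a known generating model and
compare all seven candidates:

```r
spec <- pattern_spec("emotion_pattern2", n_subjects = 20, n_voxels = 200,
                     noise_sd = 1, seed = 11)
rdms <- lapply(pattern_matrices(simulate_patterns(spec)), true_rdm)
rsa_compare(rdms, candidate_rdms(), q = 0.05)
#> RSA model comparison (20 subjects, 7 models, signed-rank test)
#>             model mean_tau        p q0.05
#>  emotion_pattern2    0.553 4.77e-05  TRUE
#>     body_pattern2    0.482 9.54e-07  TRUE
#>     body_pattern1    0.392 4.78e-05  TRUE
#>     body_separate    0.257 4.74e-05  TRUE
#>  emotion_pattern1    0.073 4.74e-05  TRUE
#>            random    0.038 1.36e-03  TRUE
#>  emotion_separate   -0.054 1.00e+00 FALSE
```

The generating model attains the highest mean τ_A and beats every other
model in the pairwise signed-rank comparisons at q(FDR) = 0.05.

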