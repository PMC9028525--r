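---
title: "Models and methods: Bubbles classification images and RSA model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: Bubbles classification images and RSA model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodybubbles)
```

This package implements two linked analyses of how observers and
body-selective visual cortex decode bodily expressions of emotion: a
**Bubbles reverse-correlation arm** that identifies which body parts and
spatial-frequency (SF) bands drive correct emotion categorization, and a
**representational-similarity arm** that compares candidate models of how
body parts and emotions are coded in ROI voxel patterns.  Because the
original stimulus set and the human behavioral/fMRI recordings are not
redistributable, a synthetic-data module generates every input the two
arms need, at desk scale, from code.

# The Bubbles arm

## Stimuli and spatial-frequency bands

Stimuli are grayscale body images (310 x 245 px, 6.90 x 5.47 degrees of
visual angle, background gray 128).  Each image is decomposed into five
non-overlapping one-octave SF bands.  The top cut-off is the horizontal
Nyquist frequency, `245 / 2 = 122.5` cycles/image; each further cut-off
halves it, giving 122.5, 61.25, 30.6, 15.3, 7.7 and 3.8 cycles/image
(22.4, 11.2, 5.6, 2.8, 1.4, 0.7 cycles/degree when divided by the 5.47
degree width).  `band_spec()` holds this table; printed values round to
one decimal.

The decomposition (`decompose_sf()`) peels layers recursively: at every
scale the current image is split by a radial low-pass filter into a
coarser remainder and the band-pass difference.  The filter family is a
raised cosine in log2 frequency with its half-amplitude point at the
band cut-off and a one-octave transition.  Two properties are
guaranteed by construction and verified by tests: the band planes plus
the final low-pass residual sum back to the input exactly (telescoping
identity), and a pure sinusoid lands almost entirely (>= 85% of
spectral energy) in its nominal band.  Any filter family with these two
properties would serve; the raised cosine keeps the bands close to
non-overlapping while remaining smooth enough to avoid ringing.

## Bubbles masks

Each band is sampled by `sample_mask()` with unit-peak Gaussian
apertures ("bubbles") at uniform random positions over the whole plane.
The bubble standard deviation is set per band so a bubble reveals 3
cycles of the band's upper cut-off: 0.13, 0.27, 0.54, 1.07, 2.14
degrees (6, 12, 24, 48, 96 px) from fine to coarse.  Overlapping
bubbles are combined by a clipped sum (values capped at 1), the usual
Bubbles convention.  A session's total bubble count is split across
bands in proportion to `1 / sigma^2`, i.e. equal *expected revealed
area* per band.  Equal per-band counts would saturate the coarse bands
(a handful of 96-px bubbles already covers the image, making the mask
identically 1), which both flattens the observer's psychometric
function and degenerates the coarse-band statistics; area-proportional
allocation is the standard remedy and is what the per-scale adjustment
of bubble numbers is for.

## The simulated observer and the density staircase

The synthetic bodies are geometric silhouettes (ellipse head, trapezoid
torso with arm bars, two leg bars) rather than realistic figures -- the
pipeline only consumes images, part masks and a planted diagnostic
region.  Emotional expressions carry an expression-specific sinusoidal
texture (distinct orientations, frequency in the second-finest band)
inside a fixed torso sub-region, the *diagnostic region*; the neutral
expression carries a diffuse texture over the whole silhouette.  Actors
share geometry and differ in base gray and texture amplitude.

The observer (`make_observer()`, `observer_respond()`) is a template
matcher: it correlates the revealed stimulus with one template per
expression (the mean diagnostic-region content of that expression) over
the template's support, adds independent Gaussian *internal noise* to
each correlation, and picks the argmax; with probability `guess_rate`
it guesses uniformly.  The template-matching decision rule is a
modeling choice -- nothing in the underlying task constrains
participants' internal decision process -- but it yields the two
properties the pipeline needs: accuracy rises monotonically with
revealed diagnostic area, and errors concentrate on trials where the
diagnostic region stayed hidden.

Parameters with units and defaults:

* `internal_noise_sd` (correlation units, default 0.25): sets where the
  psychometric function saturates.  At 0.25 the observer is
  *information-limited*: its errors are driven by what the mask hides,
  which is the regime a reverse-correlation analysis presupposes.  With
  much larger noise (e.g. 0.5) errors become mostly internal and the
  classification image contrast washes out; the staircase analyses
  below work at either value.
* `guess_rate` (probability, default 0.05): occasional lapses.
* staircase `eta` (default 0.1), `target` (0.75), bounds `[1, 500]`
  bubbles: after every trial the tracked expression's total count is
  multiplied by `1 + eta * (target - correct)`.  The state is kept
  continuous and rounded only when sampling, so small counts are not
  trapped by rounding.  The multiplicative rule equilibrates where
  `p log(1 - 0.25 eta) + (1 - p) log(1 + 0.75 eta) = 0`, i.e. p of
  about 0.74 for eta 0.1 -- just below the 75% target, well inside the
  +/- 3 percentage-point acceptance band used in the tests.

`run_session()` presents the bodies equally often in shuffled order and
logs every trial's mask (as bubble centers; planes are rebuilt
deterministically), response and density.

## Classification images and cluster inference

Following the standard reverse-correlation recipe, the masks of correct
and error trials are summed per band and pixel (`accumulate()`) and the
proportion image `correct / (correct + error)` computed pixelwise
(`proportion_image()`), with never-sampled pixels marked undefined.
The proportion images are smoothed with a Gaussian kernel (sigma 8 px)
and z-standardized (`smooth_z()`), and contiguous supra-threshold
regions (z > 2.7, 8-connectivity) are tested for extent at
cluster-level alpha 0.05 (`cluster_test()`).

Three numerical choices deserve explanation:

* **Standardization reference.**  `smooth_z()` defaults to the plane's
  own mean and standard deviation.  The pipeline functions
  (`classification_image()`, `shuffle_null()`) instead use a
  variance-stabilized reference: each pixel is first standardized by
  its *exact* standard error under the label-shuffling null, computable
  in closed form from the accumulated mask weights (the correct-mask
  sum is a random `m`-of-`n` subset of known per-pixel weights).
  Bubble coverage is strongly non-uniform -- image borders receive half
  the bubble mass, and coarse bands are sampled by very few, very large
  bubbles -- so the raw proportion field is heteroscedastic, and a
  plane-wide z-transform lets high-variance border and coarse-band
  pixels masquerade as signal (in calibration runs one band's
  false-alarm rate reached 0.30).  After variance stabilization the
  shuffled-label family-wise false-alarm rate sits at the nominal 0.05
  across all bands.
* **Smoothness.**  The cluster-extent null depends on the map's
  smoothness.  A proportion image built from Gaussian bubbles of
  standard deviation `sigma_band`, then smoothed with `sigma_smooth`,
  has the autocorrelation of white noise filtered with
  `sqrt(sigma_band^2 + sigma_smooth^2)`; `effective_fwhm()` converts
  that to the per-band FWHM the pipeline passes to `cluster_test()`.
  Passing only the applied kernel's FWHM (the bare default) understates
  the coarse bands' smoothness by an order of magnitude.
* **Cluster p-values.**  The classical closed-form random-field
  approximation (`rft_cluster_p()`: expected Euler characteristic count
  of clusters, exponential extent distribution) is available, but at
  the moderate threshold used here (z > 2.7, FWHM about 19 px) it is
  measurably conservative: on 1000 simulated stationary fields its
  family-wise error is about 0.03 at nominal 0.05, because the
  Euler-characteristic count undercounts clusters at moderate
  thresholds.  `cluster_test()` therefore defaults to a Monte-Carlo
  max-cluster-extent null (`mc_cluster_null()`): stationary Gaussian
  fields with the map's *known* smoothness are simulated once (cached,
  internally seeded, hence deterministic) and each observed cluster
  receives the family-wise-exact p-value
  `(1 + #{null max extents >= k}) / (n + 1)`.  This is the package's
  analogue of nonparametric cluster inference; it is possible here
  precisely because the smoothness is known exactly rather than
  estimated from residuals.

Diagnostic proportions then summarize significance: per band, the
significant-pixel count over the band's pixel count; per body part, the
band-pooled (union) significant pixels inside the part over the part's
pixel count, which keeps the proportion in [0, 1].  The whole image
plane is the denominator for bands, matching a whole-plane search
region.

## Behavioral indices

`unbiased_hit_rate()` implements Wagner's H_u: squared hits over the
product of the stimulus row total and response column total -- the hit
rate multiplied by the precision of the response category, which
removes response-bias inflation (H_u equals raw accuracy only for a
bias-free diagonal confusion table).  `rm_anova_gg()` is a classic
univariate two-way repeated-measures ANOVA: effect sums of squares
against their subject-interaction error terms, Greenhouse-Geisser
epsilon computed from the sample covariance of the condition scores via
orthonormal effect contrasts, corrected p-values and partial eta
squared, plus Bonferroni-adjusted pairwise contrasts;
`simple_effects()` follows the interaction with per-level one-way
RM-ANOVAs.  The implementation is checked against `car::Anova`'s
multivariate-model route and against by-hand sums-of-squares on small
examples.  One caveat: a GG-corrected p-value is *smaller* than the
uncorrected one when F < 1 (shrinking both dfs), so "corrected p >=
uncorrected p" holds only for F > 1.

# The RSA arm

For each subject and ROI the *true RDM* is 1 minus the Pearson
correlation between the voxel patterns of each pair of the 12
conditions (3 expressions x 4 body parts); group RDMs average subjects
entrywise.  Seven *candidate models* (`candidate_rdms()`) formalize
hypotheses about that geometry: four categorical models
(`body_separate`, `body_pattern1`, `emotion_separate`,
`emotion_pattern1`, entries 0/1), two ranked models (`body_pattern2`
with part-pair tiers 1/2/3, and `emotion_pattern2`, which refines the
whole-body/torso-with-arms block with emotion-graded ranks 0-5 -- same
emotion < anger-fear < emotion-neutral, crossed with body-type
mismatch -- then rank 6 for torso-arms/legs and ranks 7-8 for the
remaining two tiers), and a seeded uniform `random` model.  Rank models
are normalized to [0, 1].  The exact cellwise layout of the
emotion-graded block is a documented default (the source hypotheses fix
the tiers, not every cell); it is deliberately kept in one function so
a different reading can be swapped in.

Model fit is Kendall's tau_a (`kendall_tau_a()`): concordant minus
discordant pairs over *all* `n(n-1)/2` pairs, with no tie correction --
the appropriate choice when candidate models predict tied ranks,
because it penalizes a model for predicting a tie where the data order
is real.  A consequence worth knowing: against a model with tied
entries, tau_a cannot reach 1; its ceiling is the model's untied-pair
fraction (about 0.79 for `emotion_pattern2`), and the convergence tests
are written against that ceiling.

Inference (`rsa_compare()`): per model, a one-sided exact Wilcoxon
signed-rank test of the subject tau_a values against zero
(`relatedness_test()`); per model pair, a two-sided signed-rank test on
the paired differences (`pairwise_model_test()`); both families
controlled by Benjamini-Hochberg FDR at q = 0.05 (and 0.01), with the
family being the 7 models (or 21 pairs) within one ROI.  A t-test
option exists because both test descriptions appear in the source
literature for this design; the signed-rank default follows the variant
attached to the actual result figures.  Exact null distributions are
used wherever feasible: the standard signed-rank distribution for
untied samples, complete sign-flip enumeration for tied samples up to
n = 16, and a tie-corrected normal approximation beyond.

`mds_2d()` (classical Torgerson scaling, sign-fixed axes) and
`rdm_dendrogram()` (single linkage, i.e. nearest neighbor) provide the
customary visual summaries, and `dice_overlap()` implements the
Sorensen-Dice coefficient `2 V_overlap / (V1 + V2)` for comparing
binary activation maps (defined as 0 when both maps are empty).

## Simulated voxel patterns

`simulate_patterns()` realizes a chosen generating model: the target
correlation matrix is `C = 1 - signal_scale * R` (an affine, monotone
map of the model's normalized ranks -- the models specify rank order,
not magnitudes), condition mean patterns are built as an orthonormal
zero-mean Gaussian voxel basis times a symmetric square root of C, so
the *sample* correlations equal C exactly, and independent Gaussian
noise is added per subject.  With `noise_sd = 0` every subject's
empirical RDM is exactly `signal_scale * R`; with noise, correlations
shrink monotonically, preserving rank order in expectation.  A
non-positive-semi-definite target (notably the unstructured `random`
model at any useful contrast) raises an error advising a lower
`signal_scale`; all six structured models are PSD at any contrast in
(0, 1].  Defaults (20 subjects, 200 voxels, `signal_scale` 0.6,
`noise_sd` 1 -- voxelwise SNR 1) describe a moderately noisy experiment
under which the generating model is reliably recovered by the full
inference chain.

# What the synthetic data do and do not show

The generator reproduces the *structure* the pipeline consumes: labeled
part masks, a planted diagnostic region, an observer whose accuracy
tracks revealed information, and voxel patterns with a known
correlation geometry.  It does not emulate photorealistic bodies,
reaction times, fMRI time series, scanner noise spectra, or
between-subject variability in the diagnostic region's location.
Passing tests therefore demonstrate that the estimators and tests
recover known ground truth under their stated assumptions -- not that
real bodies carry their diagnostic information in the torso, which only
the original kind of data could show.

# Problem sizes used by the test suite

The unit tests run the full arithmetic at the published geometry and
the stochastic checks at reduced scale chosen for tight Monte-Carlo
error at desk runtimes: 120 x 96 px bodies with 4 bands for session
mechanics; 2000- and 1920-trial closed-loop sessions at the full
310 x 245 / 5-band geometry for the staircase and recovery checks; 200
label shuffles x 5 bands and 1000 independent smooth-noise fields
(internal nulls of 1000-4000 fields) for calibration; 20 subjects x
200 voxels for model recovery; and exhaustive enumeration oracles up to
n = 12 for the rank statistics.

# Known limitations

* The Monte-Carlo cluster null assumes the variance-stabilized map is
  well approximated by a stationary Gaussian field of the stated
  smoothness; very low trial counts (tens of trials) leave the
  proportion field visibly non-Gaussian and the calibration degrades.
* The staircase equilibrium sits slightly below the target (a property
  of single-trial multiplicative rules); controllers targeting the
  running mean would center the target exactly but are not implemented.
* tau_a ceilings under tied models mean relatedness magnitudes are not
  comparable across models with different tie structure; the pairwise
  signed-rank comparisons are the meaningful contrast.
* The RM-ANOVA assumes a balanced complete design; missing cells are
  rejected rather than imputed.
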