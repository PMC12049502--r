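---
title: "Detecting cognitive-map signatures of action-outcome knowledge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cognitive-map signatures of action-outcome knowledge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actmap)
```

# The scientific problem

When people learn which motor actions produce which outcomes, they may store
more than a look-up table of individual associations: they may organise the
associations into a low-dimensional relational structure — a cognitive map —
in which similar action-outcome pairs lie close together. `actmap`
implements a complete analysis chain for detecting the signatures of such a
map in behaviour and in task fMRI:

1. a **design** module generating balanced trial sequences that sample
   directions and distances in a 2-D abstract action-outcome space;
2. a **behaviour** module reconstructing the mental map from pairwise
   similarity ratings;
3. a **GLM** module for first-level event-related models;
4. an **RSA** module testing hexadirectional (grid-code-like) pattern
   similarity;
5. an **adaptation** module estimating distance- and action-overlap-based
   modulation of the BOLD response;
6. a **gPPI** module estimating condition-dependent inter-region coupling;
7. a **stats** module for sign-flip permutation group inference; and
8. a **synthetic-participant** module that generates data with exactly the
   statistical structure each downstream analysis assumes, so the whole
   chain is testable end to end without any participant data.

# The action-outcome space and the task designs

The space is a 5 x 5 grid: five joystick-1 actions map to five probabilities
of catching a launched ball (0.1, 0.3, 0.5, 0.7, 0.9) and five joystick-2
actions map to five probabilities that the ball stays visible. Adjacent
probability ranks are one distance unit apart. A pair of action combinations
defines a displacement vector — a direction and a distance — in this space.

`sample_assignment()` draws the participant-specific action-to-rank
mappings under the constraint that no action maps to the same rank on both
dimensions. The reference protocol states this constraint only by example;
we formalise it as "never the identical rank on both dimensions" and keep
it configurable (`constraint` argument). Six landmark positions (marked by
coloured balls) are fixed across participants; the colour-to-position map is
a per-participant permutation. The exact landmark coordinates and the eight
positions probed in the rating task are left open by the protocol; the defaults in
`default_landmarks()` and `default_rating_positions()` are reconstructions
chosen to cover all quadrants and the centre, and are configurable.

## Direction sampling

Twelve direction bins at nominal 30-degree spacing are sampled, each 12
times per session from 12 distinct starting positions. Cardinal bins use
axis-aligned vectors of 4, 3 and 2 units; non-cardinal bins use the integer
grid vectors of length sqrt(20), sqrt(13) and sqrt(5) within +-4 degrees of
the nominal angle. This fixes the realised mean angles at 0, 28.35, 61.65,
90, ... degrees and the non-cardinal angular deviations at 3.43 or 3.69
degrees — properties the test suite asserts exactly.

```{r}
design <- generate_task1_session(seed = 1)
direction_statistics(design)
```

Three sequencing constraints are solved per run by randomised constructive
search with a retry budget: (i) each bin appears once per run half, never in
adjacent trials; (ii) at most three consecutive trials share an alignment
class (aligned = nominal angle a multiple of 60 degrees); (iii) the four
class transitions occur 5-6 times per run, with the deficit type rotated
across runs, so session totals deviate from exact balance by at most 2.
The class sequence is built from block compositions (runs of 1-3 identical
classes), which makes the transition counts exact by construction.

Two stated design facts cannot be honoured simultaneously because they are
mutually inconsistent: a cardinal-bin mean distance of 2.8
units has no integer frequency solution over 12 samples. We implement the
stated "one fewer short distance" rule at the session level — per cardinal
bin, five runs carry (short, longer) and one run carries both longer
lengths, giving counts (3, 4, 5) for (4, 3, 2) units and a mean of 2.83 —
and expose the realised frequencies in `direction_statistics()`.

Probe types are balanced as four groups (two question types; true and false
statements) with three per alignment class per run; false statements are
sub-labelled one-false/both-false at random. Timings follow the scanner
protocol: 3 s stimuli separated by 1.5 s gaps, a 4.5 s reflection period and
a 4 s response window (1.5 s stimuli in the landmark task), TR = 1.5 s, and
a default 2 s inter-trial interval (the protocol leaves the interval open;
configurable via `iti`).

# Behavioural map reconstruction

Ratings are normalised to [0, 1] over the rater's observed range and
averaged across the two repetitions of each pair
(`normalize_average()`), reverse-coded to dissimilarities, and correlated
(Spearman) with the true Euclidean distances. The reference analysis reports
this correlation as positive for well-formed maps; reverse coding makes
that the sign convention here, documented in
`rating_distance_correlation()`.

`mds_embed()` minimises metric stress by SMACOF majorisation from random
initial configurations (default 8 restarts, convergence tolerance 1e-9 on
the stress change). No installed package minimises metric stress from a
random start, so the majorisation loop is implemented here and validated
against exact planar configurations (stress < 1e-6, perfect Procrustes
recovery).

`procrustes_distance()` is the normalised SSE after the optimal
translation + scaling + rotation (reflections allowed by default,
configurable), the scale-free goodness-of-fit used with planar maps; the
test suite cross-checks it against `vegan::procrustes(symmetric = TRUE)`
and a direct least-squares optimisation. `critical_distance()` enumerates
all n! item-to-position assignments (40320 for 8 items, 720 for 6),
computes the Procrustes distance of the embedding to each, and thresholds
the null at its 5th percentile. The enumeration is vectorised through a
closed form for 2-column configurations — the sum of singular values of the
2 x 2 cross-product matrix is sqrt(||M||_F^2 + 2|det M|) — so the full
8-item null costs four matrix-vector products. The identity assignment is a
member of the null, which makes the test exact: a pure-noise rater passes
at the nominal 5% rate, a property the acceptance suite verifies over 500
simulated raters.

# First-level GLMs

`build_design()` assembles HRF-convolved boxcar regressors per condition,
parametric-modulator columns (values demeaned within the run before
convolution — never across runs), an orthonormal cosine drift set below the
0.01 Hz high-pass cutoff, unconvolved confound columns and an intercept.
The canonical HRF is the standard double-gamma (gamma shapes 6 and 16,
undershoot ratio 1/6; unit-impulse integral 5/6, peak near 5 s); the
reference analysis specifies a canonical HRF and nothing more, so no
derivatives are included. Estimation is plain OLS per voxel (`fit_glm()`); the original
toolbox default may have prewhitened, but the simulated AR(1) noise is mild
and the estimator is unbiased either way, so prewhitening is left out of
scope. Events are modelled at a microtime resolution of TR/8.

`design_for_layout()` reproduces the reference task layouts structurally:
the RSA layout models the reflection phase with 12 direction regressors
plus 4 no-interest conditions; the adaptation layouts model 4 no-interest
conditions plus demeaned parametric modulators at the second stimulus; the
landmark-task layout splits both stimuli by colour (6 + 6 conditions) so
colour-specific offsets cannot masquerade as distance effects. The
reference regressor totals (62/51/61) include a fixed 46-regressor nuisance
set from a specific preprocessing pipeline; confound estimation is out of
scope here, so the task regressors are exact and the nuisance set is
whatever the caller supplies (the simulator emits six motion-proxy
confounds plus drift).

# Hexadirectional RSA

`condition_patterns()` averages the 12 direction betas across runs and
z-scores each voxel across conditions (the reference analysis fixes only
that a z-score normalisation is applied; the axis is configurable).
`neural_rdm()` computes squared Mahalanobis distances whitened by a
shrinkage covariance of the GLM residuals (Schafer-Strimmer diagonal-target
shrinkage with data-driven intensity, written here because no such
estimator is installed), normalised per voxel; the crossnobis variant
cross-validates pattern differences across runs, making the estimator
unbiased — its null mean is zero, which the acceptance suite verifies by
simulation.

Periodicity models are binary: entry 0 where the angular difference between
nominal direction angles is a multiple of 360/k. The reference control
analyses describe a per-direction remainder-class construction; for the
6-fold model at 30-degree sampling the two constructions coincide, and the
pairwise form is used for all k for symmetry. Two consequences are worth
stating plainly. First, at 30-degree sampling the k = 5 model is constant
off the diagonal (no pairwise difference is a multiple of 72 degrees), so
it cannot be tested and `rdm_correlation()` refuses it. Second, the k = 2
and k = 3 models are *nested* in the 6-fold structure (180 and 120 degrees
are themselves multiples of 60), so under genuinely hexadirectional data
their expected model correlation is positive, not zero; they are therefore
not valid specificity controls under a strong grid signal, and the
acceptance suite tests specificity with the k = 4 model and the
position-occupancy models (whose expected correlation is non-positive
there) plus exact size calibration of *all* models under a no-grid
simulation. Position models correlate 25-cell start/end occupancy vectors
between directions and return 1 - r as model dissimilarity.

# Adaptation and gPPI

`distance_analysis()`, `overlap_analysis()` and `joint_analysis()` return
voxel- and run-averaged parametric betas per participant. Group inference
is one-sided for distance (a positive beta — response increasing with
distance — is adaptation for near pairs) and two-sided for action overlap
(no directional hypothesis; in the simulator, a positive overlap gain
yields a positive beta, i.e. enhancement with similarity).
`subsample_equalize()` implements the reference control for unbalanced
trial classes: drop trials of the larger class uniformly per run, refit,
iterate 10 times, average — with optional exclusion of the rare
fully-reversed pairs first. One-dimensional control distances are absolute
rank differences on a single outcome dimension.

`fit_gppi()` builds the five-regressor interaction model: two convolved
condition indicators (long vs short distance), the seed time series, and
their two products. No deconvolution is applied before forming the
products; at TR = 1.5 s the product-of-convolved approximation is standard
for this model family, and that limitation is inherited knowingly. The
long/short split assigns the shortest distance class (2 and sqrt(5) units)
to "short" — the reference analysis states no threshold; a median split is
available by flag. `symmetric_gppi()` averages the two directed contrasts,
as the reference analysis does, because PPI carries no directional
information.

# Group statistics

`signflip_ttest()` compares the observed one-sample t statistic against
10000 random sign-flips by default, includes the observed statistic in the
p-value (never returns 0), and reports Cohen's d and the 95% t-interval.
The permutation p converges to the analytic t-test p for Gaussian data and
is exact-level for symmetric nulls; both properties are verified in the
acceptance suite. `bonferroni()` applies the multiplicity correction used
for the ROI analyses.

# The synthetic-participant simulator

`region_model()` describes a voxel population with a shared grid
orientation and uniform random voxel phases: voxel v responds to direction
theta with `b_v + a6 cos(k(theta - phi) + psi_v)` plus pattern noise. This
is the minimal population model that yields k-fold periodic pattern
similarity; it is a simulator construct, not a claim about entorhinal
biophysics. Second-stimulus amplitudes follow
`base (1 + gamma_d (d - dbar)/dbar + gamma_a o)`. Presets mirror the
regional dissociations under study: "ec" (grid amplitude only), "hpc"
(distance gain only), "sma" (overlap gain only), "control" (all zero).
`simulate_run()` assembles HRF-convolved event amplitudes, low-frequency
drift, the emitted confound time courses and AR(1) noise; every simulator
is a pure function of its parameters and seed, and the confounds injected
into the data are exactly those written to the confounds table, so a GLM
containing them fits a zero-noise run exactly (asserted in the tests).
`simulate_coupled_rois()` adds `delta * seed x long-indicator` to the
target region, the structure the gPPI model estimates.

What the simulator does *not* emulate: vascular and physiological noise
spectra, spatial autocorrelation and smoothing, head motion beyond abstract
confound courses, multi-session drift, and anatomical geometry. Passing
tests therefore demonstrate the correctness and calibration of the
analysis chain under its own assumptions, not performance on real scanner
data.

# Problem sizes and numerical choices

The test suite runs its calibration studies at deliberately chosen sizes:
RSA power and size at 100 replicate experiments (46 simulated participants,
200 voxels, 6 runs for power; 20 participants for size), adaptation and
gPPI null calibration at 120 replicate experiments of 12-16
participants with noise redrawn over fixed designs (test size does not
depend on the number of participants), power at the reference sample size of 46, the
behavioural null at 500 raters, and the overlap/space design correlation at
250 (tests) or 1000 (acceptance script) participants. Sign-flip tests
inside these loops use 1000 flips; the default for analysis remains 10000.

Numerical details: MDS restarts default to 8 with tolerance 1e-9 and are
seeded; degenerate (zero-variance) dissimilarities embed with a warning
flag; Procrustes on fewer than 3 points or degenerate configurations is an
error; the permutation null enumeration is guarded at 9 items; rank
deficiency in any design matrix is an error naming the collinear columns;
the joint adaptation model refuses modulators with |r| > 0.95; sign-flip
tests refuse zero-variance inputs. Ties in Spearman correlations use
average ranks throughout.

# Known limitations

The residual correlation between action overlap and 2-D space similarity
across constrained assignments reproduces at ~0.074-0.08 under this
package's reconstruction of the design (the reference analysis reports
0.091 with a matching between-participant spread); the exact randomisation
bookkeeping behind the reference value — in particular the integer
distance frequencies for cardinal directions — is not printed, and no
integer solution reproduces its stated mean exactly. The landmark and
rating positions are reconstructions. Whole-brain searchlights, anatomical
ROI definitions, preprocessing and confound estimation are out of scope;
analyses operate on simulated regions or imported voxel x time matrices.
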