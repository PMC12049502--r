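# actmap

Cognitive-map signatures of action-outcome knowledge: an end-to-end R
analysis chain for behavioural and fMRI experiments in which participants
learn to associate motor actions with outcome probabilities arranged in a
two-dimensional abstract "action-outcome space".

## The problem and the methods

When five joystick-1 actions map to five probabilities of catching a
launched ball and five joystick-2 actions to five probabilities of the ball
staying visible, every action combination is a point on a 5 x 5 grid, and a
pair of combinations defines a direction and a distance in that grid. If
the brain organises this knowledge as a map, several signatures follow,
each implemented here as a module:

- **Design generation** — balanced scanner task sequences sampling 12
  directions (30-degree spacing) 12 times each from distinct starting
  positions, with alignment-class run-length and transition balance,
  distance balancing, and probe-type balance (`generate_task1_session()`,
  `generate_task2_session()`, `generate_rating_set()`).
- **Behavioural map reconstruction** — pairwise similarity ratings are
  normalised, averaged, embedded by metric-stress MDS, and fit to the true
  configuration by Procrustes analysis; significance comes from the
  exhaustive null over all n! item-to-position assignments, thresholded at
  its 5th percentile (`behavior_pipeline()`, `critical_distance()`).
- **Hexadirectional RSA** — 12 direction-evoked patterns, (cross-validated)
  Mahalanobis distances with shrinkage noise covariance, and Spearman
  correlation with a 6-fold periodicity model against k-fold and
  position-occupancy controls (`neural_rdm()`, `model_rdm_periodicity()`,
  `rdm_correlation()`).
- **fMRI adaptation** — parametric-modulator GLMs estimating how the
  second-stimulus response scales with the pair's distance in the space
  (adaptation for near pairs) or with the number of shared actions
  (`distance_analysis()`, `overlap_analysis()`, `joint_analysis()`,
  `subsample_equalize()`).
- **gPPI** — the five-regressor generalized psychophysiological interaction
  model testing whether inter-region coupling differs between long- and
  short-distance comparisons (`fit_gppi()`, `symmetric_gppi()`).
- **Group inference** — sign-flip permutation one-sample t-tests with
  Cohen's d, confidence intervals and Bonferroni correction
  (`signflip_ttest()`, `bonferroni()`).
- **Synthetic participants** — a simulator producing ratings, multivoxel
  BOLD runs and coupled ROI time series with exactly the structure the
  analyses assume (`region_model()`, `simulate_run()`,
  `simulate_ratings()`, `simulate_coupled_rois()`), so the entire chain is
  testable without participant data.

## Worked example

```r
library(actmap)

# a participant-specific assignment and a balanced scanner session
assignment <- sample_assignment(seed = 1)
design <- generate_task1_session(seed = 1)
direction_statistics(design)[1:3, ]
#>   bin nominal mean_angle mean_distance n_longA n_longB n_short
#> 1   0       0       0.00      2.833333       3       4       5
#> 2   1      30      28.35      3.137456       3       3       6
#> 3   2      60      61.65      3.137456       3       3       6
```

The realised mean angles (0, 28.35, 61.65, ...) and the distance-class
frequencies are fixed by the admissible displacement geometry; the 144
trials sample every direction 12 times from 12 distinct starting positions.

```r
# behavioural pipeline on a noiseless synthetic rater
pos <- default_rating_positions()
ratings <- simulate_ratings(pos, sigma = 0, seed = 2)
bp <- behavior_pipeline(ratings, pos, seed = 5)
bp$spearman            # 1: rated dissimilarity tracks true distance
bp$fit$observed        # 0.0059: Procrustes distance of the recovered map
bp$fit$critical        # 0.5313: 5th percentile of the 40320-permutation null
bp$fit$significant     # TRUE
```

A perfect rater's reconstructed map beats the critical distance by two
orders of magnitude; the null has exactly 8! = 40320 entries.

```r
# hexadirectional RSA on a simulated grid-coding region
m <- region_model("ec", n_voxels = 200, sigma_p = 1, seed = 4)
pats <- simulate_condition_patterns(m, n_runs = 6, seed = 5)
rdm <- neural_rdm(scale(apply(pats, c(2, 3), mean)))
rdm_correlation(rdm, model_rdm_periodicity(6))   # 0.8625 (6-fold model)
rdm_correlation(rdm, model_rdm_periodicity(4))   # -0.1071 (mismatched control)
```

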