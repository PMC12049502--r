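Package: actmap
Title: Cognitive-Map Signatures of Action-Outcome Knowledge
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting cognitive-map signatures of abstract
    action-outcome knowledge with task fMRI. Generates balanced factorial
    event designs sampling 12 directions in a two-dimensional action-outcome
    space, reconstructs behavioural maps from pairwise similarity ratings
    (metric-stress multidimensional scaling, Procrustes fit, exhaustive
    permutation null), computes hexadirectional representational similarity
    analyses with Mahalanobis and cross-validated (crossnobis) distances,
    estimates distance- and action-overlap-based fMRI-adaptation effects with
    parametric-modulator GLMs, fits generalized psychophysiological
    interaction (gPPI) models of condition-dependent coupling, and performs
    sign-flip permutation group inference. A synthetic-participant simulator
    with hexadirectionally tuned multivoxel patterns, adaptation-scaled
    response amplitudes, HRF-convolved BOLD, and condition-dependent
    inter-region coupling makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
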