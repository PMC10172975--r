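Package: cagefrail
Title: Digital Frailty Index from Home-Cage Video Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a digital frailty index (DFI) for singly housed
    laboratory mice from per-frame home-cage video annotations. Noisy
    wheel-marker classifications are decoded into rotation events with a
    two-state hidden Markov model (Viterbi), centroid tracks are converted
    into distance and gait-speed summaries, body-weight trajectories are
    fit by weighted linear regression, coat condition is summarised by
    Sobel-gradient roughness, and nest-material displacement is measured
    over time. Eight measurements are parameterized onto a [0,1] frailty
    scale by threshold-linear mapping and averaged into a DFI. Cohort
    utilities pair DFI with manual frailty index (MFI) scores, regress
    both against chronological age, correlate age-normalized residuals,
    and cluster components by WPGMA on correlation matrices. A seeded
    synthetic-cage simulator generates ground-truth-annotated input
    channels so the whole pipeline is testable without video.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
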