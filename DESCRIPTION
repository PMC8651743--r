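Package: thrombodyn
Title: Thrombin Generation Dynamics and Goal-Oriented Coagulation Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models thrombin generation (calibrated automated thrombogram,
    CAT) curves with a delayed third-order transfer function driven by a
    tissue-factor impulse, fits the five patient-specific parameters to
    measured curves by bounded nonlinear least squares, and learns greedy
    stepwise linear maps from eight coagulation-factor concentrations
    (II, V, VII, VIII, IX, X, ATIII, protein C; percent activity) to the
    model parameters. Builds a normal CAT region from healthy-donor curves,
    scores curves against it with a mean relative error, and implements a
    single-pass Goal-oriented Coagulation Management (GCM) controller that
    recommends factor-concentration changes, clamped to the 60-140 percent
    activity band, to normalize a predicted clotting profile. Includes
    cohort equilibration statistics (delta-concentration heatmaps, Welch
    t-tests, convergence summaries) and seeded synthetic-data generators
    for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
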