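Package: locustphase
Title: Behavioral Phenotyping of Locust Phase Polyphenism in Arena Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the behavioral phase state of locust
    nymphs from open-arena trajectory recordings. Extracts the eleven
    standard zone-occupancy and activity parameters (entry frequencies,
    latencies, wall-following time, distance moved, movement bouts, and
    the attraction index) from tracked (t, x, y) paths, fits binary
    logistic discriminants of solitariness by iteratively reweighted
    least squares with forward stepwise variable selection, and scores
    individuals on the P-sol probability scale (1 = solitary behavior,
    0 = gregarious behavior). Includes the published reference
    discriminant for fourth-stadium nymphs, nonparametric and parametric
    group comparisons (Mann-Whitney U, one-way ANOVA, Student's t),
    P-sol interval summaries, and a two-state correlated-random-walk
    simulator of arena trajectories for validation studies.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
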