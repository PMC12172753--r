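Package: tmsmap
Title: TMS Motor Mapping on Cortical Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for navigated transcranial magnetic stimulation
    (TMS) motor mapping. Detects motor-evoked potentials (MEPs) in
    stimulation-locked EMG, projects stimulation sites onto triangulated
    cortical surfaces, masks them to the primary motor cortex, warps them to a
    template surface through unit-sphere registrations with curvature
    matching, and builds MEP-weighted excitability maps whose centroids,
    weighted areas, and pairwise overlaps are compared across muscles and
    stimulation intensities with repeated-measures ANOVA
    (Mauchly/Greenhouse-Geisser, Bonferroni post-hocs). Includes a synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
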