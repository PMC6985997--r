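Package: nvcflow
Title: Quantification of Neurovascular Coupling Imaging in Zebrafish Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for non-invasive neurovascular-coupling experiments
    in larval zebrafish imaged by lightsheet microscopy. Quantifies erythrocyte
    speed from time-lapse movies by particle-tracking velocimetry, neuronal
    calcium responses as background-corrected dF/F with transient peak
    detection and timing metrics, and vascular morphometry (branch points,
    centerline lengths, radii, claudin-5a reporter intensity) from 3D Z-stacks.
    Includes seeded synthetic-imagery generators with analytic ground truth for
    end-to-end validation, and the period-wise statistical comparison scheme
    (normality-gated repeated-measures tests, two-way ANOVA with Sidak post hoc
    comparisons).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    zoo,
    igraph,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
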