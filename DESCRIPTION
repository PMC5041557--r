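Package: operat
Title: Scoring and Psychometric Development of the Older People's External
    Residential Assessment Tool
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Older People's External Residential Assessment
    Tool (OPERAT), a 16-item observational instrument that scores external
    residential environments across four weighted domains (Natural Elements;
    Incivilities and Nuisance; Navigation and Mobility; Territorial
    Functioning), together with the psychometric pipeline used to build and
    validate such an instrument: Thurstone-scaled item weighting from
    importance surveys, composite domain and total scoring on a 0-100 scale,
    exploratory factor analysis with principal axis factoring and oblique
    Geomin rotation, iterative low-loading item refinement, internal
    consistency and convergent validity statistics, one-way ANOVA with Tukey
    homogeneous subsets, and Krippendorff's alpha inter-rater reliability.
    A synthetic-data module generates area assessments, weighting surveys,
    resident validation surveys and second-rater sheets with a known
    four-factor latent structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tibble,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
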