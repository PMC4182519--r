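Package: afpoverty
Title: Alkire-Foster Multidimensional Poverty Analysis for Household Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating multidimensional poverty from household
    survey data with the Alkire-Foster dual-cutoff counting method. Builds
    an 11-indicator weighted deprivation matrix from raw survey fields,
    computes the headcount ratio (H), average deprivation intensity (A) and
    adjusted headcount (M0 = H x A) with design-based confidence intervals
    honouring stratification and enumeration-area clustering, decomposes
    poverty by indicator, dimension and subgroup, and traces the headcount
    across poverty cut-offs. Includes ordinary kriging of enumeration-area
    poverty surfaces, a one-factor binary-probit latent-trait wealth index
    fitted by marginal maximum likelihood, and a calibrated synthetic
    two-stage cluster survey generator for testing and power work.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    statmod
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
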