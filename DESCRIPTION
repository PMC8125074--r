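Package: tagsip
Title: Quantitative Stable Isotope Probing of Density Gradient Fractions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired 13C/12C isopycnic CsCl gradient
    fractionations (Tag-SIP / qSIP): refractometry-to-buoyant-density
    conversion, per-OTU DNA-mass-normalized density distributions,
    weighted-mean density shifts with a Kolmogorov-Smirnov normality
    filter, conversion of density shifts to excess atom fraction of 13C
    via a GC-dependent DNA molecular-weight model, tracer mass-balance
    substrate uptake rates, quartile-trimmed metagenome coverage response
    tests, and a forward simulator of paired gradients for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
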