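Package: glycacro
Title: Dietary Glycerol and Urinary Acrolein Biomarker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating dietary glycerol intake to urinary excretion of
    the acrolein mercapturic-acid biomarkers 3-HPMA and CEMA in controlled diet
    intervention studies. Computes meal and daily glycerol from food fat content,
    converts timed urine collections to excreted biomarker amounts with
    overnight-window attribution, back-calculates intestinal acrolein with a
    mass-balance model of colonic glycerol delivery, classifies participants into
    persistent mercapturic-acid phenotypes, and summarizes glycerol/diol
    dehydratase (pdu) functional potential and short-chain fatty acid profiles
    from community tables. Includes a seeded synthetic cohort generator so the
    full pipeline is testable without access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
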