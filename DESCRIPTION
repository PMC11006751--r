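Package: e4screen
Title: Protective Rare-Variant Screening in APOE e4 Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a family-based discovery pipeline for
    rare coding variants that segregate in cognitively unaffected elderly APOE e4
    carriers and are absent in e4 non-carriers, together with its replication
    statistics (carrier-based effect-allele frequencies, 2x2 and logistic odds
    ratios, fixed-effects inverse-variance-weighted meta-analysis with Cochran's Q,
    and an age-at-onset regression) and the group-comparison statistics used for
    per-vessel immunofluorescence morphometry (Welch and Brown-Forsythe ANOVA,
    Kruskal-Wallis with Dunn's test, two-stage Benjamini-Krieger-Yekutieli FDR,
    Kolmogorov-Smirnov, and intensity-versus-diameter regression). A synthetic
    family-cohort generator with Mendelian APOE and rare-variant transmission, an
    e4-dosage-dependent Alzheimer's disease liability model, a planted protective
    effect, and sequencing-quality artifacts drives the whole analysis so that it
    runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
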