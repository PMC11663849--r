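Package: epfsit
Title: Analysis Pipeline for Entomopathogenic Fungi Combined with the Sterile Insect Technique
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of dual entomopathogenic-fungus (EPF) plus
    sterile-insect-technique (SIT) suppression studies of tsetse flies.
    Implements virulence bioassay analysis (cumulative mortality, Abbott
    control correction, median lethal time LT50 from binomial time-mortality
    regressions, SIT-compatibility classification), temperature-dependent
    fungal growth modelling (radial growth rates, linear, Lactin-1 and
    cardinal-temperature-model-with-inflection fits, AIC and adjusted R2
    model selection, Vuong non-nested comparison, cardinal temperature
    summaries), Kaplan-Meier and Mantel-Cox log-rank survival analysis of
    conidia donors and receivers, hemocytometer-based conidia load and
    retention quantification, and shared one-way ANOVA / Tukey HSD /
    compact-letter-display machinery. A synthetic-data module generates every
    input the pipeline consumes, mirroring the study designs, so the full
    workflow is testable without the unpublished raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    sandwich,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
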