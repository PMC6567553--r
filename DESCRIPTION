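Package: alsprev
Title: Incidence, Survival and Prevalence Projection for ALS from Registry Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and sex-specific incidence of amyotrophic lateral
    sclerosis (ALS) from clinic registry data with exact Poisson and Wilson
    score confidence intervals, directly standardizes rates to a reference
    population, compares regions via the standardized rate ratio, estimates
    disease duration by a from-scratch Kaplan-Meier product-limit analysis,
    and projects annual incident and prevalent cases under demographic change
    and hypothetical treatment scenarios that lengthen median survival in all
    or a genetically defined fraction of patients. Ships a synthetic registry,
    population, projection and life-table generator so the full pipeline runs
    and is testable without access to confidential case records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
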