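Package: utiaudit
Title: Diagnostic-Equity Audit of Urine-Culture Prediction Models in the
    Emergency Department
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates emergency-department encounter cohorts with urinalysis,
    urine-culture, symptom, and physician-action data; harmonizes
    heterogeneous urinalysis reporting dialects onto a single ordinal scale
    per component; derives culture-positivity, strict/liberal urinary tract
    infection (UTI), and rule-based physician-diagnosis labels; trains and
    tunes a gradient-boosted classifier of urine-culture positivity from
    urinalysis components and clinical site; and audits model versus
    physician over- and underdiagnosis across intersectional demographic
    groups, including policy-constrained decision-threshold selection,
    diagnostic odds ratios, and cross-group coefficients of variation with
    normal-approximation confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
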