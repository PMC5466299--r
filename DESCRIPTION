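Package: lesionval
Title: Lesion-Level Validation of Multiparametric MRI Diagnostic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing which multiparametric-MRI features carry
    diagnostic weight for clinically significant prostate cancer (csPCa) at
    the lesion level. Provides a lesion-table data model with csPCa labelling
    under three definitions, derived signal features (S_Max, S_Min, V_Max,
    grouped shape), a systematic logistic model battery with and without
    dynamic contrast-enhanced imaging, optimism-corrected AUC estimation via
    patient-clustered bootstrap (Harrell's procedure), bootstrap model
    comparison, and a synthetic-cohort generator that emulates the clustered,
    ordinal structure of prospective radiologic-pathologic databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
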