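Package: pcto
Title: Precision Cohort Treatment Options from Longitudinal EHR Data
Version: 0.1.0
Authors@R: person("PCTO", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Implements a precision-cohort treatment-options workflow for
    chronic disease management from longitudinal electronic health record
    (EHR) event tables: extraction of disease-specific clinical decision
    points (uncontrolled blood pressure, HbA1c or LDL at an encounter),
    stability-ranked variable selection with L1-regularized logistic
    regression, locally supervised metric learning (LSML) of a
    Mahalanobis-type patient similarity measure, dynamic construction of a
    covariate-balanced precision cohort for an index patient, and a
    treatment-options report comparing follow-up disease control across
    observed treatment decisions with Bonferroni-corrected chi-squared
    tests. Ships a synthetic-EHR generator with a confounded treatment
    policy and known ground truth so the whole pipeline is testable
    without access to any real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
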