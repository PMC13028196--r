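Package: hypotraj
Title: Five-Year Treatment-Change Trajectories of Hypoglycemia-Associated
    Medications from Pharmacy Dispensing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for drug-utilization trajectory analysis of
    glucose-lowering therapy in community-pharmacy dispensing records.
    Builds an annual medication snapshot around index and anniversary
    dates, classifies each patient-year as no change, intensification or
    de-intensification of hypoglycemia-associated medication
    (sulfonylureas and insulins), tabulates annual transition matrices,
    change subtypes and stratified crude rates, fits a continuous-time
    three-state Markov model with piecewise-constant transition
    intensities to the annual panel by maximum likelihood, computes a
    dispensing-based hypoglycemia risk score, and relates five-year net
    outcomes to risk category, age and sex by multinomial logistic
    regression. A synthetic dispensing-data generator with a known latent
    annual change process stands in for restricted pharmacy databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    nnet,
    jsonlite
Config/testthat/edition: 3
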