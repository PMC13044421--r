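Package: dualtite
Title: Dual-Agent Phase I/II Dose-Finding Designs with Late-Onset Toxicity
    and Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-based and model-assisted designs for seamless phase I/II
    dose-finding trials of two-agent combinations in which both the
    dose-limiting toxicity and the activity endpoint may occur late in a
    multi-cycle follow-up window.  Implements the Joint TITE-POCRM (partial
    order continual reassessment method with a joint two-parameter logistic
    model and Gumbel-linked binary endpoints), the Joint TITE-BLRM (per-agent
    Bayesian logistic regression models combined through an odds interaction
    model), and a TITE-comb-BOIN12 model-assisted comparator.  A seeded trial
    simulator reproduces the shared rule set (admissibility, dose skipping,
    hard safety, six stopping rules), generates correlated bivariate
    lognormal event times calibrated to scenario probabilities, and computes
    operating characteristics (correct/good/acceptable selection percentages
    and patient-assignment summaries) over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
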