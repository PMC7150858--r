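Package: pillpref
Title: Discrete Choice Experiments and Willingness-to-Pay for Solid Oral Drug Forms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and estimating discrete choice
    experiments (DCEs) on the physical characteristics of solid oral
    medications (form, size, color, copayment). Implements a
    willingness-to-pay-space mixed logit estimator fitted by maximum
    simulated likelihood with scrambled Sobol quasi-Monte-Carlo draws, a
    synthetic-respondent choice simulator with lognormally distributed scale
    and normally distributed individual WTP vectors, conditional-logit
    baselines and socio-demographic interaction models, and downstream
    willingness-to-pay summaries: significance-starred coefficient tables,
    preferred-configuration search, attribute-importance ranking and
    currency conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
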