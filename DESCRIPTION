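Package: hsctbench
Title: Risk-Adapted Benchmarking of One-Year Survival After
    Haematopoietic Stem Cell Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for registry-based, risk-adapted benchmarking of
    one-year survival after autologous and allogeneic haematopoietic stem
    cell transplantation (HSCT). Implements centre and patient eligibility
    filtering with follow-up-completeness traffic lights, the adapted
    Disease Risk Index and the HCT-specific Comorbidity Index from raw
    record fields, multiple imputation by chained equations with
    Nelson-Aalen outcome carriers, single-value imputation among 12-month
    survivors, a pooled proportional-hazards case-mix model, per-centre
    observed/expected mortality with exact-Poisson funnel limits under a
    multiplicity-adjusted significance level, data-completeness summaries
    and per-centre reports. A multi-centre synthetic registry generator
    with known ground truth makes the whole pipeline testable without
    access to any real registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    nnet,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
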