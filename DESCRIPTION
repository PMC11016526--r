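Package: acscua
Title: Lifetime Markov Cost-Utility Model of Statin Intensity After Acute
    Coronary Syndrome
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A five-state Markov cohort model comparing lifetime high-intensity
    statin therapy with low-to-moderate-intensity statin therapy in
    post-hospitalized acute coronary syndrome patients from the Indonesian
    payer perspective. Tracks a cohort through Resolved ACS, Myocardial
    Infarction, Cardiac Arrest, Revascularization and Death in one-year
    cycles with age-banded event mortality, accrues discounted costs (IDR)
    and quality-adjusted life years, and reports the incremental
    cost-effectiveness ratio. Includes probabilistic sensitivity analysis
    with beta/gamma/lognormal parameter sampling, cost-effectiveness
    acceptability curves, one-way (tornado) sensitivity analysis, a
    structural-convention sweep, a validated parameter-table data model with
    CSV/YAML round-tripping, and a synthetic parameter-table generator for
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
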