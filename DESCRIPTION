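Package: ascvdsim
Title: Lifetime Atherosclerotic Cardiovascular Disease Microsimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level discrete-event microsimulation of lifetime
    atherosclerotic cardiovascular disease (ASCVD) burden in synthetic birth
    cohorts stratified by the HDL-C/LDL-C ratio. Individuals evolve under
    competing hazards of myocardial infarction, ischaemic heart disease,
    ischaemic stroke, heart failure and other-cause (Gompertz-Makeham) death,
    with myocardial-infarction risk driven by cumulative LDL-C exposure beyond
    a 5000 mg-year threshold and stroke risk scaled per mmol/L LDL-C.
    Provides seeded synthetic-population generation, competing-risk event
    simulation, life-expectancy and quality-adjusted life-year accounting,
    per-100,000-births event tables, crude and mortality-adjusted cumulative
    incidence curves, and deterministic analytics over published summary
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    survival,
    MASS
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
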