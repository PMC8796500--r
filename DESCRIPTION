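Package: rrmscea
Title: Markov Cohort Cost-Utility Analysis of Rituximab Versus Natalizumab
    in Relapsing-Remitting Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lifetime Markov cohort state-transition model over EDSS
    disability bands for comparing two disease-modifying therapies
    (rituximab and natalizumab) in relapsing-remitting multiple sclerosis.
    Provides patient-level synthetic cohort generation, EQ-5D-3L utility
    scoring against pluggable value sets, micro-costing aggregation with
    purchasing-power-parity conversion, an annual-cycle cohort engine with
    discounting, incremental cost-effectiveness computation (ICER, net
    monetary benefit, dominance), and deterministic (tornado) plus
    probabilistic (beta/gamma Monte-Carlo) sensitivity analyses with
    cost-effectiveness acceptability curves and cost-effectiveness plane
    summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
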