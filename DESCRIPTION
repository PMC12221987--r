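Package: persisterkit
Title: Quantitative Analysis of Bacterial Antibiotic Persistence Driven by
    Alarmone-Mediated GTP Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying bacterial antibiotic persistence and
    tolerance from population and single-cell data: biphasic time-kill curve
    decomposition (persister fraction and MDK99 with persister subtraction),
    flow-cytometry gating of rare low-GTP reporter-bright subpopulations with
    an in-silico sort-and-kill assay, single-cell dormancy-entrance detection
    on time-lapse lineage traces with switch-versus-graded model comparison,
    and condition-sweep correlation analyses that separate persistence from
    tolerance. Ships a stochastic single-cell model of the (p)ppGpp-GTP
    feedback circuit of Bacillus subtilis (Hill-type self-amplifying alarmone
    synthesis, GTP-synthesis inhibition, GTP-coupled growth, and a
    CodY-repressed fluorescent low-GTP reporter) that generates all synthetic
    inputs the analysis pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
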