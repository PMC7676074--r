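Package: rtsched
Title: Radiotherapy Session Scheduling with Patient Time-Window Preferences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weekly scheduling and sequencing of external-beam radiotherapy
    sessions on linear accelerators (linacs). Builds a mixed-integer linear
    program that books every remaining irradiation session of every patient
    onto a linac, day and starting time slot while minimizing deviation from
    patient-requested time windows, subject to timeliness (due dates),
    session spacing, same-linac continuity, machine availability,
    new-patient start caps and restricted staff-presence frames. Includes a
    greedy workload-balancing patient-to-linac pre-assignment heuristic and
    a linac-cluster decomposition for large centers, a seeded synthetic
    instance generator calibrated to empirical distributions of a large
    Dutch center, solver-independent feasibility checking, schedule quality
    metrics, and JSON/CSV/YAML input-output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: python (>= 3.8) with scipy (>= 1.9) on the PATH for
    solving the mixed-integer programs (HiGHS via scipy.optimize.milp)
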