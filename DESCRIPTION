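Package: mcda4hta
Title: Multi-Criteria Decision Analysis for Health Technology Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated multi-criteria decision model for health technology
    assessment built on the nine-domain HTA Core Model. Provides a four-level
    criteria hierarchy with elicitation planning, Analytic Hierarchy Process
    (AHP) group weighting from Saaty-scale pairwise judgments with consistency
    control, triangular-fuzzy encoding of mixed-type evidence (numeric, yes/no,
    7-level linguistic), and three ranking engines - fuzzy TOPSIS, fuzzy VIKOR
    and goal programming - reported so that lower indices identify better
    technology alternatives. Includes a seeded synthetic-study generator for
    end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
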