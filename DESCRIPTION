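Package: mmtraj
Title: Multimorbidity Trajectory Sequencing, Patterns and Progression Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequencing of chronic-condition onsets into ordinal
    multimorbidity trajectories, enumeration of multimorbidity patterns as
    combinations and permutations of the first conditions, and a
    fixed-window progression design estimating relative risks of developing
    a subsequent condition given existing ones, with modified Poisson
    regression (robust sandwich variance) and Benjamini-Hochberg false
    discovery rate control. Includes a synthetic multistate cohort
    generator with known history-dependent onset hazards so that every
    analysis stage is testable without restricted claims data, plus
    self-contained implementations of the classical procedures involved
    (Wilcoxon rank-sum, Mann-Kendall, chi-square, Cochran-Armitage, Cox
    regression with Breslow tie handling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    sandwich,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
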