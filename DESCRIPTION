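Package: medras
Title: Mechanistic Modelling of DNA Double-Strand-Break Repair, Misrepair
    and Cell Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the Medras mechanistic model of radiation response.
    Starting from a minimal radiation phenotype (genome size, chromosome
    number, repair-pathway competence, checkpoint status and cell-cycle
    phase) and an exposure protocol (dose, dose-rate segments, fractions,
    radiation quality), the package simulates the induction of DNA
    double-strand breaks, their repair kinetics through fast (NHEJ), slow
    (HR or processed NHEJ) and backup (MMEJ) pathways, the fidelity of
    rejoining through an analytic Gaussian proximity model or an
    event-driven Monte Carlo engine, the biological consequences of binary
    misrepair (dicentrics, deletions, inter-arm exchanges, mutations), and
    cell survival through lethal aberrations, mitotic catastrophe and
    apoptosis.  Dose-response curves, mean inactivation doses (MID) and
    relative biological effectiveness (RBE) are derived without any
    cell-specific fitting parameters.  Damage patterns can be exchanged
    through a plain-text dialect of the Standard for DNA Damage (SDD)
    format.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
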