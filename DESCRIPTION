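Package: olzpk
Title: Parent-Metabolite Pharmacokinetics of Olanzapine Under Endotoxemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the pharmacokinetic analysis of olanzapine and its
    CYP1A2-formed metabolite desmethylolanzapine (DMO) in small-animal
    inflammation studies. Implements a joint parent-metabolite two-compartment
    model with presystemic dose splitting, solved analytically between dose
    events; a Bailer-type non-compartmental AUC estimator for destructive
    (batch) and sparse serial sampling designs with bootstrap-t confidence
    intervals; equilibrium-dialysis unbound-fraction reduction with the
    tissue-homogenate dilution correction; brain-to-plasma partition
    coefficients for total and unbound drug (Kp, Kp,uu); pooled
    maximum-likelihood fitting of the compartmental model across dosing arms
    with group contrasts; relative gene-expression quantification by the
    2^-ddCt method; and a synthetic-study generator reproducing the
    two-group, three-arm sparse sampling design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    Matrix,
    deSolve,
    readr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
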