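Package: readerscreen
Title: Quantitative Analysis for Methyl-Lysine Reader Ligand Screening Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for a ligand-screening platform targeting
    methyl-lysine reader proteins such as Spindlin1 and the JMJD2C double
    Tudor domain. Provides plate-level quantitation for AlphaLISA and
    fluorescence-polarization (FP) displacement assays (inhibition and
    quench percentages, Z'-factor, four-parameter logistic IC50 fits,
    hook-effect detection in cross-titration matrices), closed-form and
    numerical solvers for 1:1 and competitive binding equilibria, the FP
    specific-binding correction chain and hyperbolic K_D fitting, thermal
    shift (FTSA/DSF) melting-curve analysis with K_D estimation from
    ligand-dose-dependent Tm shifts via a coupled unfolding-binding model,
    global 1:1 Langmuir fitting of biolayer interferometry sensorgrams
    with competitive report-point and dissociation-shift readouts, and
    CETSA aggregation-curve analysis. Seeded simulators emulate every
    assay readout so the full pipeline is testable end to end without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
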