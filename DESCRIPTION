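Package: maldikit
Title: MALDI-MS Protein Profiling, Peptide Mass Fingerprinting and
    Fragment-Ion Identification
Version: 0.1.0
Authors@R:
    person("maldikit", "developers", email = "maldikit@example.org",
           role = c("aut", "cre"))
Description: Tools for MALDI time-of-flight mass spectrometry of protein
    mixtures and tryptic digests: residue-level mass and isoelectric-point
    arithmetic, in-silico tryptic digestion with missed cleavages and
    variable phosphorylation, theoretical b/y fragment-ion series, peak-list
    and FASTA input/output with intensity-based peak selection, multicharge
    (+1/+2/+3) deconvolution of linear-mode protein profiles with
    condition-versus-condition differential calls, a transparent peptide
    mass fingerprinting and MS/MS matching engine with isoform
    discrimination (coverage, identity, substitution maps), Beer-Lambert
    enzyme-assay arithmetic with hemodynamic indices and unpaired t-tests,
    and seeded synthetic-data generators that emit ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
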