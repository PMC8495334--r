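Package: mrmarker
Title: Design and Quantification of Species-Specific Peptide Markers for
    Meat Speciation by Targeted Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building multiple-reaction-monitoring (MRM) assays
    that detect and quantify meat adulteration. Performs in-silico tryptic
    digestion of per-species proteomes, screens digested peptides for
    species specificity (proteotypic markers) with isobaric Leu/Ile
    handling, computes monoisotopic precursor and b/y fragment ion m/z with
    fixed and variable modifications, assigns collision energies from a
    linear ramp, exports vendor-neutral transition lists, and fits linear
    standard curves from binary-mixture calibration series to estimate
    adulterant mass fractions, detection limits, and contamination calls.
    Includes a seeded synthetic-data generator (toy proteomes with planted
    unique and shared peptides; simulated mixture intensity tables) so the
    whole workflow is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
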