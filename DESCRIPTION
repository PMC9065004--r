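Package: oligoms
Title: Tandem Mass Spectrometry Identification of Modified RNA
    Oligonucleotides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bottom-up LC-MS/MS analysis of RNA sequences and their
    post-transcriptional modifications. Performs in silico endonuclease
    digestion of RNA into a target-decoy theoretical MS/MS library with
    flexible terminal chemistry, modification placement and isotope
    labeling; matches Mascot Generic Format spectra against the library
    within ppm tolerances; scores matches with an empirical S_p score and
    relative delta scores; controls false discovery rates via the
    target-decoy competition; and maps identifications onto the input
    sequences with coverage reporting. Includes a spectrum simulator for
    ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
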