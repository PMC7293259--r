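Package: apobecedit
Title: APOBEC3A Activity from Mutational Signatures, RNA-Editing Hotspots,
    and Droplet Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterize APOBEC3A (A3A) and APOBEC3B (A3B) activity
    in tumors from sequence data. Includes stem-loop (hairpin) detection and
    scoring of DNA/RNA substrate sites, YTCA/RTCA tetranucleotide context
    classification of somatic SNV catalogs with per-tumor A3A+/A3B+/APOBEC-
    labelling, discovery and quantification of DNA-absent C-to-U RNA-editing
    hotspots from paired DNA/RNA variant counts, Poisson inversion of
    two-channel droplet digital PCR counts into absolute concentrations and
    edited fractions with positivity calling, and synthetic-data generators
    with recorded ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
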