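Package: haplogeo
Title: Phylogeographic Analysis of Single-Locus Haplotype Data
Version: 0.1.0
Authors@R:
    person("Packaged", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for intraspecific phylogeography from aligned
    single-locus sequence data (e.g. mitochondrial COI or ribosomal ITS
    spacers): haplotype collapsing and diversity statistics (h with
    sampling variance, nucleotide diversity), population differentiation
    (HS/HT/GST/NST with permutation tests, AMOVA and pairwise FST, spatial
    AMOVA group search, Mantel tests), median-joining haplotype networks,
    demographic-history inference (Tajima's D, Fu's Fs, mismatch
    distributions with sudden-expansion fitting and expansion-time
    conversion), and population-level DNA-barcoding identification via
    minimum-distance and best-close-match classifiers. Includes a
    structured-coalescent simulator for generating test data with a
    two-refugium, post-expansion population structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
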