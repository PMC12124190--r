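Package: introgain
Title: Discovery of Intron Gain Events by Protein-Space Intron Marking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to locate recently gained introns in a focal species by
    projecting intron positions into protein coordinates, aligning marked
    ortholog proteins, mapping intron presence and absence onto a species
    taxonomy, and scoring candidate gain clades by the number of species that
    share the intron minus the number that lack it. Includes a detector for
    intronization events, in which part of an exon becomes a new intron, and a
    gene-family simulator that plants gain, loss, paralogy and intronization
    events along a phylogeny so the whole pipeline can be exercised and
    validated on data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
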