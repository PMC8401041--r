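Package: pseudotax
Title: Genome-Based Species Delimitation and Group Partitioning for Pseudomonas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-based bacterial taxonomy in the genus
    Pseudomonas: fragment-based average nucleotide identity (ANIb) with an
    internal seed-and-extend aligner, rpoD marker extraction and identity
    screening, a species-assignment decision tree with a digital DNA-DNA
    hybridization (dDDH) tie-break for the 95-96.5 percent ambiguity zone,
    single-linkage synonymy collapse and new-species clustering,
    neighbor-joining group/subgroup delineation from marker distances with
    bootstrap supports, and rule-based screening of NRPS gene clusters for
    cyclic lipopeptide (CLP) biosynthesis. Includes a synthetic genome and
    gene-cluster generator with recorded ground truth, and packaged
    transcriptions of the published group, synonymy, and reassignment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
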