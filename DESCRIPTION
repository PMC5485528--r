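Package: aukmatch
Title: Ancient-DNA Mitogenome Identity Matching for Museum Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An ancient-DNA analysis pipeline for testing whether museum
    specimens derive from the same individual by comparing complete
    mitochondrial genomes. Simulates damaged short-fragment aDNA reads from
    a circular mitogenome, trims and collapses read pairs, maps reads
    gaplessly to the circular reference, removes PCR duplicates, estimates
    terminal deamination profiles and rescales base qualities, calls
    haploid genotypes with genotype qualities, builds relaxed and strict
    consensus sequences, computes complete-deletion pairwise difference
    matrices, reports zero-distance identity matches, and reconstructs an
    HKY maximum-likelihood phylogeny with neighbour-joining start and
    nonparametric bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
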