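Package: cubevol
Title: Codon Usage Bias and Its Evolution in Yeast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetic-code-aware codon usage analysis for budding-yeast
    genomes, including clades with reassigned nuclear CTG codons.
    Computes relative synonymous codon usage (RSCU), GC3/GC3s, the
    effective number of codons (Nc) with Wright's null expectation,
    tRNA gene inventories from tRNAscan-SE output with gene-copy-number
    filtering, tRNA adaptation index (tAI) codon adaptiveness under
    wobble-pairing rules, and the genome-level S-value measuring
    translational selection.  Also provides protein-guided codon
    alignment, conserved-arginine site detection with parsimonious
    ancestral-codon inference, phylogenetic comparative regressions
    (independent contrasts and PGLS with Pagel's lambda), and seeded
    simulators of coding-sequence sets, tRNA pools, ortholog families,
    and trees that exercise every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
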