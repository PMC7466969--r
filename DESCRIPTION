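Package: hgtcensus
Title: Detection and Census of Bacterially Derived Horizontal Gene Transfer in Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a screen for bacterially derived
    horizontally transferred (HGT) genes in fungal genome assemblies, and of
    the secondary-metabolism (SM) gene census such candidates feed into. The
    screen combines a BLAST best-hit taxonomy classification (fungal-hit veto,
    bacterial-only candidacy at an e-value cutoff), a read-coverage z-score
    filter against the harboring scaffold that flags mis-assembled or
    contaminant genes, and a genomic-context filter requiring fungal
    neighbors. Compositional evidence (GC-content ANOVA with Tukey HSD,
    intron-count and normalized intron-length Kruskal-Wallis, 5-mer and
    codon-usage PCA) is computed from first principles. The census side
    merges antiSMASH/SMURF-style core-gene predictions (NRPS, PKS, terpene
    cyclase and relatives), cross-tabulates them against the HGT set,
    assigns domains to reference clades on phylogenies, summarizes TPM
    expression, and quantifies siderophore activity from CAS plate images.
    A fully seeded synthetic-genome generator provides ground-truthed inputs
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    ape,
    Biostrings,
    rtracklayer,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
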