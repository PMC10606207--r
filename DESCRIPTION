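Package: lncdrought
Title: Identification and Multi-Omic Analysis of Drought-Responsive lncRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for characterizing drought-responsive long
    noncoding RNAs (lncRNAs) in maize roots from stranded RNA-seq derived
    inputs. Implements a multi-stage lncRNA identification cascade
    (coding-potential consensus, protein-alignment filter, translation filter
    via RNC-seq abundance, length/abundance filter), strand-aware positional
    classification relative to coding genes, differential-expression calling
    with an exact negative-binomial test, Shannon-entropy expression
    specificity, contingency and proportion statistics, overlap of gene loci
    with recombination fragments in recombinant inbred lines, metagene
    profiling of histone/DNA/RNA modifications, SNP-density enrichment with
    expression-matched controls, simplified co-expression module detection
    with eigengene and module-trait statistics, and miRNA-bridged ceRNA
    network assembly. Ships a seeded synthetic-data generator emulating the
    statistical structure of the study design (two parents plus recombinant
    inbred lines under well-watered and water-stress conditions) with planted
    ground truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
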