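Package: polyhomeo
Title: Subgenome-Aware Analysis of Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing allopolyploid genomes at the subgenome level:
    a synthetic allopolyploid data generator with known ground truth,
    homeolog expression normalization with subgenome-balanced effective
    library sizes (TPM, TMM, log2-CPM), cross-mapping filters, Wilcoxon
    differential expression with FDR control, coverage-based copy-number
    estimation for repetitive loci such as 45S rDNA arrays, nucleolar
    dominance calls, detection of homeologous exchanges from reciprocal
    0-copy/4-copy read-depth segments corroborated by Hi-C trans-contact
    enrichment and discordant read pairs, population analyses of
    transposable-element insertion polymorphisms (site-frequency spectra,
    founder-bottleneck signatures, an inter-subgenome jump null model),
    and exact hypergeometric gene-set enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
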