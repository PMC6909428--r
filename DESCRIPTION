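Package: mutmapr
Title: Bulked-Segregant (MutMap-Style) Mapping of EMS-Induced Mutations in F2 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping a recessive EMS-induced mutation by bulked
    segregant analysis of an F2 cross. Computes the SNP-index (alternative-allele
    read fraction) per phenotype pool from stranded DP4 read counts, derives the
    expected pool indices analytically from the cross design, screens candidate
    sites with the dual-pool criterion (index 1.0 in the mutant pool, 0.3 +/- 0.1
    in the wild-type pool), tests phenotype counts against Mendelian ratios,
    discriminates tightly linked candidates with individual F2 genotypes
    (recombinant-based exclusion), and classifies the coding consequence of
    candidate SNPs (synonymous, missense, stop-gained). Includes a seeded
    synthetic-data generator for the whole design - EMS mutation spectrum,
    Haldane-map F2 meiosis, phenotype pooling, and pooled short-read counts -
    plus VCF/TSV readers and writers and a one-call pipeline orchestrator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    vcfR,
    Biostrings,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
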