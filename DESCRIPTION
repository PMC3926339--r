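Package: diploidsim
Title: Diploid Genome Variant Simulation and Quality-Profile Based Read Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the three common classes of germline variation (SNVs,
    indels and allele-specific CNVs) on a diploid realization of a reference
    genome, and generates single- or paired-end Illumina-like short reads from
    the mutated alleles using an empirical per-cycle Phred quality profile
    trained on real FASTQ data. Variant placement respects N-regions, a minimum
    SNV spacing, a user-defined transition/transversion ratio, literature-based
    indel size-category frequencies and allele-specific copy-number states.
    Every simulated variant is logged to a truth set, and a rediscovery harness
    scores variant-caller VCFs against the truth logs stratified by variant
    type, zygosity and indel size class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    parallel,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
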