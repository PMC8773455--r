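Package: mtlineage
Title: Matrilineal Structure Analysis from Mitochondrial Control-Region Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale analysis of human mitochondrial DNA
    control-region data: rCRS-relative variant profiling with forensic-style
    indel placement, motif-based haplogroup classification against a
    PhyloTree-style motif tree with macro-haplogroup and geographic-origin
    partitioning, sequence diversity statistics (segregating sites, haplotype
    and nucleotide diversity, p-distance matrices), ordination (frequency PCA
    and classical MDS), pairwise haplotype-sharing ratios between populations,
    and a spatiotemporal tracing procedure that classifies the arrival history
    of maternal lineages from dated, georeferenced ancient mitogenomes. A
    synthetic-data module generates multi-population control-region datasets
    and ancient metadata tables with known truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
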