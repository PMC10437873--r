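Package: geothermenz
Title: Extracellular Enzyme Potential Profiling for Geothermal Spring Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-annotation analysis of secreted organic-matter-degrading
    enzyme potential in hot-spring metagenome assemblies. Parses CAZyme
    overview tables, peptidase/EC annotation tables, signal-peptide
    summaries, gene maps and contig coverage; applies secretion and
    multi-tool support filters; builds coverage-normalized family-by-sample
    abundance matrices; scores cell-necromass versus photosynthate
    substrate groups; runs Spearman-correlation hierarchical clustering,
    PCA ordination and Kruskal-Wallis province comparisons; and converts
    fluorometric plate assays into potential hydrolysis rates. Includes a
    synthetic study generator with planted structure for end-to-end
    validation, and curated reference tables for 63 surveyed springs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
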