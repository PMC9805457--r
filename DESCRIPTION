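Package: pdnt
Title: Participation Degree of Non-Coding RNAs in the Transcriptome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes differentially expressed non-coding RNAs (miRNAs and
    lncRNAs) by their participation degree in the transcriptome. Each ncRNA
    receives a Contribution value (C value): the sum, over pathways enriched in
    differentially expressed genes, of the proportion of the pathway covered by
    the ncRNA's differential target genes weighted by -log10 of the pathway's
    enrichment p-value. Includes differential-expression screening,
    hypergeometric over-representation analysis with Benjamini-Hochberg
    correction, miRNA target-list ingestion and lncRNA target inference by
    co-expression, an evaluation suite (pathway-proportion comparison,
    protein-protein-interaction degree partitioning, region ratios, increase
    rates, key-ncRNA rank sums) and a seeded synthetic-data generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
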