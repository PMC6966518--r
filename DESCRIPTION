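Package: gelmap
Title: Conservation Liftover, Secretion-Signal Statistics and Degradome
    Filtering for Gelatinase A Orthologues
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative sequence analysis of gelatinase A (MMP2)
    orthologue families: curation of aligned orthologue sets, gap-map
    coordinate liftover between residue, alignment-column and reference
    coordinates, cross-species conservation tiering of predicted
    phosphorylation sites, rank-based comparison of secretion-signal
    (SignalP-style S-mean) score distributions with compact letter display,
    TAILS N-terminomics degradome filtering with P1-prime cleavage-site
    classification, and 1-D fluorescence intensity profile correlation.
    Includes a synthetic-data generator with planted ground truth so every
    stage can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
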