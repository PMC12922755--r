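Package: pancarm
Title: Arm-Level Aneuploidy and Duplex Mutation Analysis for Pancreatic Neoplasia
Version: 0.1.0
Authors@R: person("pancarm", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for chromosome-arm aneuploidy in pancreatic
    ductal adenocarcinoma and its precursor lesions. Calls arm-level gains and
    losses from discrete 500-kb bin copy-number calls produced by low-pass
    whole-genome sequencing segmentation, localizes minimal commonly gained
    regions on chromosome arms from tumors with subchromosomal gains, computes
    co-occurrence and progression-context statistics with a first-principles
    two-tailed Fisher exact test, scores per-nucleus FISH probe signal counts
    into positivity calls, and calls somatic mutations from UID-barcoded
    duplex amplicon reads. A fully seeded synthetic cohort generator emulates
    every input (karyotypes, bin-call matrices, FISH counts, expression, and
    barcoded reads) so the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
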