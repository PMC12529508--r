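Package: cyscreen
Title: Cysteine Ligandability Analysis for Competitive Chemoproteomic Screens
Version: 0.1.0
Authors@R:
    person("cyscreen", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of competitive isoTOP-ABPP style cysteine
    chemoproteomic screens. Reads labeled peptide-spectrum-match (PSM)
    quantification tables and a proteome FASTA, maps probe-labeled peptides to
    cysteine residue identifiers (ProteinID_C#), computes per-site log2(H/L)
    competition ratios with replicate merging, applies ligandability and
    anti-ligandability calling rules, summarises per-compound reactivity,
    categorises sites against a reference database, and compares stereoisomer
    pairs. Includes a synthetic-screen generator with planted ground-truth
    effects so the whole pipeline is testable without raw mass-spectrometry
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
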