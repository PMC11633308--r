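Package: zfpkit
Title: Integrative Target Analysis for Zinc-Finger RNA- and DNA-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrating multi-omic measurements of zinc-finger
    protein (ZFP) function: significant-event calling from knockdown
    differential tables with batch-residual outlier detection; eCLIP
    enriched-window annotation to transcript features with enrichment
    odds ratios; RNA Bind-n-Seq (RBNS) k-mer enrichment and
    enrichment-weighted motif matrices; protein-level calling of
    arginine/lysine-rich loci, disordered regions and occlusion-derived
    RNA-binding regions; DNA/RNA dual-binder classification with
    colocalization distances and metagene density profiles; SLAM-seq
    first-order decay fitting and half-life shift tests; Ribo-STAMP
    edits-per-read statistics; and tethering-reporter tests. A
    synthetic-data module generates every input format with planted
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
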