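Package: dualTCR
Title: Identification and Characterization of Single- and Dual-TCR T Cells
    from Single-Cell V(D)J Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@dualtcr.org",
           role = c("aut", "cre"))
Description: Tools for identifying single- and dual-receptor (allelic
    inclusion) T cells from single-cell V(D)J contig annotations, such as
    10x Genomics filtered_contig_annotations.csv files or AIRR rearrangement
    tables. Implements contig-level quality filtering, collapse of contigs
    into distinct functional alpha/beta chains per cell, a five-class
    receptor pairing taxonomy, clonotype calling and clonal expansion
    summaries, V/J gene segment usage profiles stratified by receptor class,
    integration of external T-cell subset annotations, and the group-level
    statistical comparisons (t tests, chi-square, one-way ANOVA) used in
    immune repertoire studies. A seeded synthetic-data generator with full
    ground truth supports testing of every pipeline stage, and the published
    per-sample pairing counts for the GSE168732 Kawasaki-disease IVIG cohort
    are included as a reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
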