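# Shared fixture builders: tiny contig tables written in code, plus a
# one-call wrapper running the QC stages on a simulated sample.

# A minimal well-formed 10x-style annotation data.frame; override any
# column by name.
tenxRow <- function(barcode = "AAACCTGAGTACGTTC-1",
                    contig_id = paste0(barcode, "_contig_1"),
                    is_cell = "True", high_confidence = "True",
                    chain = "TRA", v_gene = "TRAV1-1", d_gene = "",
                    j_gene = "TRAJ33", c_gene = "TRAC",
                    productive = "True", cdr3 = "CAVR", cdr3_nt = "TGTGCC",
                    reads = 100, umis = 4) {
  data.frame(barcode = barcode, is_cell = is_cell, contig_id = contig_id,
             high_confidence = high_confidence, chain = chain,
             v_gene = v_gene, d_gene = d_gene, j_gene = j_gene,
             c_gene = c_gene, productive = productive, cdr3 = cdr3,
             cdr3_nt = cdr3_nt, reads = reads, umis = umis,
             stringsAsFactors = FALSE)
}

tenxTable <- function(...) do.call(rbind, list(...))

# A paired cell: one TRA and one TRB contig (plus extras) for a barcode.
pairedCellRows <- function(barcode, extraAlpha = 0, extraBeta = 0,
                           sampleTag = barcode) {
  rows <- list(
    tenxRow(barcode, paste0(barcode, "_c1"), chain = "TRA",
            v_gene = "TRAV2", j_gene = "TRAJ4",
            cdr3_nt = paste0("TGT", sampleTag, "A")),
    tenxRow(barcode, paste0(barcode, "_c2"), chain = "TRB",
            v_gene = "TRBV2", j_gene = "TRBJ1-1",
            cdr3_nt = paste0("TGT", sampleTag, "B")))
  if (extraAlpha > 0)
    for (i in seq_len(extraAlpha))
      rows[[length(rows) + 1L]] <- tenxRow(
        barcode, paste0(barcode, "_ca", i), chain = "TRA",
        v_gene = "TRAV9-2", j_gene = "TRAJ10",
        cdr3_nt = paste0("TGT", sampleTag, "A", i))
  if (extraBeta > 0)
    for (i in seq_len(extraBeta))
      rows[[length(rows) + 1L]] <- tenxRow(
        barcode, paste0(barcode, "_cb", i), chain = "TRB",
        v_gene = "TRBV9", j_gene = "TRBJ2-1",
        cdr3_nt = paste0("TGT", sampleTag, "B", i))
  do.call(rbind, rows)
}

# Run QC + pairing on a simulateSample() result.
cellsFromSim <- function(sim, sampleId = sim$truth$cells$sample_id[1]) {
  cs <- ContigSet(sim$contigs, sampleId)
  classifyPairing(requirePaired(collapseChains(
    filterFunctionalContigs(cs))))
}
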