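test_that("each exclusion rule drops exactly its offenders, with audited counts", {
  tab <- tenxTable(
    tenxRow("B1-1", "c1"),                                   # retained
    tenxRow("B2-1", "c2", is_cell = "False"),                # rule 1
    tenxRow("B3-1", "c3", high_confidence = "False"),        # rule 2
    tenxRow("B4-1", "c4", chain = "TRG"),                    # rule 3
    tenxRow("B5-1", "c5", chain = "Multi"),                  # rule 3
    tenxRow("B6-1", "c6", productive = "False"),             # rule 4
    tenxRow("B7-1", "c7", productive = "None"),              # rule 4
    tenxRow("B8-1", "c8", chain = "TRB", v_gene = "TRBV9",
            j_gene = "TRBJ1-1"))                             # retained
  fc <- filterFunctionalContigs(ContigSet(tab, "S1"))
  df <- contigData(fc)
  expect_equal(df$barcode, c("B1-1", "B8-1"))
  qs <- qcStats(fc)
  expect_equal(qs$drop_not_cell, 1L)
  expect_equal(qs$drop_low_confidence, 1L)
  expect_equal(qs$drop_chain_not_ab, 2L)
  expect_equal(qs$drop_not_productive, 2L)
  ## drops + retained = input
  expect_equal(qs$drop_not_cell + qs$drop_low_confidence +
                 qs$drop_chain_not_ab + qs$drop_not_productive +
                 qs$n_functional, qs$n_input)
  ## idempotence
  fc2 <- filterFunctionalContigs(fc)
  expect_identical(contigData(fc2), contigData(fc))
  expect_equal(qcStats(fc2)$n_functional, qs$n_functional)
})

test_that("contigs with one chain key collapse with summed UMIs; distinct keys stay distinct", {
  tab <- tenxTable(
    tenxRow("B1-1", "c1", chain = "TRA", v_gene = "TRAV1-1",
            j_gene = "TRAJ33", cdr3_nt = "TGTGCCAAA", umis = 3),
    tenxRow("B1-1", "c2", chain = "TRA", v_gene = "TRAV1-1",
            j_gene = "TRAJ33", cdr3_nt = "TGTGCCAAA", umis = 2),
    tenxRow("B1-1", "c3", chain = "TRA", v_gene = "TRAV1-1",
            j_gene = "TRAJ33", cdr3_nt = "TGTGCCTTT", umis = 1))
  cc <- collapseChains(filterFunctionalContigs(ContigSet(tab, "S1")))
  ch <- chainData(cc)
  expect_equal(nrow(ch), 2L)  # same key merged, different junction kept
  expect_equal(sort(ch$umis), c(1L, 5L))
  expect_equal(cellData(cc)$n_alpha, 2L)
})

test_that("one CellChains per barcode, invariant under row permutation", {
  tab <- do.call(rbind, lapply(paste0("BC", 1:4, "-1"), pairedCellRows))
  base <- collapseChains(filterFunctionalContigs(ContigSet(tab, "S1")))
  expect_equal(nrow(cellData(base)), 4L)
  set.seed(1)
  perm <- tab[sample(nrow(tab)), ]
  shuffled <- collapseChains(filterFunctionalContigs(ContigSet(perm, "S1")))
  expect_identical(chainData(shuffled), chainData(base))
  expect_identical(cellData(shuffled), cellData(base))
})

test_that("contigs that cannot form a chain key are dropped with a warning", {
  tab <- tenxTable(pairedCellRows("BC1-1"),
                   tenxRow("BC1-1", "cx", v_gene = ""))
  fc <- filterFunctionalContigs(ContigSet(tab, "S1"))
  expect_warning(cc <- collapseChains(fc), "dropped")
  expect_equal(qcStats(cc)$drop_unkeyable, 1L)
  expect_equal(nrow(chainData(cc)), 2L)
})

test_that("chain identity level changes what counts as one chain", {
  ## two TRA contigs: same V/J and amino-acid CDR3, different junctions
  tab <- tenxTable(
    tenxRow("B1-1", "c1", cdr3 = "CAVR", cdr3_nt = "TGTGCCGTA"),
    tenxRow("B1-1", "c2", cdr3 = "CAVR", cdr3_nt = "TGCGCCGTC"),
    tenxRow("B1-1", "c3", chain = "TRB", v_gene = "TRBV9",
            j_gene = "TRBJ1-1", cdr3 = "CASS", cdr3_nt = "TGTAGC"))
  fc <- filterFunctionalContigs(ContigSet(tab, "S1"))
  expect_equal(cellData(collapseChains(fc, "nt"))$n_alpha, 2L)
  expect_equal(cellData(collapseChains(fc, "aa"))$n_alpha, 1L)
  expect_equal(cellData(collapseChains(fc, "gene"))$n_alpha, 1L)
})

test_that("requirePaired keeps exactly the cells with both loci", {
  tab <- tenxTable(
    pairedCellRows("BC1-1"),
    tenxRow("BC2-1", "u1", chain = "TRA", cdr3_nt = "TGTAAA"),  # alpha only
    tenxRow("BC3-1", "u2", chain = "TRB", v_gene = "TRBV9",
            j_gene = "TRBJ1-1", cdr3_nt = "TGTCCC"))            # beta only
  pp <- requirePaired(collapseChains(filterFunctionalContigs(
    ContigSet(tab, "S1"))))
  expect_equal(cellData(pp)$barcode, "BC1-1")
  expect_equal(qcStats(pp)$n_unpaired_removed, 2L)
  expect_equal(qcStats(pp)$n_paired, 1L)
  ## chains of removed cells are gone too
  expect_setequal(unique(chainData(pp)$barcode), "BC1-1")
})
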