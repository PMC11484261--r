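test_that("a well-formed 10x CSV parses row-for-row with normalized flags", {
  tab <- tenxTable(
    tenxRow("BC1-1", "BC1-1_c1", is_cell = "True", productive = "True"),
    tenxRow("BC2-1", "BC2-1_c1", is_cell = "FALSE", productive = "False",
            chain = "TRB", v_gene = "TRBV20-1*01"),
    tenxRow("BC3-1", "BC3-1_c1", high_confidence = "false",
            productive = "None"))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  cs <- readContigs(f, sampleId = "S1")
  df <- contigData(cs)
  expect_equal(nrow(df), 3L)
  expect_equal(df$barcode, c("BC1-1", "BC2-1", "BC3-1"))  # order-preserving
  expect_equal(df$is_cell, c(TRUE, FALSE, TRUE))
  expect_equal(df$high_confidence, c(TRUE, TRUE, FALSE))
  expect_equal(df$productive, c("true", "false", "none"))
  expect_equal(df$v_gene[2], "TRBV20-1")  # allele suffix stripped
  expect_equal(df$sample_id, rep("S1", 3))
})

test_that("vendor spellings of productive map onto the tri-state", {
  tab <- do.call(rbind, lapply(
    c("True", "TRUE", "true", "False", "FALSE", "false", "None", "Non",
      "NA", ""),
    function(p) tenxRow(paste0("B", p, "x-1"), productive = p)))
  cs <- ContigSet(tab, "S1")
  expect_equal(contigData(cs)$productive,
               c(rep("true", 3), rep("false", 3), rep("none", 4)))
  bad <- tenxRow("BCX-1", productive = "maybe")
  expect_error(ContigSet(bad, "S1"), "row 1")
})

test_that("AIRR rows map onto the common schema with safe defaults", {
  tab <- data.frame(cell_id = "BC1-1", sequence_id = "BC1-1_r1",
                    locus = "TRB", v_call = "TRBV20-1*01",
                    j_call = "TRBJ2-7*01", junction = "TGTGCCAGC",
                    junction_aa = "CAS", productive = "T",
                    duplicate_count = 7, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  df <- contigData(readContigs(f, "S1", dialect = "airr_tsv"))
  expect_equal(df$v_gene, "TRBV20-1")
  expect_equal(df$barcode, "BC1-1")
  expect_equal(df$chain, "TRB")
  expect_equal(df$cdr3_nt, "TGTGCCAGC")
  expect_equal(df$umis, 7L)
  expect_true(df$is_cell)          # defaults when the dialect lacks them
  expect_true(df$high_confidence)
})

test_that("a missing required column is reported by name", {
  tab <- tenxRow("BC1-1")
  expect_error(ContigSet(tab[, setdiff(names(tab), "productive")], "S1"),
               "productive")
  expect_error(ContigSet(data.frame(cell_id = "x"), "S1",
                         dialect = "airr_tsv"), "locus")
})

test_that("write/read round trips preserve the dialect's fields", {
  sim <- simulateSample(simConfig(nCells = 10, seed = 21))
  cs <- ContigSet(sim$contigs, "S9")
  for (dialect in c("tenx_csv", "airr_tsv")) {
    f <- withr::local_tempfile()
    kept <- writeContigs(cs, f, dialect = dialect)
    back <- readContigs(f, "S9", dialect = dialect)
    for (field in kept)
      expect_equal(contigData(back)[[field]], contigData(cs)[[field]],
                   label = paste(dialect, field))
  }
  ## the 10x->AIRR->10x trip loses exactly is_cell and high_confidence
  lost <- setdiff(writeContigs(cs, withr::local_tempfile(), "tenx_csv"),
                  writeContigs(cs, withr::local_tempfile(), "airr_tsv"))
  expect_setequal(lost, c("is_cell", "high_confidence"))
})

test_that("an empty ContigSet writes a valid header-only file", {
  empty <- ContigSet(tenxRow("B-1")[0, ], "S1")
  f <- withr::local_tempfile(fileext = ".csv")
  writeContigs(empty, f, "tenx_csv")
  back <- readContigs(f, "S1")
  expect_equal(nrow(contigData(back)), 0L)
})
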