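test_that("the generator is deterministic in its seed", {
  a <- simulateSample(simConfig(nCells = 150, seed = 42,
                                noise = list(fracNonCell = 0.05,
                                             duplicateContigRate = 0.05)))
  b <- simulateSample(simConfig(nCells = 150, seed = 42,
                                noise = list(fracNonCell = 0.05,
                                             duplicateContigRate = 0.05)))
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$subsets, b$subsets)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- simulateSample(simConfig(nCells = 150, seed = 43))
  expect_false(identical(a$contigs, c$contigs))
})

test_that("zero-noise output is perfectly identifiable", {
  sim <- simulateSample(simConfig(nCells = 600, seed = 3))
  cells <- cellsFromSim(sim)
  ce <- cellData(cells)
  tr <- sim$truth$cells
  expect_equal(nrow(ce), nrow(tr))
  m <- match(ce$barcode, tr$barcode)
  expect_equal(ce$pairing_type, tr$pairing_type[m])
  counts <- table(factor(ce$pairing_type, levels = pairingLevels()))
  expect_equal(as.integer(counts),
               as.integer(sim$truth$class_counts))
})

test_that("injected noise is labeled and fails exactly one rule each", {
  cfg <- simConfig(nCells = 250, seed = 19, noise = list(
    fracNonCell = 0.06, fracLowConf = 0.05, fracNonProductive = 0.07,
    fracGammaDelta = 0.03, duplicateContigRate = 0.04,
    unpairedCellRate = 0.08))
  sim <- simulateSample(cfg)
  expect_equal(length(sim$truth$contig_labels), nrow(sim$contigs))
  nc <- sim$truth$noise_counts
  lab <- table(sim$truth$contig_labels)
  expect_equal(unname(lab[["noncell"]]), unname(nc[["noncell"]]))
  ## duplicates collapse away: chain counts match truth despite them
  cells <- cellsFromSim(sim)
  ce <- cellData(cells)
  tr <- sim$truth$cells
  expect_equal(nrow(ce), nrow(tr))
  expect_equal(ce$pairing_type,
               tr$pairing_type[match(ce$barcode, tr$barcode)])
})

test_that("impossible or malformed configs are rejected", {
  expect_error(simConfig(nCells = 10,
                         plantedClones = list(list(size = 11))),
               "planted")
  expect_error(simConfig(pairingProbs = c(SINGLE_AB = 0.5,
                                          DUAL_A_B1B2 = 0.2,
                                          DUAL_B_A1A2 = 0.2,
                                          DUAL_A1A2B1B2 = 0.2,
                                          OTHERS = 0.2)), "sum to 1")
  expect_error(simConfig(noise = list(fracBogus = 0.1)), "fracBogus")
  expect_error(simConfig(noise = list(fracNonCell = 1.5)), "rate")
  expect_error(simConfig(plantedClones = list(list(size = 2,
                                                   pairing = "TRIPLE"))),
               "pairing")
})

test_that("synthetic junctions look like junctions", {
  sim <- simulateSample(simConfig(nCells = 80, seed = 23))
  nt <- sim$contigs$cdr3_nt
  expect_true(all(substr(nt, 1, 3) %in% c("TGT", "TGC")))
  expect_true(all(nchar(nt) %% 3 == 0))
  expect_true(all(nchar(nt) >= 30 & nchar(nt) <= 60))
  ## chain keys are unique within each cell (clone members share chains
  ## across cells by design)
  ch <- chainData(cellsFromSim(sim))
  expect_false(anyDuplicated(paste(ch$barcode, ch$chain_key)) > 0)
})

test_that("cohorts write one file pair per sample plus the manifest", {
  preset <- kdCohortPreset(seed = 2, nScale = 0.01)
  dir <- withr::local_tempdir()
  cohort <- simulateCohort(preset$configs, preset$manifest, dir = dir)
  expect_setequal(names(cohort$sims), preset$manifest$sample_id)
  expect_true(all(file.exists(cohort$paths$contigs)))
  expect_true(all(file.exists(cohort$paths$subsets)))
  back <- readContigs(cohort$paths$contigs[["KD1_pre"]], "KD1_pre")
  expect_gt(nrow(contigData(back)), 0)
  dup <- preset$configs[c(1, 1)]
  expect_error(simulateCohort(dup, preset$manifest), "uniquely named")
})
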