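test_that("pairing type is a pure function of chain multiplicities", {
  ## frozen rule table over all (a, b) in 1..4 x 1..4
  expected <- matrix("OTHERS", 4, 4)
  expected[1, 1] <- "SINGLE_AB"
  expected[1, 2] <- "DUAL_A_B1B2"
  expected[2, 1] <- "DUAL_B_A1A2"
  expected[2, 2] <- "DUAL_A1A2B1B2"
  for (a in 1:4)
    for (b in 1:4)
      expect_equal(pairingType(a, b), expected[a, b],
                   label = sprintf("a=%d b=%d", a, b))
  expect_error(pairingType(0, 1), "paired")
  expect_equal(receptorClass(c("SINGLE_AB", "OTHERS", "DUAL_B_A1A2")),
               c("single", "dual", "dual"))
})

test_that("classifyPairing labels every paired cell and rejects unpaired ones", {
  tab <- tenxTable(pairedCellRows("BC1-1"),
                   pairedCellRows("BC2-1", extraAlpha = 1),
                   pairedCellRows("BC3-1", extraAlpha = 2))
  cells <- classifyPairing(requirePaired(collapseChains(
    filterFunctionalContigs(ContigSet(tab, "S1")))))
  ce <- cellData(cells)
  expect_equal(ce$pairing_type[match(paste0("BC", 1:3, "-1"), ce$barcode)],
               c("SINGLE_AB", "DUAL_B_A1A2", "OTHERS"))
  unpaired <- collapseChains(filterFunctionalContigs(ContigSet(
    tenxRow("BX-1", chain = "TRA"), "S1")))
  expect_error(classifyPairing(unpaired), "requirePaired")
})

test_that("sample summaries reproduce published single/dual arithmetic", {
  counts <- kdCohortCounts()
  smry <- summaryFromCounts(counts)
  kd1 <- smry[smry$sample_id == "KD1_pre", ]
  expect_equal(kd1$n_paired, 1217)
  expect_equal(kd1$pct_single, 95.40)   # 1161 / 1217
  expect_equal(kd1$pct_dual_total, 4.60)
  kd3 <- smry[smry$sample_id == "KD3_pre", ]
  expect_equal(kd3$n_dual_total, 104 + 288 + 49 + 23)  # 464
  expect_equal(kd3$pct_dual_total, 15.08)
})

test_that("an all-single sample gives 100/0 and an empty sample errors", {
  tab <- do.call(rbind, lapply(sprintf("BC%03d-1", 1:100), pairedCellRows))
  cells <- cellsFromSim(list(contigs = tab,
                             truth = list(cells = data.frame(
                               sample_id = "S1"))), "S1")
  smry <- summarizeSample(cells)
  expect_equal(smry$n_paired, 100L)
  expect_equal(smry$pct_single, 100)
  expect_equal(smry$pct_dual_total, 0)
  expect_error(summaryFromCounts(data.frame(
    sample_id = "E", n_single = 0, n_dual_a_b1b2 = 0, n_dual_b_a1a2 = 0,
    n_dual_a1a2b1b2 = 0, n_others = 0)), "empty")
})

test_that("summary invariants hold on simulated samples across seeds", {
  for (seed in 1:3) {
    sim <- simulateSample(simConfig(nCells = 400, seed = seed))
    smry <- summarizeSample(cellsFromSim(sim))
    expect_equal(smry$n_single + smry$n_dual_total, smry$n_paired)
    expect_equal(smry$n_dual_a_b1b2 + smry$n_dual_b_a1a2 +
                   smry$n_dual_a1a2b1b2 + smry$n_others,
                 smry$n_dual_total)
    ## unrounded proportions partition 100 exactly
    u <- 100 * c(smry$n_single, smry$n_dual_total) / smry$n_paired
    expect_equal(sum(u), 100)
  }
})

test_that("group aggregation averages unrounded per-sample proportions", {
  smry <- summaryFromCounts(kdCohortCounts())
  agg <- aggregateGroups(smry)
  nc <- agg[agg$group == "control" & agg$metric == "pct_dual_total", ]
  ## frozen from the published control counts: mean of 406/3350, 287/2389,
  ## 351/2844 in percent
  expect_equal(nc$mean, 12.1582, tolerance = 1e-4)
  expect_equal(nc$n_samples, 3L)
  ## single-sample group: mean = that sample, sd absent
  one <- summaryFromCounts(kdCohortCounts()[1, ])
  agg1 <- aggregateGroups(one)
  expect_true(all(is.na(agg1$sd)))
  expect_equal(agg1$mean[agg1$metric == "pct_dual_total"],
               100 * 56 / 1217, tolerance = 1e-9)
})

test_that("pre/post pairs are aligned by patient id through the manifest", {
  smry <- summaryFromCounts(kdCohortCounts())
  pd <- pairedDifferences(smry, kdCohortManifest())
  expect_equal(pd$patient_id, paste0("KD", 1:6))
  expect_equal(pd$before[pd$patient_id == "KD1"], 100 * 56 / 1217,
               tolerance = 1e-9)
  expect_equal(pd$after[pd$patient_id == "KD1"], 100 * 407 / 2911,
               tolerance = 1e-9)
  ## the one patient whose dual fraction decreased
  expect_lt(pd$diff[pd$patient_id == "KD5"], 0)
  expect_equal(sum(pd$diff > 0), 5L)
})
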