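# One dual cell's rows sharing a fixed chain set, for clonotype fixtures.
dualCellRows <- function(barcode, alphaTag = "AAA") {
  tenxTable(
    tenxRow(barcode, paste0(barcode, "_c1"), chain = "TRA",
            v_gene = "TRAV2", j_gene = "TRAJ4",
            cdr3_nt = paste0("TGT", alphaTag)),
    tenxRow(barcode, paste0(barcode, "_c2"), chain = "TRB",
            v_gene = "TRBV2", j_gene = "TRBJ1-1", cdr3_nt = "TGTBBB"),
    tenxRow(barcode, paste0(barcode, "_c3"), chain = "TRB",
            v_gene = "TRBV9", j_gene = "TRBJ2-1", cdr3_nt = "TGTCCC"))
}

test_that("cells sharing a full chain set form one expanded clonotype", {
  tab <- do.call(rbind, lapply(c("BC1-1", "BC2-1", "BC3-1"), dualCellRows))
  cells <- cellsFromSim(list(contigs = tab), "S1")
  cl <- callClonotypes(cells)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size, 3L)
  expect_true(cl$expanded)
  expect_equal(cl$receptor_class, "dual")
  expect_equal(cl$n_chains, 3)
})

test_that("all-unique cells give singleton, unexpanded clonotypes", {
  tab <- do.call(rbind, lapply(sprintf("BC%02d-1", 1:8), pairedCellRows))
  cl <- callClonotypes(cellsFromSim(list(contigs = tab), "S1"))
  expect_equal(nrow(cl), 8L)
  expect_true(all(cl$size == 1L))
  expect_false(any(cl$expanded))
})

test_that("beta_only merges cells that full_set keeps apart", {
  ## same beta pair, alpha chains differ
  tab <- rbind(dualCellRows("BC1-1", alphaTag = "AAA"),
               dualCellRows("BC2-1", alphaTag = "GGG"))
  cells <- cellsFromSim(list(contigs = tab), "S1")
  expect_equal(nrow(callClonotypes(cells, "full_set")), 2L)
  beta <- callClonotypes(cells, "beta_only")
  expect_equal(nrow(beta), 1L)
  expect_equal(beta$size, 2L)
  expect_error(callClonotypes(cells, "byN"), "definition")
})

test_that("clonotype partition and permutation invariance hold on simulations", {
  for (seed in c(2, 5)) {
    sim <- simulateSample(simConfig(nCells = 300, seed = seed))
    cells <- cellsFromSim(sim)
    cl <- callClonotypes(cells)
    ce <- cellData(cells)
    for (cls in c("single", "dual"))
      expect_equal(sum(cl$size[cl$receptor_class == cls]),
                   sum(ce$receptor_class == cls),
                   label = paste("partition", cls, "seed", seed))
    ## permutation of the input contig rows changes nothing
    perm <- sim$contigs[rev(seq_len(nrow(sim$contigs))), ]
    cl2 <- callClonotypes(cellsFromSim(list(contigs = perm), "S1"))
    cl2$clonotype_id <- sub("^S1", sim$truth$cells$sample_id[1],
                            cl2$clonotype_id)
    cl2$sample_id <- sim$truth$cells$sample_id[1]
    expect_identical(cl2, cl)
  }
})

test_that("expansion summary arithmetic on clone sizes {3,1,1}", {
  tab <- rbind(do.call(rbind, lapply(c("BC1-1", "BC2-1", "BC3-1"),
                                     dualCellRows)),
               pairedCellRows("BC4-1", sampleTag = "X1"),
               pairedCellRows("BC5-1", sampleTag = "X2"))
  cl <- callClonotypes(cellsFromSim(list(contigs = tab), "S1"))
  es <- expansionSummary(cl)
  dual <- es[es$receptor_class == "dual", ]
  expect_equal(dual$n_expanded, 1L)
  expect_equal(dual$n_cells_expanded, 3L)
  expect_equal(dual$max_clone_size, 3L)
  expect_equal(dual$frac_cells_expanded, 1)  # all 3 dual cells in the clone
  single <- es[es$receptor_class == "single", ]
  expect_equal(single$n_expanded, 0L)
  expect_equal(single$frac_cells_expanded, 0)
})

test_that("a planted clone surfaces in the expansion summary", {
  sim <- simulateSample(simConfig(
    nCells = 200, seed = 13,
    plantedClones = list(list(size = 5, pairing = "DUAL_B_A1A2"))))
  cl <- callClonotypes(cellsFromSim(sim))
  es <- expansionSummary(cl)
  dual <- es[es$receptor_class == "dual", ]
  expect_gte(dual$n_expanded, 1L)
  expect_equal(dual$max_clone_size, 5L)
})

test_that("usage counts chains, not cells, and normalizes within strata", {
  ## one dual cell with two beta chains: both genes counted once
  tab <- dualCellRows("BC1-1")
  cells <- cellsFromSim(list(contigs = tab), "S1")
  us <- geneUsage(cells, "TRBV")
  expect_setequal(us$gene, c("TRBV2", "TRBV9"))
  expect_equal(us$chain_count, c(1L, 1L))
  expect_equal(us$frequency, c(0.5, 0.5))
  ## a stratum with a single chain has frequency 1
  ua <- geneUsage(cells, "TRAV")
  expect_equal(ua$frequency, 1)
  ## frequencies sum to 1 in every non-empty stratum of a larger sample
  sim <- simulateSample(simConfig(nCells = 300, seed = 4))
  big <- geneUsage(cellsFromSim(sim), "TRBV")
  sums <- tapply(big$frequency, big$receptor_class, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("generator pool weights are recovered from usage frequencies", {
  pools <- defaultGenePools()
  pools$TRBV <- list(genes = c("TRBV5-1", "TRBV19", "TRBV28"),
                     weights = c(0.5, 0.3, 0.2))
  sim <- simulateSample(simConfig(
    nCells = 10000, seed = 17,
    pairingProbs = c(SINGLE_AB = 1, DUAL_A_B1B2 = 0, DUAL_B_A1A2 = 0,
                     DUAL_A1A2B1B2 = 0, OTHERS = 0),
    genePools = pools))
  us <- geneUsage(cellsFromSim(sim), "TRBV")
  expect_equal(sum(us$chain_count), 10000L)  # one beta chain per cell
  got <- us$frequency[match(c("TRBV5-1", "TRBV19", "TRBV28"), us$gene)]
  expect_equal(got, c(0.5, 0.3, 0.2), tolerance = 0.02)
})
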