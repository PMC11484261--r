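## Seeded synthetic contig-table generator with full ground truth, so that
## every pipeline stage can be tested without any external download.

## Static codon table used to reverse-translate synthetic CDR3 amino-acid
## strings into nucleotide junctions (random synonymous codon per residue).
.CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"),
  F = c("TTT", "TTC"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"), L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  M = "ATG", N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA", "CCG"), Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))

.AA <- names(.CODONS)

## Chain multiplicities implied by each pairing type; OTHERS is generated
## as the minimal instance of the residual class (3 alpha + 1 beta).
.N_ALPHA <- c(SINGLE_AB = 1L, DUAL_A_B1B2 = 1L, DUAL_B_A1A2 = 2L,
              DUAL_A1A2B1B2 = 2L, OTHERS = 3L)
.N_BETA <- c(SINGLE_AB = 1L, DUAL_A_B1B2 = 2L, DUAL_B_A1A2 = 1L,
             DUAL_A1A2B1B2 = 2L, OTHERS = 1L)

#' Default V/J gene pools with biased usage weights
#'
#' IMGT-style gene segment names with geometrically decaying sampling
#' weights, emulating the biased V/J usage of real repertoires. Names are
#' opaque strings to the pipeline; no nomenclature semantics are attached.
#'
#' @return A list with elements \code{TRAV}, \code{TRAJ}, \code{TRBV},
#'   \code{TRBJ}, each a list of \code{genes} and normalized
#'   \code{weights}.
#' @export
defaultGenePools <- function() {
  decayw <- function(n, rate) {
    w <- exp(-rate * seq_len(n))
    w / sum(w)
  }
  trav <- c("TRAV1-1", "TRAV1-2", paste0("TRAV", 2:41))
  traj <- paste0("TRAJ", 3:61)
  trbv <- paste0("TRBV", 2:30)
  trbj <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))
  list(TRAV = list(genes = trav, weights = decayw(length(trav), 0.08)),
       TRAJ = list(genes = traj, weights = decayw(length(traj), 0.05)),
       TRBV = list(genes = trbv, weights = decayw(length(trbv), 0.10)),
       TRBJ = list(genes = trbj, weights = decayw(length(trbj), 0.15)))
}

.checkProbs <- function(p, labels, what) {
  if (is.null(names(p))) names(p) <- labels
  if (!setequal(names(p), labels))
    bail(what, " must be named over: ", paste(labels, collapse = ", "))
  p <- p[labels]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    bail(what, " must be non-negative and sum to 1")
  p
}

.checkRate <- function(r, what) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
    bail(what, " must be a rate in [0, 1]")
  r
}

#' Configuration for one synthetic sample
#'
#' Assembles and validates the parameters of the generator. Defaults
#' describe a realistic peripheral-blood alpha/beta T-cell sample: a
#' 12.1\% dual-receptor fraction dominated by the two-alpha
#' (\code{DUAL_B_A1A2}) class - the composition observed in healthy
#' pediatric controls - a mostly-unexpanded geometric clone-size law
#' (mean clone size ~1.11), biased V/J usage, seven-subset composition,
#' and zero noise.
#'
#' @param nCells Number of true paired T cells to simulate.
#' @param pairingProbs Probabilities over the five pairing types
#'   (named, summing to 1).
#' @param cloneGeomP Success parameter of the geometric clone-size law:
#'   clone size = 1 + Geom(\code{cloneGeomP}), mean 1/\code{cloneGeomP}.
#' @param plantedClones Optional list of fixed clones, each
#'   \code{list(size =, pairing =)}; planted cells count toward
#'   \code{nCells}.
#' @param genePools V/J pools as from \code{\link{defaultGenePools}}.
#' @param subsetProbs Probabilities over the seven subsets.
#' @param dualSubsetBias Named multipliers applied to \code{subsetProbs}
#'   for dual cells (renormalized), e.g. \code{c(treg = 2)} plants a
#'   two-fold Treg enrichment among dual cells.
#' @param noise List of contamination rates, all defaulting to 0:
#'   \code{fracNonCell}, \code{fracLowConf}, \code{fracNonProductive},
#'   \code{fracGammaDelta} (relative to the clean contig count),
#'   \code{duplicateContigRate} (fraction of clean contigs emitted twice
#'   with split UMIs), \code{unpairedCellRate} (extra single-locus cells
#'   relative to \code{nCells}), \code{doubletRate} (fraction of cells
#'   merged pairwise under one barcode - the main biological confounder
#'   of dual-TCR calls, off by default).
#' @param seed Integer seed; identical seeds give identical output.
#' @param sampleId Sample label written into the annotation table.
#' @return A validated config list of class \code{"dualTCRSimConfig"}.
#' @seealso \code{\link{simulateSample}}
#' @export
simConfig <- function(nCells = 1000L,
                      pairingProbs = c(SINGLE_AB = 0.879,
                                       DUAL_A_B1B2 = 0.034,
                                       DUAL_B_A1A2 = 0.073,
                                       DUAL_A1A2B1B2 = 0.010,
                                       OTHERS = 0.004),
                      cloneGeomP = 0.9,
                      plantedClones = list(),
                      genePools = defaultGenePools(),
                      subsetProbs = c(naive_cd4 = 0.25, naive_cd8 = 0.20,
                                      cd4_cm = 0.15, cd8_cm = 0.10,
                                      cd4_em = 0.10, cd8_em = 0.12,
                                      treg = 0.08),
                      dualSubsetBias = NULL,
                      noise = list(),
                      seed = 1L,
                      sampleId = "S1") {
  nCells <- as.integer(nCells)
  if (is.na(nCells) || nCells < 1L)
    bail("nCells must be a positive integer")
  pairingProbs <- .checkProbs(pairingProbs, .PAIRING_TYPES, "pairingProbs")
  subsetProbs <- .checkProbs(subsetProbs, .SUBSET_LABELS, "subsetProbs")
  if (cloneGeomP <= 0 || cloneGeomP > 1)
    bail("cloneGeomP must be in (0, 1]")
  bias <- stats::setNames(rep(1, length(.SUBSET_LABELS)), .SUBSET_LABELS)
  if (!is.null(dualSubsetBias)) {
    bad <- setdiff(names(dualSubsetBias), .SUBSET_LABELS)
    if (length(bad))
      bail("unknown subset in dualSubsetBias: ", paste(bad, collapse = ", "))
    bias[names(dualSubsetBias)] <- dualSubsetBias
  }
  noiseDefaults <- list(fracNonCell = 0, fracLowConf = 0,
                        fracNonProductive = 0, fracGammaDelta = 0,
                        duplicateContigRate = 0, unpairedCellRate = 0,
                        doubletRate = 0)
  bad <- setdiff(names(noise), names(noiseDefaults))
  if (length(bad))
    bail("unknown noise rate(s): ", paste(bad, collapse = ", "))
  noiseDefaults[names(noise)] <- noise
  for (nm in names(noiseDefaults)) .checkRate(noiseDefaults[[nm]], nm)
  for (pc in plantedClones) {
    if (is.null(pc$size) || pc$size < 1L)
      bail("each planted clone needs a positive size")
    if (!is.null(pc$pairing) && !pc$pairing %in% .PAIRING_TYPES)
      bail("unknown planted-clone pairing type: ", pc$pairing)
  }
  plantedTotal <- sum(vapply(plantedClones,
                             function(pc) as.integer(pc$size), integer(1L)))
  if (plantedTotal > nCells)
    bail("planted clones hold ", plantedTotal, " cells but nCells is ",
         nCells)
  structure(list(nCells = nCells, pairingProbs = pairingProbs,
                 cloneGeomP = cloneGeomP, plantedClones = plantedClones,
                 genePools = genePools, subsetProbs = subsetProbs,
                 dualSubsetBias = bias, noise = noiseDefaults,
                 seed = as.integer(seed), sampleId = as.character(sampleId)),
            class = "dualTCRSimConfig")
}

## n unique cell barcodes: random 16-mers with the usual "-1" suffix.
.randomBarcodes <- function(n, avoid = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    mat <- matrix(sample(c("A", "C", "G", "T"), 16L * need, replace = TRUE),
                  nrow = need)
    bc <- paste0(apply(mat, 1L, paste, collapse = ""), "-1")
    out <- unique(c(out, setdiff(bc, avoid)))
  }
  out[seq_len(n)]
}

## Random CDR3s: amino-acid string starting with Cys, 10-20 residues,
## reverse-translated with random synonymous codons (length 30-60 nt,
## multiple of 3). Cosmetically realistic; no junctional biology claimed.
.randomCdr3 <- function(n) {
  if (n == 0L)
    return(list(aa = character(0), nt = character(0)))
  lens <- sample(10:20, n, replace = TRUE)
  total <- sum(lens)
  chainIdx <- rep.int(seq_len(n), lens)
  firstPos <- !duplicated(chainIdx)
  aa <- sample(.AA, total, replace = TRUE)
  aa[firstPos] <- "C"
  ncod <- lengths(.CODONS)
  flat <- unlist(.CODONS, use.names = FALSE)
  offset <- cumsum(ncod) - ncod
  aaIdx <- match(aa, .AA)
  pick <- offset[aaIdx] + 1L + floor(stats::runif(total) * ncod[aaIdx])
  codons <- flat[pick]
  list(aa = unname(vapply(split(aa, chainIdx), paste, character(1L),
                          collapse = "")),
       nt = unname(vapply(split(codons, chainIdx), paste, character(1L),
                          collapse = "")))
}

## Draw n chains for one locus: V/J from the weighted pools plus a unique
## CDR3; uniqueness across the sample guarantees distinct chain keys.
.drawChains <- function(n, locus, pools) {
  if (n == 0L)
    return(data.frame(locus = character(0), v_gene = character(0),
                      j_gene = character(0), cdr3_aa = character(0),
                      cdr3_nt = character(0), stringsAsFactors = FALSE))
  vp <- pools[[paste0(locus, "V")]]
  jp <- pools[[paste0(locus, "J")]]
  cdr3 <- .randomCdr3(n)
  while (anyDuplicated(cdr3$nt)) {
    dup <- which(duplicated(cdr3$nt))
    redo <- .randomCdr3(length(dup))
    cdr3$aa[dup] <- redo$aa
    cdr3$nt[dup] <- redo$nt
  }
  data.frame(locus = locus,
             v_gene = sample(vp$genes, n, replace = TRUE,
                             prob = vp$weights),
             j_gene = sample(jp$genes, n, replace = TRUE,
                             prob = jp$weights),
             cdr3_aa = cdr3$aa, cdr3_nt = cdr3$nt,
             stringsAsFactors = FALSE)
}

#' Simulate one sample's contig annotation table with ground truth
#'
#' Draws clonotypes (pairing type, chain set, clone size), expands them
#' into cells, assigns each cell a T-cell subset, and emits (i) a raw
#' contig annotation table in the 10x CSV column layout, (ii) a subset
#' annotation table and (iii) a ground-truth record. At zero noise the
#' emitted table is perfectly identifiable: QC passes every contig,
#' collapse recovers exactly the generated chain sets, and every pipeline
#' stage reproduces the truth labels.
#'
#' Noise contigs are injected after the clean table is built, each
#' violating exactly one QC rule (non-cell barcode, low-confidence flag,
#' non-productive junction, gamma/delta locus), so per-rule drop counts
#' can be asserted against the injected counts exactly. Duplicate contigs
#' repeat an existing chain with split UMIs and are absorbed by chain
#' collapse; unpaired single-locus cells are removed by the paired-cell
#' rule. Every emitted row carries a hidden truth label in
#' \code{truth$contig_labels}.
#'
#' @param config A \code{\link{simConfig}}.
#' @return A list: \code{contigs} (raw annotation \code{data.frame} in 10x
#'   column layout, flags spelled \code{"True"/"False"/"None"}),
#'   \code{subsets} (annotation table for the true cells), and
#'   \code{truth} with per-cell labels (\code{barcode},
#'   \code{pairing_type}, \code{receptor_class}, \code{clonotype_id},
#'   \code{subset}), \code{clone_sizes}, \code{class_counts},
#'   \code{noise_counts} and \code{contig_labels}.
#' @examples
#' sim <- simulateSample(simConfig(nCells = 100, seed = 42))
#' head(sim$contigs)
#' sim$truth$class_counts
#' @export
simulateSample <- function(config) {
  if (!inherits(config, "dualTCRSimConfig"))
    bail("config must come from simConfig()")
  set.seed(config$seed)
  pools <- config$genePools
  sid <- config$sampleId

  ## --- clonotypes: planted first, then geometric sizes ----------------
  plantedSizes <- vapply(config$plantedClones,
                         function(pc) as.integer(pc$size), integer(1L))
  plantedPairing <- vapply(config$plantedClones, function(pc) {
    if (is.null(pc$pairing)) "DUAL_B_A1A2" else pc$pairing
  }, character(1L))
  remaining <- config$nCells - sum(plantedSizes)
  sizes <- plantedSizes
  pairing <- plantedPairing
  if (remaining > 0L) {
    draw <- 1L + stats::rgeom(remaining, config$cloneGeomP)
    keep <- which(cumsum(draw) >= remaining)[1L]
    draw <- draw[seq_len(keep)]
    draw[keep] <- draw[keep] - (sum(draw) - remaining)
    draw <- draw[draw > 0L]
    sizes <- c(sizes, draw)
    pairing <- c(pairing, sample(.PAIRING_TYPES, length(draw),
                                 replace = TRUE,
                                 prob = config$pairingProbs))
  }
  nClones <- length(sizes)

  ## --- chain sets per clonotype ---------------------------------------
  nA <- .N_ALPHA[pairing]
  nB <- .N_BETA[pairing]
  alpha <- .drawChains(sum(nA), "TRA", pools)
  beta <- .drawChains(sum(nB), "TRB", pools)
  alpha$clone <- rep.int(seq_len(nClones), nA)
  beta$clone <- rep.int(seq_len(nClones), nB)
  chains <- rbind(alpha, beta)
  chains <- chains[order(chains$clone), , drop = FALSE]
  chainCount <- as.integer(nA + nB)
  chainOffset <- cumsum(chainCount) - chainCount

  ## --- cells -----------------------------------------------------------
  cloneOfCell <- rep.int(seq_len(nClones), sizes)
  nCells <- length(cloneOfCell)
  barcodes <- .randomBarcodes(nCells)
  isDual <- pairing[cloneOfCell] != "SINGLE_AB"
  dualProbs <- config$subsetProbs * config$dualSubsetBias
  dualProbs <- dualProbs / sum(dualProbs)
  subset <- character(nCells)
  subset[!isDual] <- sample(.SUBSET_LABELS, sum(!isDual), replace = TRUE,
                            prob = config$subsetProbs)
  subset[isDual] <- sample(.SUBSET_LABELS, sum(isDual), replace = TRUE,
                           prob = dualProbs)

  ## --- doublet emulation (default off) --------------------------------
  doubletPairs <- 0L
  if (config$noise$doubletRate > 0 && nCells >= 2L) {
    doubletPairs <- floor(config$noise$doubletRate * nCells / 2)
    if (doubletPairs > 0L) {
      picked <- sample(nCells, 2L * doubletPairs)
      keepBc <- picked[seq_len(doubletPairs)]
      dropBc <- picked[doubletPairs + seq_len(doubletPairs)]
      barcodes[dropBc] <- barcodes[keepBc]
    }
  }

  ## --- clean contig rows ----------------------------------------------
  perCell <- chainCount[cloneOfCell]
  cellRep <- rep.int(seq_len(nCells), perCell)
  rowIdx <- sequence(perCell) + rep.int(chainOffset[cloneOfCell], perCell)
  cc <- chains[rowIdx, , drop = FALSE]
  nContig <- nrow(cc)
  umis <- 1L + stats::rpois(nContig, 3)
  contigs <- data.frame(
    barcode = barcodes[cellRep],
    is_cell = "True",
    contig_id = paste0(barcodes[cellRep], "_contig_", sequence(perCell)),
    high_confidence = "True",
    chain = cc$locus,
    v_gene = cc$v_gene,
    d_gene = ifelse(cc$locus == "TRB",
                    sample(c("TRBD1", "TRBD2"), nContig, replace = TRUE),
                    ""),
    j_gene = cc$j_gene,
    c_gene = ifelse(cc$locus == "TRB",
                    sample(c("TRBC1", "TRBC2"), nContig, replace = TRUE),
                    "TRAC"),
    productive = "True",
    cdr3 = cc$cdr3_aa,
    cdr3_nt = cc$cdr3_nt,
    reads = umis * sample(20:60, nContig, replace = TRUE),
    umis = umis,
    stringsAsFactors = FALSE)
  labels <- rep("clean", nContig)
  ## doublets: contig ids can collide after barcode merging; re-suffix
  if (doubletPairs > 0L)
    contigs$contig_id <- paste0(contigs$barcode, "_contig_",
                                stats::ave(seq_len(nContig),
                                           contigs$barcode,
                                           FUN = seq_along))
  nClean <- nContig

  noiseRow <- function(n, barcode, chainLab, productive, isCell, highConf,
                       tag) {
    if (n == 0L) return(NULL)
    loci <- chainLab
    tra <- loci == "TRA"
    trb <- loci == "TRB"
    v <- j <- character(n)
    cdr <- .randomCdr3(n)
    if (any(tra)) {
      v[tra] <- sample(pools$TRAV$genes, sum(tra), replace = TRUE,
                       prob = pools$TRAV$weights)
      j[tra] <- sample(pools$TRAJ$genes, sum(tra), replace = TRUE,
                       prob = pools$TRAJ$weights)
    }
    if (any(trb)) {
      v[trb] <- sample(pools$TRBV$genes, sum(trb), replace = TRUE,
                       prob = pools$TRBV$weights)
      j[trb] <- sample(pools$TRBJ$genes, sum(trb), replace = TRUE,
                       prob = pools$TRBJ$weights)
    }
    other <- !(tra | trb)
    if (any(other)) {
      v[other] <- "TRGV9"
      j[other] <- "TRGJ1"
    }
    u <- 1L + stats::rpois(n, 2)
    data.frame(
      barcode = barcode, is_cell = isCell,
      contig_id = paste0(barcode, "_", tag, "_", seq_len(n)),
      high_confidence = highConf, chain = loci, v_gene = v,
      d_gene = "", j_gene = j, c_gene = "",
      productive = productive, cdr3 = cdr$aa, cdr3_nt = cdr$nt,
      reads = u * sample(20:60, n, replace = TRUE), umis = u,
      stringsAsFactors = FALSE)
  }

  noise <- config$noise
  realBc <- unique(barcodes)

  ## non-cell barcodes (fail the is_cell rule only)
  nNonCell <- round(noise$fracNonCell * nClean)
  if (nNonCell > 0L) {
    bc <- .randomBarcodes(nNonCell, avoid = realBc)
    contigs <- rbind(contigs, noiseRow(
      nNonCell, bc, sample(c("TRA", "TRB"), nNonCell, replace = TRUE),
      "True", "False", "True", "noncell"))
    labels <- c(labels, rep("noncell", nNonCell))
  }
  ## low-confidence contigs on real cells (fail high_confidence only)
  nLowConf <- round(noise$fracLowConf * nClean)
  if (nLowConf > 0L) {
    bc <- sample(realBc, nLowConf, replace = TRUE)
    contigs <- rbind(contigs, noiseRow(
      nLowConf, bc, sample(c("TRA", "TRB"), nLowConf, replace = TRUE),
      "True", "True", "False", "lowconf"))
    labels <- c(labels, rep("lowconf", nLowConf))
  }
  ## gamma/delta contigs on real cells (fail the chain rule only)
  nNonAb <- round(noise$fracGammaDelta * nClean)
  if (nNonAb > 0L) {
    bc <- sample(realBc, nNonAb, replace = TRUE)
    contigs <- rbind(contigs, noiseRow(
      nNonAb, bc, sample(c("TRG", "TRD"), nNonAb, replace = TRUE),
      "True", "True", "True", "nonab"))
    labels <- c(labels, rep("nonab", nNonAb))
  }
  ## non-productive contigs on real cells (fail the productive rule only)
  nNonProd <- round(noise$fracNonProductive * nClean)
  if (nNonProd > 0L) {
    bc <- sample(realBc, nNonProd, replace = TRUE)
    contigs <- rbind(contigs, noiseRow(
      nNonProd, bc, sample(c("TRA", "TRB"), nNonProd, replace = TRUE),
      sample(c("False", "None"), nNonProd, replace = TRUE),
      "True", "True", "nonprod"))
    labels <- c(labels, rep("nonproductive", nNonProd))
  }
  ## duplicate contigs: an existing chain emitted twice with split UMIs;
  ## absorbed by collapseChains, so ground truth is unchanged
  nDup <- round(noise$duplicateContigRate * nClean)
  if (nDup > 0L) {
    pick <- sample(nClean, nDup)
    dup <- contigs[pick, , drop = FALSE]
    u <- dup$umis
    dup$umis <- ifelse(u >= 2L, u %/% 2L, 1L)
    contigs$umis[pick] <- ifelse(u >= 2L, u - u %/% 2L, 1L)
    dup$contig_id <- paste0(dup$contig_id, "_dup")
    contigs <- rbind(contigs, dup)
    labels <- c(labels, rep("duplicate", nDup))
  }
  ## unpaired single-locus cells (removed by the paired-cell rule)
  nUnpaired <- round(noise$unpairedCellRate * config$nCells)
  if (nUnpaired > 0L) {
    bc <- .randomBarcodes(nUnpaired, avoid = contigs$barcode)
    contigs <- rbind(contigs, noiseRow(
      nUnpaired, bc, sample(c("TRA", "TRB"), nUnpaired, replace = TRUE),
      "True", "True", "True", "unpaired"))
    labels <- c(labels, rep("unpaired", nUnpaired))
  }

  ## deterministic shuffle so input order carries no signal
  ord <- sample(nrow(contigs))
  contigs <- contigs[ord, , drop = FALSE]
  labels <- labels[ord]
  rownames(contigs) <- NULL

  truthCells <- data.frame(
    sample_id = sid, barcode = barcodes,
    pairing_type = pairing[cloneOfCell],
    receptor_class = receptorClass(pairing[cloneOfCell]),
    clonotype_id = cloneOfCell, subset = subset,
    stringsAsFactors = FALSE)
  if (doubletPairs > 0L)
    truthCells$is_doublet <- barcodes %in%
      barcodes[duplicated(barcodes)]
  ## subset annotations describe barcodes (one row per barcode)
  annKeep <- !duplicated(barcodes)
  subsetsTab <- data.frame(sample_id = sid, barcode = barcodes[annKeep],
                           subset = subset[annKeep],
                           stringsAsFactors = FALSE)
  classCounts <- table(factor(pairing[cloneOfCell],
                              levels = .PAIRING_TYPES))
  list(
    contigs = contigs,
    subsets = subsetsTab,
    truth = list(
      cells = truthCells,
      clone_sizes = data.frame(clonotype_id = seq_len(nClones),
                               pairing_type = pairing,
                               receptor_class = receptorClass(pairing),
                               size = sizes,
                               stringsAsFactors = FALSE),
      class_counts = classCounts,
      noise_counts = c(noncell = nNonCell, lowconf = nLowConf,
                       nonab = nNonAb, nonproductive = nNonProd,
                       duplicate = nDup, unpaired_cells = nUnpaired,
                       doublet_pairs = doubletPairs),
      contig_labels = labels,
      config = config))
}

#' Simulate a multi-sample cohort
#'
#' Runs \code{\link{simulateSample}} for every config and optionally
#' writes one contig CSV and one subset TSV per sample plus the manifest,
#' giving a complete on-disk cohort that the pipeline can consume.
#'
#' @param configs Named list of \code{\link{simConfig}} objects; names
#'   must be unique sample ids matching the manifest.
#' @param manifest \code{data.frame} with \code{sample_id},
#'   \code{patient_id}, \code{group}.
#' @param dir Output directory (created if needed); \code{NULL} keeps the
#'   simulation in memory only.
#' @return Invisibly, a list with \code{sims} (per-sample simulation
#'   results), \code{manifest}, and \code{paths} when \code{dir} is set.
#' @export
simulateCohort <- function(configs, manifest, dir = NULL) {
  if (is.null(names(configs)) || anyDuplicated(names(configs)))
    bail("configs must be a uniquely named list of sample configs")
  if (!all(names(configs) %in% manifest$sample_id))
    bail("config sample id(s) missing from manifest: ",
         paste(setdiff(names(configs), manifest$sample_id), collapse = ", "))
  sims <- lapply(names(configs), function(sid) {
    cfg <- configs[[sid]]
    cfg$sampleId <- sid
    simulateSample(cfg)
  })
  names(sims) <- names(configs)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(contigs = character(0), subsets = character(0))
    for (sid in names(sims)) {
      fc <- file.path(dir, paste0(sid, "_contigs.csv"))
      fs <- file.path(dir, paste0(sid, "_subsets.tsv"))
      utils::write.csv(sims[[sid]]$contigs, fc, row.names = FALSE,
                       quote = FALSE)
      utils::write.table(sims[[sid]]$subsets, fs, row.names = FALSE,
                         quote = FALSE, sep = "\t")
      paths$contigs[sid] <- fc
      paths$subsets[sid] <- fs
    }
    paths$manifest <- file.path(dir, "manifest.tsv")
    utils::write.table(manifest, paths$manifest, row.names = FALSE,
                       quote = FALSE, sep = "\t")
  }
  invisible(list(sims = sims, manifest = manifest, paths = paths))
}
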