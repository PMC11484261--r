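## Contig-level QC filtering and collapse of contigs into distinct
## functional chains per cell.

#' Retain functional alpha/beta contigs
#'
#' Applies the four contig-level exclusion rules, in order: drop contigs
#' whose barcode is not a called cell (\code{is_cell = FALSE}), drop
#' low-confidence contigs (\code{high_confidence = FALSE}), drop contigs on
#' loci other than TRA/TRB (gamma/delta, \code{Multi}, \code{None}), and
#' drop non-productive contigs (\code{productive} \code{"false"} or
#' \code{"none"}). Per-rule drop counts are accumulated in
#' \code{\link{qcStats}} so that the retained count plus the drops always
#' equals the input count. The operation is idempotent.
#'
#' @param x A \code{\linkS4class{ContigSet}}.
#' @return A filtered \code{ContigSet} whose \code{qcStats} gains
#'   \code{drop_not_cell}, \code{drop_low_confidence},
#'   \code{drop_chain_not_ab}, \code{drop_not_productive} and
#'   \code{n_functional}.
#' @examples
#' sim <- simulateSample(simConfig(nCells = 100, seed = 1,
#'                                 noise = list(fracNonCell = 0.1)))
#' fc <- filterFunctionalContigs(ContigSet(sim$contigs, "S1"))
#' qcStats(fc)$drop_not_cell
#' @export
filterFunctionalContigs <- function(x) {
  stopifnot(is(x, "ContigSet"))
  df <- x@contigs
  n0 <- nrow(df)
  keep <- df$is_cell
  d_cell <- n0 - sum(keep)
  df <- df[keep, , drop = FALSE]

  keep <- df$high_confidence
  d_conf <- nrow(df) - sum(keep)
  df <- df[keep, , drop = FALSE]

  keep <- df$chain %in% c("TRA", "TRB")
  d_chain <- nrow(df) - sum(keep)
  df <- df[keep, , drop = FALSE]

  keep <- df$productive == "true"
  d_prod <- nrow(df) - sum(keep)
  df <- df[keep, , drop = FALSE]

  stats <- x@qcStats
  stats$n_input <- stats$n_input %||% n0
  stats$drop_not_cell <- (stats$drop_not_cell %||% 0L) + d_cell
  stats$drop_low_confidence <- (stats$drop_low_confidence %||% 0L) + d_conf
  stats$drop_chain_not_ab <- (stats$drop_chain_not_ab %||% 0L) + d_chain
  stats$drop_not_productive <- (stats$drop_not_productive %||% 0L) + d_prod
  stats$n_functional <- nrow(df)
  rownames(df) <- NULL
  new("ContigSet", contigs = df, qcStats = stats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## chain key under a given identity level; the key is what defines "one
## distinct functional chain".
.chainKey <- function(locus, v, j, nt, aa, level) {
  switch(level,
         nt = paste(locus, v, j, nt, sep = "|"),
         aa = paste(locus, v, j, aa, sep = "|"),
         gene = paste(locus, v, j, sep = "|"))
}

#' Collapse contigs into distinct functional chains per cell
#'
#' Groups functional-filtered contigs by (sample, barcode) and collapses
#' contigs describing the same chain into one, summing their UMIs.
#' Chain identity defaults to \code{"nt"}: locus + V gene + J gene +
#' nucleotide CDR3, which separates convergent rearrangements that share
#' V/J but differ in junction. \code{"aa"} keys on the amino-acid CDR3
#' instead, and \code{"gene"} on the V/J pair alone. The D gene is never
#' part of the key (frequently uncalled on TRA, unreliable on TRB, and
#' already encoded by the junction); the C gene is likewise ignored.
#' Contigs lacking a V gene, J gene or CDR3 after filtering cannot form a
#' chain key and are dropped with a warning, counted in
#' \code{qcStats$drop_unkeyable}.
#'
#' No UMI-dominance filtering is applied: secondary chains are the object
#' of study, and any uncited UMI threshold would bias dual-TCR calls. A
#' minimum-UMI option exists but defaults to 0.
#'
#' @param x A functional-filtered \code{\linkS4class{ContigSet}}.
#' @param chainIdentity \code{"nt"} (default), \code{"aa"} or
#'   \code{"gene"}.
#' @param minUmis Minimum summed UMIs for a collapsed chain to be kept;
#'   default 0 (keep all).
#' @return A \code{\linkS4class{CellChainSet}} with one row per cell in
#'   \code{cellData} and one row per distinct chain in \code{chainData}.
#'   Output is invariant under permutation of input rows.
#' @export
collapseChains <- function(x, chainIdentity = c("nt", "aa", "gene"),
                           minUmis = 0) {
  stopifnot(is(x, "ContigSet"))
  chainIdentity <- match.arg(chainIdentity)
  df <- x@contigs
  stats <- x@qcStats

  keyable <- nzchar(df$v_gene) & nzchar(df$j_gene) & nzchar(df$cdr3_nt)
  if (chainIdentity == "aa")
    keyable <- keyable & nzchar(df$cdr3_aa)
  n_unkeyable <- sum(!keyable)
  if (n_unkeyable > 0) {
    warning(n_unkeyable,
            " contig(s) lacked v_gene/j_gene/CDR3 and were dropped",
            call. = FALSE)
    df <- df[keyable, , drop = FALSE]
  }
  stats$drop_unkeyable <- n_unkeyable

  key <- .chainKey(df$chain, df$v_gene, df$j_gene, df$cdr3_nt, df$cdr3_aa,
                   chainIdentity)
  grp <- paste(df$sample_id, df$barcode, key, sep = "\r")
  ## collapse duplicates: sum UMIs, keep first-seen annotation fields;
  ## sort by group key so output ordering is permutation-invariant.
  ord <- order(grp, df$contig_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  grp <- grp[ord]
  first <- !duplicated(grp)
  umis <- as.integer(rowsum(as.numeric(df$umis), grp,
                            reorder = FALSE)[, 1L])
  chains <- data.frame(
    sample_id = df$sample_id[first],
    barcode = df$barcode[first],
    locus = df$chain[first],
    v_gene = df$v_gene[first],
    j_gene = df$j_gene[first],
    cdr3_nt = df$cdr3_nt[first],
    cdr3_aa = df$cdr3_aa[first],
    umis = umis,
    chain_key = .chainKey(df$chain[first], df$v_gene[first],
                          df$j_gene[first], df$cdr3_nt[first],
                          df$cdr3_aa[first], chainIdentity),
    stringsAsFactors = FALSE)
  if (minUmis > 0)
    chains <- chains[chains$umis >= minUmis, , drop = FALSE]
  rownames(chains) <- NULL

  cellgrp <- paste(chains$sample_id, chains$barcode, sep = "\r")
  ord2 <- order(cellgrp, method = "radix")
  chains <- chains[ord2, , drop = FALSE]
  cellgrp <- cellgrp[ord2]
  firstc <- !duplicated(cellgrp)
  n_alpha <- as.integer(rowsum(as.numeric(chains$locus == "TRA"), cellgrp,
                               reorder = FALSE)[, 1L])
  n_beta <- as.integer(rowsum(as.numeric(chains$locus == "TRB"), cellgrp,
                              reorder = FALSE)[, 1L])
  cells <- data.frame(
    sample_id = chains$sample_id[firstc],
    barcode = chains$barcode[firstc],
    n_alpha = n_alpha,
    n_beta = n_beta,
    stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  stats$n_barcodes_with_chains <- nrow(cells)
  new("CellChainSet", chains = chains, cells = cells,
      chainIdentity = chainIdentity, qcStats = stats)
}

#' Keep only cells with both an alpha and a beta chain
#'
#' Removes cells carrying chains from a single locus only, the final QC
#' rule. The number of retained cells is the sample's "paired TCR cells"
#' denominator against which all pairing-type proportions are computed.
#'
#' @param x A \code{\linkS4class{CellChainSet}} from
#'   \code{\link{collapseChains}}.
#' @return A \code{CellChainSet} restricted to paired cells;
#'   \code{qcStats} gains \code{n_unpaired_removed} and \code{n_paired}.
#' @export
requirePaired <- function(x) {
  stopifnot(is(x, "CellChainSet"))
  ce <- x@cells
  keep <- ce$n_alpha >= 1L & ce$n_beta >= 1L
  kept <- ce[keep, , drop = FALSE]
  keycells <- paste(kept$sample_id, kept$barcode)
  ch <- x@chains
  ch <- ch[paste(ch$sample_id, ch$barcode) %in% keycells, , drop = FALSE]
  rownames(kept) <- rownames(ch) <- NULL
  stats <- x@qcStats
  stats$n_unpaired_removed <- sum(!keep)
  stats$n_paired <- nrow(kept)
  new("CellChainSet", chains = ch, cells = kept,
      chainIdentity = x@chainIdentity, qcStats = stats)
}
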