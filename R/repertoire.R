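## Clonotype calling, clonal-expansion summaries and V/J gene-segment
## usage profiles stratified by receptor class.

#' Call clonotypes within each sample and receptor class
#'
#' Two cells belong to the same clonotype when their receptor chain sets
#' match under the chosen definition. \code{"full_set"} (default) requires
#' the entire set of distinct chain keys to be identical, so a dual cell's
#' clone must match on all three or four chains - the strictest reading of
#' clone size for dual-TCR cells and the only one that makes a dual clone
#' unambiguous. \code{"beta_only"} keys on the set of beta chains alone,
#' the convention of bulk-repertoire studies. Clonotypes are computed
#' separately within receptor classes (single vs dual) and within samples,
#' so single and dual expansion are reported independently and clone sizes
#' are never pooled across timepoints. A clonotype is flagged
#' \code{expanded} when its size is at least 2 cells.
#'
#' @param x A classified \code{\linkS4class{CellChainSet}}.
#' @param definition \code{"full_set"} or \code{"beta_only"}.
#' @return A \code{data.frame} with one row per clonotype:
#'   \code{clonotype_id}, \code{sample_id}, \code{receptor_class},
#'   \code{chain_key_set} (canonical sorted key string), \code{n_chains},
#'   \code{size}, \code{expanded}. Within each (sample, class), sizes sum
#'   to the number of cells of that class. Output is invariant under cell
#'   order permutation.
#' @examples
#' sim <- simulateSample(simConfig(nCells = 200, seed = 3,
#'                                 plantedClones = list(
#'                                   list(size = 5, pairing = "DUAL_B_A1A2"))))
#' cells <- classifyPairing(requirePaired(collapseChains(
#'   filterFunctionalContigs(ContigSet(sim$contigs, "S1")))))
#' cl <- callClonotypes(cells)
#' subset(cl, expanded)
#' @export
callClonotypes <- function(x, definition = c("full_set", "beta_only")) {
  stopifnot(is(x, "CellChainSet"))
  definition <- matchChoice(definition[1L], c("full_set", "beta_only"),
                            "clonotype definition")
  ce <- x@cells
  if (!"receptor_class" %in% names(ce))
    bail("cells are not classified; run classifyPairing() first")
  ch <- x@chains
  if (definition == "beta_only")
    ch <- ch[ch$locus == "TRB", , drop = FALSE]
  ## canonical per-cell key: sorted chain keys joined
  cellid <- paste(ch$sample_id, ch$barcode, sep = "\r")
  ord <- order(cellid, ch$chain_key, method = "radix")
  ch <- ch[ord, , drop = FALSE]
  cellid <- cellid[ord]
  keyset <- vapply(split(ch$chain_key, cellid),
                   paste, character(1L), collapse = " + ")
  ce_id <- paste(ce$sample_id, ce$barcode, sep = "\r")
  ce$keyset <- unname(keyset[ce_id])
  if (anyNA(ce$keyset))
    bail("cell(s) without chains under the chosen definition")

  grp <- paste(ce$sample_id, ce$receptor_class, ce$keyset, sep = "\r")
  tab <- table(grp)
  first <- ce[!duplicated(grp), , drop = FALSE]
  first$size <- as.integer(tab[paste(first$sample_id, first$receptor_class,
                                     first$keyset, sep = "\r")])
  ## deterministic ids: by sample, class, then decreasing size, then key
  ord2 <- order(first$sample_id, first$receptor_class, -first$size,
                first$keyset, method = "radix")
  first <- first[ord2, , drop = FALSE]
  within <- stats::ave(seq_len(nrow(first)),
                       paste(first$sample_id, first$receptor_class),
                       FUN = seq_along)
  out <- data.frame(
    clonotype_id = sprintf("%s:%s:c%04d", first$sample_id,
                           first$receptor_class, within),
    sample_id = first$sample_id,
    receptor_class = first$receptor_class,
    chain_key_set = first$keyset,
    n_chains = lengths(strsplit(first$keyset, " + ", fixed = TRUE)),
    size = first$size,
    expanded = first$size >= 2L,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-sample clonal expansion summary
#'
#' Tabulates, for each (sample, receptor class), the number of expanded
#' clonotypes (size >= 2), the number of cells they contain, the largest
#' clone size and the fraction of cells sitting in expanded clones.
#'
#' @param clonotypes Output of \code{\link{callClonotypes}}.
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{receptor_class}, \code{n_clonotypes}, \code{n_cells},
#'   \code{n_expanded}, \code{n_cells_expanded}, \code{max_clone_size},
#'   \code{frac_cells_expanded}.
#' @export
expansionSummary <- function(clonotypes) {
  need <- c("sample_id", "receptor_class", "size", "expanded")
  if (length(setdiff(need, names(clonotypes))))
    bail("not a clonotype table from callClonotypes()")
  grp <- paste(clonotypes$sample_id, clonotypes$receptor_class, sep = "\r")
  rows <- lapply(split(clonotypes, grp), function(sub) {
    data.frame(
      sample_id = sub$sample_id[1L],
      receptor_class = sub$receptor_class[1L],
      n_clonotypes = nrow(sub),
      n_cells = sum(sub$size),
      n_expanded = sum(sub$expanded),
      n_cells_expanded = sum(sub$size[sub$expanded]),
      max_clone_size = max(sub$size),
      frac_cells_expanded = sum(sub$size[sub$expanded]) / sum(sub$size),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$receptor_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' V/J gene-segment usage by receptor class
#'
#' Counts every chain (not every cell) of the requested segment family
#' within each stratum, so a dual-beta cell contributes two TRBV
#' observations - the convention that makes a dual-vs-single usage
#' comparison well defined. Frequencies are normalized within each
#' stratum and sum to 1 wherever the stratum is non-empty. Gene names are
#' compared after allele stripping but otherwise taken verbatim; no
#' nomenclature validation is attempted.
#'
#' @param x A classified \code{\linkS4class{CellChainSet}} (with a
#'   \code{group} column if \code{"group"} is among \code{by}).
#' @param family \code{"TRAV"}, \code{"TRBV"}, \code{"TRAJ"} or
#'   \code{"TRBJ"}.
#' @param by Stratification columns from \code{cellData}; default
#'   \code{"receptor_class"}, optionally plus \code{"group"} or
#'   \code{"sample_id"}.
#' @return A \code{data.frame}: one row per (gene, stratum) with
#'   \code{chain_count} and \code{frequency}.
#' @export
geneUsage <- function(x, family = c("TRAV", "TRBV", "TRAJ", "TRBJ"),
                      by = "receptor_class") {
  stopifnot(is(x, "CellChainSet"))
  family <- match.arg(family)
  ce <- x@cells
  missing <- setdiff(by, names(ce))
  if (length(missing))
    bail("stratification column(s) not on cells: ",
         paste(missing, collapse = ", "))
  locus <- substr(family, 1L, 3L)
  segment <- if (substr(family, 4L, 4L) == "V") "v_gene" else "j_gene"
  ch <- x@chains[x@chains$locus == locus, , drop = FALSE]
  idx <- match(paste(ch$sample_id, ch$barcode),
               paste(ce$sample_id, ce$barcode))
  strata <- ce[idx, by, drop = FALSE]
  keep <- stats::complete.cases(strata)
  ch <- ch[keep, , drop = FALSE]
  strata <- strata[keep, , drop = FALSE]
  if (!nrow(ch)) {
    out <- cbind(data.frame(gene = character(0)),
                 stats::setNames(
                   as.data.frame(replicate(length(by), character(0),
                                           simplify = FALSE)), by),
                 data.frame(chain_count = integer(0),
                            frequency = numeric(0)))
    return(out)
  }
  skey <- do.call(paste, c(strata, list(sep = "\r")))
  gkey <- paste(ch[[segment]], skey, sep = "\r")
  tab <- table(gkey)
  first <- !duplicated(gkey)
  out <- cbind(
    data.frame(gene = ch[[segment]][first], stringsAsFactors = FALSE),
    strata[first, , drop = FALSE])
  out$chain_count <- as.integer(tab[gkey[first]])
  total <- stats::ave(out$chain_count,
                      do.call(paste, c(out[by], list(sep = "\r"))),
                      FUN = sum)
  out$frequency <- out$chain_count / total
  ord <- do.call(order, c(out[by], list(-out$chain_count, out$gene)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
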