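## Joining externally supplied T-cell subset labels to receptor
## classifications and computing single/dual composition per subset.

#' Validate (or read) a subset annotation table
#'
#' Subset labels are an input, not something this package computes: they
#' come from transcriptome clustering and reference annotation upstream.
#' The vocabulary is fixed to the seven T-cell subsets
#' (\code{\link{subsetLevels}}); an unknown label is an error rather than
#' a pass-through, so manifest typos are caught early, as is a duplicated
#' (sample, barcode) pair.
#'
#' @param annotations A \code{data.frame} with columns \code{sample_id},
#'   \code{barcode}, \code{subset}, or (for
#'   \code{readSubsetAnnotations}) the path of a TSV with those columns.
#' @return The validated \code{data.frame}.
#' @export
validateSubsetAnnotations <- function(annotations) {
  need <- c("sample_id", "barcode", "subset")
  missing <- setdiff(need, names(annotations))
  if (length(missing))
    bail("annotation table lacks column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(annotations$subset), .SUBSET_LABELS)
  if (length(bad))
    bail("unknown subset label(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(.SUBSET_LABELS, collapse = ", "))
  key <- paste(annotations$sample_id, annotations$barcode)
  if (anyDuplicated(key))
    bail("duplicate (sample_id, barcode) in annotations: ",
         key[duplicated(key)][1L])
  annotations
}

#' @rdname validateSubsetAnnotations
#' @param path Path to a tab-separated annotation file.
#' @export
readSubsetAnnotations <- function(path) {
  if (!file.exists(path))
    bail("file not found: ", path)
  validateSubsetAnnotations(
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character"))
}

#' Join subset annotations onto classified cells
#'
#' Inner-join semantics on (sample_id, barcode), realized as a
#' \code{subset} column on \code{cellData}: annotated cells get their
#' label, unannotated cells get \code{NA} and are excluded from subset
#' analyses while remaining available to sample-level analyses. Counts of
#' unmatched records on both sides are recorded in \code{qcStats$subset_join}.
#'
#' @param x A \code{\linkS4class{CellChainSet}}.
#' @param annotations A validated annotation table (see
#'   \code{\link{validateSubsetAnnotations}}).
#' @return The set with a \code{subset} column; join bookkeeping satisfies
#'   matched + unmatched_cells = number of cells.
#' @export
joinSubsets <- function(x, annotations) {
  stopifnot(is(x, "CellChainSet"))
  annotations <- validateSubsetAnnotations(annotations)
  ce <- x@cells
  akey <- paste(annotations$sample_id, annotations$barcode)
  ckey <- paste(ce$sample_id, ce$barcode)
  idx <- match(ckey, akey)
  ce$subset <- as.character(annotations$subset)[idx]
  stats <- x@qcStats
  stats$subset_join <- list(
    n_cells = nrow(ce),
    n_matched = sum(!is.na(idx)),
    n_unmatched_cells = sum(is.na(idx)),
    n_unmatched_annotations = sum(!akey %in% ckey))
  initialize(x, cells = ce, qcStats = stats)
}

#' Single/dual composition of each T-cell subset
#'
#' Tabulates, within each (group, subset) stratum, the cells of each
#' receptor class (or each of the five pairing types) and their
#' percentage of the stratum's paired cells; unrounded percentages sum to
#' 100 within every non-empty stratum. \code{margin = "class"} gives the
#' transposed view - for each (group, class), the distribution over
#' subsets - which answers where dual-TCR cells originate (e.g. whether
#' they come mainly from the Treg compartment).
#'
#' @param x A classified, subset-annotated (and, if \code{"group"} is
#'   used, group-labelled) \code{\linkS4class{CellChainSet}}. Cells
#'   without a subset label are excluded.
#' @param by \code{"receptor_class"} (default) or \code{"pairing_type"}.
#' @param margin \code{"subset"} (default; percentages within each
#'   (group, subset)) or \code{"class"} (percentages within each
#'   (group, class) across subsets).
#' @return A \code{data.frame}: \code{group}, \code{subset}, class column,
#'   \code{cell_count}, \code{percent}. Empty strata yield zero-count
#'   rows with \code{percent = NA}.
#' @export
subsetComposition <- function(x, by = c("receptor_class", "pairing_type"),
                              margin = c("subset", "class")) {
  stopifnot(is(x, "CellChainSet"))
  by <- match.arg(by)
  margin <- match.arg(margin)
  ce <- x@cells
  if (!"subset" %in% names(ce))
    bail("cells carry no subset labels; run joinSubsets() first")
  if (!by %in% names(ce))
    bail("cells are not classified; run classifyPairing() first")
  if (!"group" %in% names(ce))
    ce$group <- "all"
  ce <- ce[!is.na(ce$subset) & !is.na(ce$group), , drop = FALSE]
  levelsBy <- if (by == "receptor_class") c("single", "dual")
  else .PAIRING_TYPES
  tab <- as.data.frame(table(
    group = ce$group,
    subset = factor(ce$subset, levels = .SUBSET_LABELS),
    class = factor(ce[[by]], levels = levelsBy)),
    stringsAsFactors = FALSE)
  names(tab)[3:4] <- c(by, "cell_count")
  denomKey <- if (margin == "subset")
    paste(tab$group, tab$subset) else paste(tab$group, tab[[by]])
  denom <- stats::ave(tab$cell_count, denomKey, FUN = sum)
  tab$percent <- ifelse(denom > 0, 100 * tab$cell_count / denom, NA_real_)
  tab <- tab[order(tab$group, tab$subset, tab[[by]]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
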