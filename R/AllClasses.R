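#' @import methods
NULL

## Controlled vocabularies used throughout the package.
.PAIRING_TYPES <- c("SINGLE_AB", "DUAL_A_B1B2", "DUAL_B_A1A2",
                    "DUAL_A1A2B1B2", "OTHERS")
.DUAL_TYPES <- .PAIRING_TYPES[-1L]
.SUBSET_LABELS <- c("naive_cd4", "naive_cd8", "cd4_cm", "cd8_cm",
                    "cd4_em", "cd8_em", "treg")
.GROUP_LABELS <- c("pre_ivig", "post_ivig", "control")
.CHAIN_IDENTITY_LEVELS <- c("nt", "aa", "gene")

.CONTIG_COLUMNS <- c("barcode", "contig_id", "is_cell", "high_confidence",
                     "chain", "v_gene", "d_gene", "j_gene", "c_gene",
                     "cdr3_aa", "cdr3_nt", "productive", "umis", "reads",
                     "sample_id")

#' Pairing-type and subset vocabularies
#'
#' The five-class receptor pairing taxonomy partitions every paired
#' alpha/beta T cell: \code{SINGLE_AB} (one alpha + one beta chain),
#' \code{DUAL_A_B1B2} (one alpha + two beta), \code{DUAL_B_A1A2} (one beta +
#' two alpha), \code{DUAL_A1A2B1B2} (two of each) and \code{OTHERS} (any
#' residual multi-chain combination, e.g. three alpha chains). The seven
#' subset labels are the T-cell subpopulations used for composition
#' analyses: naive CD4/CD8, CD4/CD8 central memory, CD4/CD8 effector memory
#' and regulatory T cells.
#'
#' @return A character vector of level names, in canonical order.
#' @examples
#' pairingLevels()
#' subsetLevels()
#' @export
pairingLevels <- function() .PAIRING_TYPES

#' @rdname pairingLevels
#' @export
subsetLevels <- function() .SUBSET_LABELS

#' ContigSet: a normalized table of V(D)J contig annotations
#'
#' A \code{ContigSet} holds one row per assembled V(D)J contig, normalized
#' from either the 10x Genomics \code{filtered_contig_annotations.csv}
#' dialect or an AIRR rearrangement TSV. Boolean flags are stored as
#' logicals, \code{productive} as the tri-state character
#' \code{"true"/"false"/"none"}, and gene calls with allele suffixes
#' (\code{"*01"}) stripped. The \code{qcStats} slot accumulates per-rule
#' counts as filtering operations are applied.
#'
#' @slot contigs A \code{data.frame} with the columns \code{barcode},
#'   \code{contig_id}, \code{is_cell}, \code{high_confidence}, \code{chain},
#'   \code{v_gene}, \code{d_gene}, \code{j_gene}, \code{c_gene},
#'   \code{cdr3_aa}, \code{cdr3_nt}, \code{productive}, \code{umis},
#'   \code{reads}, \code{sample_id}.
#' @slot qcStats A named list of bookkeeping counts (see
#'   \code{\link{filterFunctionalContigs}}).
#'
#' @seealso \code{\link{readContigs}}, \code{\link{filterFunctionalContigs}}
#' @export
setClass("ContigSet",
         representation(contigs = "data.frame", qcStats = "list"),
         prototype(qcStats = list()))

setValidity("ContigSet", function(object) {
  df <- object@contigs
  missing <- setdiff(.CONTIG_COLUMNS, names(df))
  if (length(missing))
    return(paste0("missing contig column(s): ",
                  paste(missing, collapse = ", ")))
  if (nrow(df) == 0L)
    return(TRUE)
  if (!is.logical(df$is_cell) || !is.logical(df$high_confidence))
    return("is_cell and high_confidence must be logical")
  if (!all(df$productive %in% c("true", "false", "none")))
    return("productive must be one of 'true', 'false', 'none'")
  if (any(!nzchar(df$barcode)) || any(!nzchar(df$contig_id)))
    return("barcode and contig_id must be non-empty")
  if (any(df$umis < 0) || any(df$reads < 0))
    return("umis and reads must be non-negative")
  key <- paste(df$sample_id, df$contig_id)
  if (anyDuplicated(key))
    return("contig_id must be unique within a sample")
  TRUE
})

#' CellChainSet: distinct functional TCR chains per cell
#'
#' A \code{CellChainSet} is the per-barcode view produced by
#' \code{\link{collapseChains}}: for every cell, the set of distinct
#' functional alpha (TRA) and beta (TRB) chains that survived QC. Chain
#' identity is configurable: \code{"nt"} (locus + V + J + nucleotide CDR3,
#' the default), \code{"aa"} (amino-acid CDR3) or \code{"gene"} (V + J
#' only). Optional per-cell annotation columns (\code{pairing_type},
#' \code{group}, \code{subset}) are filled in by
#' \code{\link{classifyPairing}}, \code{\link{assignGroups}} and
#' \code{\link{joinSubsets}}.
#'
#' @slot chains A \code{data.frame} with one row per distinct chain:
#'   \code{sample_id}, \code{barcode}, \code{locus}, \code{v_gene},
#'   \code{j_gene}, \code{cdr3_nt}, \code{cdr3_aa}, \code{umis},
#'   \code{chain_key}.
#' @slot cells A \code{data.frame} with one row per cell: \code{sample_id},
#'   \code{barcode}, \code{n_alpha}, \code{n_beta}, and optionally
#'   \code{pairing_type}, \code{group}, \code{subset}.
#' @slot chainIdentity The chain-identity level used to build the set.
#' @slot qcStats A named list of bookkeeping counts carried through the
#'   pipeline.
#'
#' @seealso \code{\link{collapseChains}}, \code{\link{requirePaired}},
#'   \code{\link{classifyPairing}}
#' @export
setClass("CellChainSet",
         representation(chains = "data.frame", cells = "data.frame",
                        chainIdentity = "character", qcStats = "list"),
         prototype(chainIdentity = "nt", qcStats = list()))

setValidity("CellChainSet", function(object) {
  ch <- object@chains
  ce <- object@cells
  need_ch <- c("sample_id", "barcode", "locus", "v_gene", "j_gene",
               "cdr3_nt", "cdr3_aa", "umis", "chain_key")
  need_ce <- c("sample_id", "barcode", "n_alpha", "n_beta")
  if (length(setdiff(need_ch, names(ch))))
    return("chains table lacks required columns")
  if (length(setdiff(need_ce, names(ce))))
    return("cells table lacks required columns")
  if (!object@chainIdentity %in% .CHAIN_IDENTITY_LEVELS)
    return("chainIdentity must be one of 'nt', 'aa', 'gene'")
  if (nrow(ch) && !all(ch$locus %in% c("TRA", "TRB")))
    return("chain locus must be TRA or TRB")
  if (nrow(ch) &&
      anyDuplicated(paste(ch$sample_id, ch$barcode, ch$chain_key)))
    return("duplicate chain keys within a cell")
  if (nrow(ce) && any(ce$n_alpha + ce$n_beta < 1L))
    return("every cell must carry at least one chain")
  if ("pairing_type" %in% names(ce)) {
    pt <- ce$pairing_type
    if (!all(is.na(pt) | pt %in% .PAIRING_TYPES))
      return("invalid pairing_type value")
  }
  TRUE
})

#' TCRTestResult: the outcome of a group comparison
#'
#' Container for the statistics computed by \code{\link{independentT}},
#' \code{\link{pairedT}}, \code{\link{chiSquareTest}} and
#' \code{\link{anovaOneway}}: the test statistic, its degrees of freedom
#' (one value, or two for an F test), the two-sided p-value and a summary
#' of the per-group inputs (n/mean/sd, or the contingency counts).
#'
#' @slot testName One of \code{"independent_t"}, \code{"paired_t"},
#'   \code{"chi_square"}, \code{"anova_oneway"}.
#' @slot statistic The test statistic (t, chi-square or F).
#' @slot df Degrees of freedom; length 2 for the F test.
#' @slot pValue Two-sided p-value in [0, 1].
#' @slot groupSummaries A \code{data.frame} of per-group summaries, or the
#'   contingency table as a data.frame for the chi-square test.
#' @export
setClass("TCRTestResult",
         representation(testName = "character", statistic = "numeric",
                        df = "numeric", pValue = "numeric",
                        groupSummaries = "data.frame"))

setValidity("TCRTestResult", function(object) {
  if (length(object@pValue) != 1L ||
      is.na(object@pValue) ||
      object@pValue < 0 || object@pValue > 1)
    return("pValue must be a single value in [0, 1]")
  if (any(object@df <= 0))
    return("degrees of freedom must be positive")
  TRUE
})
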