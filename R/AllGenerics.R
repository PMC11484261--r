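#' Accessors for dualTCR containers
#'
#' \code{contigData} returns the normalized contig table of a
#' \code{\linkS4class{ContigSet}}; \code{chainData} and \code{cellData}
#' return the per-chain and per-cell tables of a
#' \code{\linkS4class{CellChainSet}}; \code{chainIdentity} returns the
#' chain-identity level; \code{qcStats} returns the accumulated QC
#' bookkeeping counts of either container.
#'
#' @param x A \code{ContigSet} or \code{CellChainSet}.
#' @return A \code{data.frame} (tables), character scalar
#'   (\code{chainIdentity}) or named list (\code{qcStats}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contigData", function(x) standardGeneric("contigData"))

#' @rdname accessors
#' @export
setGeneric("chainData", function(x) standardGeneric("chainData"))

#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname accessors
#' @export
setGeneric("chainIdentity", function(x) standardGeneric("chainIdentity"))

#' @rdname accessors
#' @export
setGeneric("qcStats", function(x) standardGeneric("qcStats"))

#' @rdname accessors
#' @export
setMethod("contigData", "ContigSet", function(x) x@contigs)

#' @rdname accessors
#' @export
setMethod("chainData", "CellChainSet", function(x) x@chains)

#' @rdname accessors
#' @export
setMethod("cellData", "CellChainSet", function(x) x@cells)

#' @rdname accessors
#' @export
setMethod("chainIdentity", "CellChainSet", function(x) x@chainIdentity)

#' @rdname accessors
#' @export
setMethod("qcStats", "ContigSet", function(x) x@qcStats)

#' @rdname accessors
#' @export
setMethod("qcStats", "CellChainSet", function(x) x@qcStats)

setMethod("show", "ContigSet", function(object) {
  df <- object@contigs
  cat("ContigSet with", nrow(df), "contigs from",
      length(unique(df$sample_id)), "sample(s)\n")
  if (nrow(df)) {
    cat("  chains:",
        paste(names(table(df$chain)), table(df$chain),
              sep = ":", collapse = " "), "\n")
    cat("  barcodes:", length(unique(paste(df$sample_id, df$barcode))), "\n")
  }
  if (length(object@qcStats))
    cat("  qcStats:", paste(names(object@qcStats), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "CellChainSet", function(object) {
  ce <- object@cells
  cat("CellChainSet with", nrow(ce), "cells and", nrow(object@chains),
      "distinct chains (identity:", object@chainIdentity, ")\n")
  if (nrow(ce)) {
    paired <- sum(ce$n_alpha >= 1L & ce$n_beta >= 1L)
    cat("  paired (>=1 alpha and >=1 beta):", paired, "\n")
    if ("pairing_type" %in% names(ce) && !all(is.na(ce$pairing_type))) {
      tab <- table(factor(ce$pairing_type, levels = .PAIRING_TYPES))
      cat("  pairing:", paste(names(tab), tab, sep = ":", collapse = " "),
          "\n")
    }
  }
  invisible(NULL)
})

setMethod("show", "TCRTestResult", function(object) {
  cat(object@testName, ": statistic = ",
      format(object@statistic, digits = 6),
      ", df = ", paste(format(object@df, digits = 6), collapse = ", "),
      ", p = ", format(object@pValue, digits = 4), "\n", sep = "")
  invisible(NULL)
})
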