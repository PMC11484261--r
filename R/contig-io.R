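## Reading/writing contig annotation tables in the 10x CSV dialect and the
## AIRR rearrangement TSV dialect, normalized into a ContigSet.

.TENX_REQUIRED <- c("barcode", "is_cell", "high_confidence", "chain",
                    "v_gene", "j_gene", "cdr3_nt", "productive", "umis")
.AIRR_REQUIRED <- c("cell_id", "locus", "v_call", "j_call", "junction",
                    "productive", "duplicate_count")

## Accepted spellings for flag columns; 10x has emitted all of these
## across cellranger versions.
.parseFlag <- function(x, column) {
  x <- as.character(x)
  out <- rep(NA, length(x))
  out[x %in% c("True", "TRUE", "true", "T")] <- TRUE
  out[x %in% c("False", "FALSE", "false", "F")] <- FALSE
  if (anyNA(out)) {
    row <- which(is.na(out))[1L]
    bail("unreadable value '", x[row], "' in column '", column,
         "' at row ", row)
  }
  out
}

## productive is tri-state: vendor pipelines write "None" (and variants)
## for contigs where productivity could not be called.
.parseProductive <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "none"
  out <- rep(NA_character_, length(x))
  out[x %in% c("True", "TRUE", "true", "T")] <- "true"
  out[x %in% c("False", "FALSE", "false", "F")] <- "false"
  out[x %in% c("None", "Non", "NA", "", "none")] <- "none"
  if (anyNA(out)) {
    row <- which(is.na(out))[1L]
    bail("unreadable value '", x[row], "' in column 'productive' at row ",
         row)
  }
  out
}

.parseCount <- function(x, column) {
  out <- suppressWarnings(as.integer(x))
  out[is.na(out)] <- 0L
  if (any(out < 0)) {
    row <- which(out < 0)[1L]
    bail("negative value in column '", column, "' at row ", row)
  }
  out
}

.chr <- function(df, col, default = "") {
  if (col %in% names(df)) {
    x <- as.character(df[[col]])
    x[is.na(x)] <- default
    x
  } else {
    rep(default, nrow(df))
  }
}

.checkColumns <- function(df, required, dialect) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    bail("input lacks required ", dialect, " column(s): ",
         paste(missing, collapse = ", "))
}

.normalizeTenx <- function(df, sampleId) {
  .checkColumns(df, .TENX_REQUIRED, "tenx_csv")
  n <- nrow(df)
  contig_id <- .chr(df, "contig_id")
  if (n > 0L && all(!nzchar(contig_id)))
    contig_id <- paste0(.chr(df, "barcode"), "_contig_", seq_len(n))
  data.frame(
    barcode = .chr(df, "barcode"),
    contig_id = contig_id,
    is_cell = .parseFlag(df$is_cell, "is_cell"),
    high_confidence = .parseFlag(df$high_confidence, "high_confidence"),
    chain = .chr(df, "chain", default = "None"),
    v_gene = stripAllele(.chr(df, "v_gene")),
    d_gene = stripAllele(.chr(df, "d_gene")),
    j_gene = stripAllele(.chr(df, "j_gene")),
    c_gene = stripAllele(.chr(df, "c_gene")),
    cdr3_aa = .chr(df, "cdr3"),
    cdr3_nt = .chr(df, "cdr3_nt"),
    productive = .parseProductive(df$productive),
    umis = .parseCount(df$umis, "umis"),
    reads = .parseCount(if ("reads" %in% names(df)) df$reads
                        else rep(0L, n), "reads"),
    sample_id = rep(sampleId, n),
    stringsAsFactors = FALSE)
}

.normalizeAirr <- function(df, sampleId) {
  .checkColumns(df, .AIRR_REQUIRED, "airr_tsv")
  n <- nrow(df)
  contig_id <- .chr(df, "sequence_id")
  if (n > 0L && all(!nzchar(contig_id)))
    contig_id <- paste0(.chr(df, "cell_id"), "_contig_", seq_len(n))
  ## is_cell / high_confidence are not part of the AIRR rearrangement
  ## schema; default to TRUE so AIRR inputs pass those QC rules untouched.
  is_cell <- if ("is_cell" %in% names(df))
    .parseFlag(df$is_cell, "is_cell") else rep(TRUE, n)
  high_conf <- if ("high_confidence" %in% names(df))
    .parseFlag(df$high_confidence, "high_confidence") else rep(TRUE, n)
  data.frame(
    barcode = .chr(df, "cell_id"),
    contig_id = contig_id,
    is_cell = is_cell,
    high_confidence = high_conf,
    chain = .chr(df, "locus", default = "None"),
    v_gene = stripAllele(.chr(df, "v_call")),
    d_gene = stripAllele(.chr(df, "d_call")),
    j_gene = stripAllele(.chr(df, "j_call")),
    c_gene = stripAllele(.chr(df, "c_call")),
    cdr3_aa = .chr(df, "junction_aa"),
    cdr3_nt = .chr(df, "junction"),
    productive = .parseProductive(df$productive),
    umis = .parseCount(df$duplicate_count, "duplicate_count"),
    reads = .parseCount(if ("consensus_count" %in% names(df))
      df$consensus_count else rep(0L, n), "consensus_count"),
    sample_id = rep(sampleId, n),
    stringsAsFactors = FALSE)
}

#' Construct a ContigSet from an in-memory annotation table
#'
#' Normalizes a raw contig annotation \code{data.frame} (as produced by
#' \code{\link{simulateSample}} or read from disk by other means) into a
#' validated \code{\linkS4class{ContigSet}}. Boolean flags are parsed
#' case-insensitively, \code{productive} is mapped to the tri-state
#' \code{"true"/"false"/"none"} (vendor spellings \code{"None"},
#' \code{"Non"}, \code{"NA"} and empty all map to \code{"none"}), and
#' allele suffixes (\code{"*01"}) are stripped from all gene calls, since
#' gene-level identity is what downstream usage profiles report.
#'
#' @param table A \code{data.frame} in the 10x
#'   \code{filtered_contig_annotations.csv} column layout or the AIRR
#'   rearrangement layout.
#' @param sampleId Sample identifier injected into every record. Sample
#'   identity is supplied by the caller, never inferred from barcode
#'   suffixes, because per-sample files carry no sample column.
#' @param dialect \code{"tenx_csv"} or \code{"airr_tsv"}.
#' @return A \code{\linkS4class{ContigSet}}.
#' @seealso \code{\link{readContigs}} to read from a file.
#' @export
ContigSet <- function(table, sampleId, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!is.character(sampleId) || length(sampleId) != 1L || !nzchar(sampleId))
    bail("sampleId must be a non-empty string")
  df <- switch(dialect,
               tenx_csv = .normalizeTenx(table, sampleId),
               airr_tsv = .normalizeAirr(table, sampleId))
  new("ContigSet", contigs = df,
      qcStats = list(n_input = nrow(df)))
}

#' Read a contig annotation file
#'
#' Reads single-cell V(D)J contig annotations from disk into a
#' \code{\linkS4class{ContigSet}}. Two dialects are supported: the 10x
#' Genomics \code{filtered_contig_annotations.csv} layout
#' (comma-separated) and the AIRR Community rearrangement TSV
#' (tab-separated, with \code{cell_id}/\code{locus}/\code{v_call}/
#' \code{junction}/\code{duplicate_count} mapped onto the common schema;
#' \code{is_cell} and \code{high_confidence} default to \code{TRUE} when the
#' dialect lacks them). Extra columns are tolerated; a missing required
#' column raises an error naming it. Parsing is order-preserving and
#' deterministic.
#'
#' @param path Path to the annotation file.
#' @param sampleId Sample identifier injected into every record.
#' @param dialect \code{"tenx_csv"} or \code{"airr_tsv"}.
#' @return A \code{\linkS4class{ContigSet}}.
#' @examples
#' sim <- simulateSample(simConfig(nCells = 50, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write.csv(sim$contigs, f, row.names = FALSE)
#' cs <- readContigs(f, sampleId = "S1")
#' cs
#' @export
readContigs <- function(path, sampleId,
                        dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    bail("file not found: ", path)
  df <- switch(dialect,
               tenx_csv = utils::read.csv(path, stringsAsFactors = FALSE,
                                          check.names = FALSE,
                                          colClasses = "character"),
               airr_tsv = utils::read.delim(path, stringsAsFactors = FALSE,
                                            check.names = FALSE,
                                            colClasses = "character"))
  ContigSet(df, sampleId = sampleId, dialect = dialect)
}

## Field support per dialect, used by writeContigs and documented for the
## cross-dialect round trip: AIRR output does not carry is_cell or
## high_confidence (they are re-defaulted to TRUE on read), and neither
## dialect serializes sample_id (re-injected by the caller on read).
.DIALECT_FIELDS <- list(
  tenx_csv = setdiff(.CONTIG_COLUMNS, "sample_id"),
  airr_tsv = setdiff(.CONTIG_COLUMNS,
                     c("sample_id", "is_cell", "high_confidence")))

#' Write a ContigSet to disk
#'
#' Serializes a \code{\linkS4class{ContigSet}} back into the 10x CSV or
#' AIRR TSV dialect. Reading the file back with \code{\link{readContigs}}
#' (using the same \code{sampleId}) reproduces the records field-for-field
#' on the dialect's supported fields: the 10x dialect carries every field
#' except \code{sample_id}; the AIRR dialect additionally drops
#' \code{is_cell} and \code{high_confidence}, which default back to
#' \code{TRUE} on read. An empty set writes a valid header-only file.
#'
#' @param x A \code{ContigSet}.
#' @param path Output file path.
#' @param dialect \code{"tenx_csv"} or \code{"airr_tsv"}.
#' @return Invisibly, the set of field names preserved by the dialect.
#' @export
writeContigs <- function(x, path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(is(x, "ContigSet"))
  df <- x@contigs
  flag <- function(v) ifelse(v, "True", "False")
  prod10x <- c(true = "True", false = "False", none = "None")
  if (dialect == "tenx_csv") {
    out <- data.frame(
      barcode = df$barcode, is_cell = flag(df$is_cell),
      contig_id = df$contig_id, high_confidence = flag(df$high_confidence),
      chain = df$chain, v_gene = df$v_gene, d_gene = df$d_gene,
      j_gene = df$j_gene, c_gene = df$c_gene,
      productive = unname(prod10x[df$productive]),
      cdr3 = df$cdr3_aa, cdr3_nt = df$cdr3_nt,
      reads = df$reads, umis = df$umis,
      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    prodAirr <- c(true = "T", false = "F", none = "")
    out <- data.frame(
      cell_id = df$barcode, sequence_id = df$contig_id,
      locus = df$chain, v_call = df$v_gene, d_call = df$d_gene,
      j_call = df$j_gene, c_call = df$c_gene,
      junction = df$cdr3_nt, junction_aa = df$cdr3_aa,
      productive = unname(prodAirr[df$productive]),
      duplicate_count = df$umis, consensus_count = df$reads,
      stringsAsFactors = FALSE)
    utils::write.table(out, path, row.names = FALSE, quote = FALSE,
                       sep = "\t")
  }
  invisible(.DIALECT_FIELDS[[dialect]])
}
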