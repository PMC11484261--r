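## Pairing-type classification and per-sample / per-group summaries.

#' Classify a paired cell by its chain multiplicities
#'
#' The pairing type is a pure function of the number of distinct alpha
#' chains \code{a} and beta chains \code{b} in a paired cell:
#' (1,1) \code{SINGLE_AB}; (1,2) \code{DUAL_A_B1B2}; (2,1)
#' \code{DUAL_B_A1A2}; (2,2) \code{DUAL_A1A2B1B2}; any other combination
#' with \code{a >= 1, b >= 1} (i.e. three or more chains at one locus)
#' \code{OTHERS}. The five classes partition all paired cells; the four
#' dual classes plus \code{OTHERS} together form the dual-TCR total.
#'
#' @param nAlpha,nBeta Integer vectors of distinct chain counts
#'   (recycled to common length).
#' @return Character vector of pairing types.
#' @examples
#' pairingType(c(1, 1, 2, 2, 3), c(1, 2, 1, 2, 1))
#' @export
pairingType <- function(nAlpha, nBeta) {
  n <- max(length(nAlpha), length(nBeta))
  a <- rep_len(as.integer(nAlpha), n)
  b <- rep_len(as.integer(nBeta), n)
  if (any(a < 1L | b < 1L))
    bail("pairingType is defined only for paired cells (>=1 alpha and ",
         ">=1 beta chain)")
  out <- rep("OTHERS", n)
  out[a == 1L & b == 1L] <- "SINGLE_AB"
  out[a == 1L & b == 2L] <- "DUAL_A_B1B2"
  out[a == 2L & b == 1L] <- "DUAL_B_A1A2"
  out[a == 2L & b == 2L] <- "DUAL_A1A2B1B2"
  out
}

#' Receptor class (single vs dual) of a pairing type
#'
#' @param pairing Character vector of pairing types.
#' @return \code{"single"} for \code{SINGLE_AB}, \code{"dual"} for all
#'   other classes (including \code{OTHERS}, which is counted inside the
#'   dual total because only that convention balances the published
#'   per-sample count tables).
#' @export
receptorClass <- function(pairing) {
  bad <- setdiff(unique(pairing), .PAIRING_TYPES)
  if (length(bad))
    bail("unknown pairing type(s): ", paste(bad, collapse = ", "))
  ifelse(pairing == "SINGLE_AB", "single", "dual")
}

#' Assign pairing types to all cells of a CellChainSet
#'
#' Adds a \code{pairing_type} column to \code{\link{cellData}}. All cells
#' must be paired (run \code{\link{requirePaired}} first); an unpaired
#' cell is a contract violation and raises an error.
#'
#' @param x A paired \code{\linkS4class{CellChainSet}}.
#' @return The same set with \code{pairing_type} (and its derived
#'   \code{receptor_class}) filled in.
#' @export
classifyPairing <- function(x) {
  stopifnot(is(x, "CellChainSet"))
  ce <- x@cells
  if (nrow(ce) && any(ce$n_alpha < 1L | ce$n_beta < 1L))
    bail("classifyPairing requires paired cells; run requirePaired() first")
  ce$pairing_type <- if (nrow(ce))
    pairingType(ce$n_alpha, ce$n_beta) else character(0)
  ce$receptor_class <- if (nrow(ce))
    receptorClass(ce$pairing_type) else character(0)
  initialize(x, cells = ce)
}

.summaryRow <- function(sample_id, group, counts) {
  counts <- unlist(counts)
  n_single <- counts[["SINGLE_AB"]]
  n_dual <- sum(counts[.DUAL_TYPES])
  n_paired <- n_single + n_dual
  if (n_paired == 0L)
    bail("empty sample '", sample_id, "': no paired cells, proportions ",
         "are undefined")
  pct <- function(k) roundHalfUp(100 * k / n_paired, 2L)
  data.frame(
    sample_id = sample_id, group = group,
    n_paired = n_paired, n_single = n_single, n_dual_total = n_dual,
    n_dual_a_b1b2 = counts[["DUAL_A_B1B2"]],
    n_dual_b_a1a2 = counts[["DUAL_B_A1A2"]],
    n_dual_a1a2b1b2 = counts[["DUAL_A1A2B1B2"]],
    n_others = counts[["OTHERS"]],
    pct_single = pct(n_single), pct_dual_total = pct(n_dual),
    pct_dual_a_b1b2 = pct(counts[["DUAL_A_B1B2"]]),
    pct_dual_b_a1a2 = pct(counts[["DUAL_B_A1A2"]]),
    pct_dual_a1a2b1b2 = pct(counts[["DUAL_A1A2B1B2"]]),
    pct_others = pct(counts[["OTHERS"]]),
    stringsAsFactors = FALSE)
}

#' Summarize pairing-type composition of one sample
#'
#' Counts cells of each pairing type and expresses each count as a
#' percentage of the paired-cell denominator. Percentages are rounded
#' half-up to 2 decimals for display; every statistical computation in the
#' package consumes the underlying counts, never the rounded values. The
#' count invariants (single + dual = paired; the four dual subtypes sum to
#' the dual total) hold by construction.
#'
#' @param x A classified single-sample \code{\linkS4class{CellChainSet}}.
#' @param group Optional group label attached to the summary row.
#' @return A one-row \code{data.frame} with counts \code{n_*} and display
#'   percentages \code{pct_*}.
#' @seealso \code{\link{summarizeSamples}} for multi-sample sets,
#'   \code{\link{summaryFromCounts}} to build summaries from published
#'   count tables.
#' @export
summarizeSample <- function(x, group = NA_character_) {
  stopifnot(is(x, "CellChainSet"))
  ce <- x@cells
  if (!"pairing_type" %in% names(ce))
    bail("cells are not classified; run classifyPairing() first")
  sid <- unique(ce$sample_id)
  if (length(sid) != 1L)
    bail("summarizeSample expects exactly one sample; got ",
         length(sid), " (use summarizeSamples)")
  counts <- table(factor(ce$pairing_type, levels = .PAIRING_TYPES))
  .summaryRow(sid, group, as.list(counts))
}

#' Summarize pairing-type composition per sample
#'
#' @param x A classified \code{\linkS4class{CellChainSet}}, possibly
#'   spanning several samples.
#' @param manifest Optional sample manifest \code{data.frame} with columns
#'   \code{sample_id} and \code{group} used to label the rows.
#' @return A \code{data.frame} with one row per sample, as produced by
#'   \code{\link{summarizeSample}}.
#' @export
summarizeSamples <- function(x, manifest = NULL) {
  stopifnot(is(x, "CellChainSet"))
  ce <- x@cells
  if (!"pairing_type" %in% names(ce))
    bail("cells are not classified; run classifyPairing() first")
  sids <- unique(ce$sample_id)
  rows <- lapply(sids, function(sid) {
    sub <- ce[ce$sample_id == sid, , drop = FALSE]
    grp <- NA_character_
    if (!is.null(manifest)) {
      hit <- manifest$group[manifest$sample_id == sid]
      if (length(hit) == 1L) grp <- as.character(hit)
    }
    counts <- table(factor(sub$pairing_type, levels = .PAIRING_TYPES))
    .summaryRow(sid, grp, as.list(counts))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build sample summaries from a table of pairing counts
#'
#' Recomputes proportions from per-sample class counts, e.g. a published
#' per-sample count table such as \code{\link{kdCohortCounts}}. Input
#' counts are validated against the partition invariants before any
#' proportion is computed: the four dual subtype counts must sum to the
#' dual total, and single + dual must equal the paired total.
#'
#' @param counts A \code{data.frame} with columns \code{sample_id},
#'   \code{n_single}, \code{n_dual_a_b1b2}, \code{n_dual_b_a1a2},
#'   \code{n_dual_a1a2b1b2}, \code{n_others}, and optionally
#'   \code{group}, \code{n_paired} and \code{n_dual_total} (validated when
#'   present, derived otherwise).
#' @return A summary \code{data.frame} in the layout of
#'   \code{\link{summarizeSamples}}.
#' @examples
#' smry <- summaryFromCounts(kdCohortCounts())
#' smry[, c("sample_id", "pct_single", "pct_dual_total")]
#' @export
summaryFromCounts <- function(counts) {
  need <- c("sample_id", "n_single", "n_dual_a_b1b2", "n_dual_b_a1a2",
            "n_dual_a1a2b1b2", "n_others")
  missing <- setdiff(need, names(counts))
  if (length(missing))
    bail("counts table lacks column(s): ", paste(missing, collapse = ", "))
  dual <- counts$n_dual_a_b1b2 + counts$n_dual_b_a1a2 +
    counts$n_dual_a1a2b1b2 + counts$n_others
  if ("n_dual_total" %in% names(counts) &&
      any(counts$n_dual_total != dual))
    bail("dual subtype counts do not sum to n_dual_total for sample(s): ",
         paste(counts$sample_id[counts$n_dual_total != dual],
               collapse = ", "))
  paired <- counts$n_single + dual
  if ("n_paired" %in% names(counts) && any(counts$n_paired != paired))
    bail("n_single + dual total does not equal n_paired for sample(s): ",
         paste(counts$sample_id[counts$n_paired != paired],
               collapse = ", "))
  grp <- if ("group" %in% names(counts))
    as.character(counts$group) else rep(NA_character_, nrow(counts))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    .summaryRow(as.character(counts$sample_id[i]), grp[i], list(
      SINGLE_AB = counts$n_single[i],
      DUAL_A_B1B2 = counts$n_dual_a_b1b2[i],
      DUAL_B_A1A2 = counts$n_dual_b_a1a2[i],
      DUAL_A1A2B1B2 = counts$n_dual_a1a2b1b2[i],
      OTHERS = counts$n_others[i]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Unrounded percentage columns recomputed from the counts of a summary
## table; statistics consume these, never the display-rounded pct_*.
.unroundedPct <- function(smry) {
  p <- function(k) 100 * smry[[k]] / smry$n_paired
  data.frame(sample_id = smry$sample_id, group = smry$group,
             pct_single = p("n_single"),
             pct_dual_total = p("n_dual_total"),
             pct_dual_a_b1b2 = p("n_dual_a_b1b2"),
             pct_dual_b_a1a2 = p("n_dual_b_a1a2"),
             pct_dual_a1a2b1b2 = p("n_dual_a1a2b1b2"),
             pct_others = p("n_others"),
             stringsAsFactors = FALSE)
}

#' Aggregate sample summaries by group
#'
#' Computes, per group and per proportion metric, the across-sample mean
#' and standard deviation of the unrounded percentages. Groups with a
#' single sample report \code{sd = NA}; a group absent from the summaries
#' is omitted with a warning.
#'
#' @param summaries A summary \code{data.frame} from
#'   \code{\link{summarizeSamples}} or \code{\link{summaryFromCounts}},
#'   with non-missing \code{group} labels.
#' @return A long \code{data.frame}: \code{group}, \code{metric},
#'   \code{n_samples}, \code{mean}, \code{sd}.
#' @examples
#' agg <- aggregateGroups(summaryFromCounts(kdCohortCounts()))
#' subset(agg, metric == "pct_dual_total")
#' @export
aggregateGroups <- function(summaries) {
  u <- .unroundedPct(summaries)
  if (all(is.na(u$group)))
    bail("summaries carry no group labels")
  if (anyNA(u$group)) {
    warning("dropping ", sum(is.na(u$group)),
            " summary row(s) without a group label", call. = FALSE)
    u <- u[!is.na(u$group), , drop = FALSE]
  }
  metrics <- setdiff(names(u), c("sample_id", "group"))
  rows <- list()
  for (g in unique(u$group)) {
    sub <- u[u$group == g, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, n_samples = length(v),
        mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Within-patient before/after differences of a proportion metric
#'
#' Aligns pre- and post-treatment samples of the same patient through the
#' manifest and tabulates the unrounded percentage of the requested metric
#' for each, ready for a paired t test. Patients lacking either timepoint
#' are dropped with a warning.
#'
#' @param summaries Summary rows for the pre and post samples.
#' @param manifest \code{data.frame} with \code{sample_id},
#'   \code{patient_id}, \code{group}.
#' @param metric One of the \code{pct_*} summary columns
#'   (default \code{"pct_dual_total"}).
#' @param groups Length-2 character vector naming the before and after
#'   group labels (default \code{c("pre_ivig", "post_ivig")}).
#' @return A \code{data.frame}: \code{patient_id}, \code{before},
#'   \code{after}, \code{diff} (after - before), in percentage points.
#' @export
pairedDifferences <- function(summaries, manifest,
                              metric = "pct_dual_total",
                              groups = c("pre_ivig", "post_ivig")) {
  u <- .unroundedPct(summaries)
  if (!metric %in% names(u))
    bail("unknown metric '", metric, "'")
  if (length(groups) != 2L)
    bail("groups must name exactly a before and an after label")
  m <- merge(u[, c("sample_id", metric)],
             manifest[, c("sample_id", "patient_id", "group")],
             by = "sample_id")
  pre <- m[m$group == groups[1L], c("patient_id", metric)]
  post <- m[m$group == groups[2L], c("patient_id", metric)]
  names(pre)[2L] <- "before"
  names(post)[2L] <- "after"
  out <- merge(pre, post, by = "patient_id")
  n_drop <- length(unique(c(pre$patient_id, post$patient_id))) - nrow(out)
  if (n_drop > 0)
    warning(n_drop, " patient(s) lacked one of the two timepoints",
            call. = FALSE)
  out$diff <- out$after - out$before
  out[order(out$patient_id), , drop = FALSE]
}

#' Attach group labels from a sample manifest
#'
#' @param x A \code{\linkS4class{CellChainSet}}.
#' @param manifest \code{data.frame} with columns \code{sample_id} and
#'   \code{group}; group labels come from the manifest only, never from
#'   parsing sample names.
#' @return The set with a \code{group} column on \code{cellData}. Samples
#'   absent from the manifest get \code{NA} with a warning.
#' @export
assignGroups <- function(x, manifest) {
  stopifnot(is(x, "CellChainSet"))
  if (!all(c("sample_id", "group") %in% names(manifest)))
    bail("manifest must have sample_id and group columns")
  if (anyDuplicated(manifest$sample_id))
    bail("duplicate sample_id in manifest")
  ce <- x@cells
  idx <- match(ce$sample_id, manifest$sample_id)
  if (anyNA(idx) && nrow(ce))
    warning("sample(s) missing from manifest: ",
            paste(unique(ce$sample_id[is.na(idx)]), collapse = ", "),
            call. = FALSE)
  ce$group <- as.character(manifest$group)[idx]
  initialize(x, cells = ce)
}
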