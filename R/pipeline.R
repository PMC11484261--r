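## One-call pipeline orchestration: ingest -> qc -> classify ->
## repertoire -> subsets -> compare, with a TSV report bundle.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  path
}

.asAnnotationTable <- function(annotations) {
  if (is.null(annotations)) return(NULL)
  if (is.data.frame(annotations))
    return(validateSubsetAnnotations(annotations))
  if (is.character(annotations)) {
    tabs <- lapply(annotations, function(p)
      utils::read.delim(p, stringsAsFactors = FALSE,
                        colClasses = "character"))
    return(validateSubsetAnnotations(do.call(rbind, tabs)))
  }
  if (is.list(annotations))
    return(validateSubsetAnnotations(do.call(rbind, annotations)))
  bail("annotations must be a data.frame, file path(s), or a list of ",
       "data.frames")
}

#' Run the full single/dual TCR analysis pipeline
#'
#' Executes every stage on a cohort of samples and writes a plain-TSV
#' report bundle to \code{outDir}: \code{summary.tsv} (per-sample pairing
#' counts and percentages), \code{group_stats.tsv},
#' \code{clonotypes.tsv}, \code{expansion.tsv}, \code{gene_usage.tsv}
#' (TRAV and TRBV by receptor class and group),
#' \code{subset_composition.tsv} (when annotations are given),
#' \code{tests.tsv} (paired t on the dual fraction, one-way ANOVA across
#' groups, chi-square on the pooled single/dual x group table, as
#' applicable to the design), \code{qc_report.json} (per-sample, per-rule
#' drop counts) and \code{run_log.txt}. A \code{MANIFEST} file lists the
#' stages that completed, so a failed run leaves an auditable partial
#' bundle. All outputs are plain text without timestamps: rerunning on
#' identical inputs produces byte-identical files.
#'
#' @param samples Contig input per sample: a named character vector of
#'   file paths, or a named list of raw annotation \code{data.frame}s
#'   (e.g. \code{$contigs} from \code{\link{simulateSample}}); names are
#'   the sample ids.
#' @param manifest \code{data.frame} with \code{sample_id},
#'   \code{patient_id}, \code{group}.
#' @param outDir Output directory, created if needed.
#' @param annotations Optional subset annotations: a \code{data.frame},
#'   file path(s), or list of \code{data.frame}s covering all samples.
#' @param dialect Contig dialect, \code{"tenx_csv"} or \code{"airr_tsv"}.
#' @param chainIdentity Chain identity level for \code{\link{collapseChains}}.
#' @param clonotypeDef Clonotype definition for \code{\link{callClonotypes}}.
#' @param alpha Significance threshold echoed into \code{tests.tsv}.
#' @return Invisibly, a list with the stage outputs (\code{summary},
#'   \code{groupStats}, \code{clonotypes}, \code{expansion},
#'   \code{geneUsage}, \code{subsetComposition}, \code{tests},
#'   \code{cells}) and \code{paths} of the written files.
#' @examples
#' preset <- kdCohortPreset(seed = 1, nScale = 0.02)
#' cohort <- simulateCohort(preset$configs, preset$manifest)
#' out <- runPipeline(lapply(cohort$sims, `[[`, "contigs"),
#'                    preset$manifest, tempfile("bundle"),
#'                    annotations = lapply(cohort$sims, `[[`, "subsets"))
#' out$summary[, c("sample_id", "pct_dual_total")]
#' @export
runPipeline <- function(samples, manifest, outDir, annotations = NULL,
                        dialect = c("tenx_csv", "airr_tsv"),
                        chainIdentity = c("nt", "aa", "gene"),
                        clonotypeDef = c("full_set", "beta_only"),
                        alpha = 0.05) {
  dialect <- match.arg(dialect)
  chainIdentity <- match.arg(chainIdentity)
  clonotypeDef <- match.arg(clonotypeDef)
  if (is.null(names(samples)) || anyDuplicated(names(samples)))
    bail("samples must be uniquely named by sample id")
  if (!all(c("sample_id", "patient_id", "group") %in% names(manifest)))
    bail("manifest must have sample_id, patient_id and group columns")
  if (!all(names(samples) %in% manifest$sample_id))
    bail("sample(s) missing from manifest: ",
         paste(setdiff(names(samples), manifest$sample_id), collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  completed <- character(0)
  writeLines(completed, file.path(outDir, "MANIFEST"))
  markDone <- function(stage) {
    completed <<- c(completed, stage)
    writeLines(completed, file.path(outDir, "MANIFEST"))
  }
  paths <- list()
  logLines <- c("dualTCR pipeline run",
                paste0("package version: ",
                       as.character(utils::packageVersion("dualTCR"))),
                paste0("dialect: ", dialect),
                paste0("chain identity: ", chainIdentity),
                paste0("clonotype definition: ", clonotypeDef),
                paste0("alpha: ", alpha),
                paste0("samples: ", paste(names(samples), collapse = ", ")))

  ## ingest + qc, per sample
  perSample <- list()
  qcReport <- list()
  for (sid in names(samples)) {
    inp <- samples[[sid]]
    cs <- if (is.character(inp)) readContigs(inp, sid, dialect)
    else ContigSet(inp, sid, dialect)
    fc <- filterFunctionalContigs(cs)
    cc <- collapseChains(fc, chainIdentity = chainIdentity)
    pp <- requirePaired(cc)
    perSample[[sid]] <- pp
    qcReport[[sid]] <- qcStats(pp)[c(
      "n_input", "drop_not_cell", "drop_low_confidence",
      "drop_chain_not_ab", "drop_not_productive", "drop_unkeyable",
      "n_functional", "n_barcodes_with_chains", "n_unpaired_removed",
      "n_paired")]
    logLines <- c(logLines, sprintf(
      "%s: %d contigs in, %d functional, %d barcodes, %d paired",
      sid, qcReport[[sid]]$n_input, qcReport[[sid]]$n_functional,
      qcReport[[sid]]$n_barcodes_with_chains, qcReport[[sid]]$n_paired))
  }
  markDone("ingest")
  jsonlite::write_json(qcReport, file.path(outDir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$qc_report <- file.path(outDir, "qc_report.json")
  markDone("qc")

  ## combine into one multi-sample set and classify
  cells <- new("CellChainSet",
               chains = do.call(rbind, c(lapply(perSample, chainData),
                                         list(make.row.names = FALSE))),
               cells = do.call(rbind, c(lapply(perSample, cellData),
                                        list(make.row.names = FALSE))),
               chainIdentity = chainIdentity,
               qcStats = list(per_sample = qcReport))
  cells <- classifyPairing(cells)
  cells <- assignGroups(cells, manifest)
  summary <- summarizeSamples(cells, manifest)
  ## partition invariant asserted on every run
  stopifnot(summary$n_single + summary$n_dual_total == summary$n_paired)
  paths$summary <- .writeTsv(summary, file.path(outDir, "summary.tsv"))
  groupStats <- aggregateGroups(summary)
  paths$group_stats <- .writeTsv(groupStats,
                                 file.path(outDir, "group_stats.tsv"))
  markDone("classify")

  ## repertoire: clonotypes, expansion, gene usage
  clonotypes <- callClonotypes(cells, definition = clonotypeDef)
  expansion <- expansionSummary(clonotypes)
  usage <- rbind(cbind(family = "TRAV",
                       geneUsage(cells, "TRAV",
                                 by = c("receptor_class", "group"))),
                 cbind(family = "TRBV",
                       geneUsage(cells, "TRBV",
                                 by = c("receptor_class", "group"))))
  paths$clonotypes <- .writeTsv(clonotypes,
                                file.path(outDir, "clonotypes.tsv"))
  paths$expansion <- .writeTsv(expansion,
                               file.path(outDir, "expansion.tsv"))
  paths$gene_usage <- .writeTsv(usage,
                                file.path(outDir, "gene_usage.tsv"))
  markDone("repertoire")

  ## subsets
  composition <- NULL
  annTab <- .asAnnotationTable(annotations)
  if (!is.null(annTab)) {
    cells <- joinSubsets(cells, annTab)
    composition <- subsetComposition(cells, by = "receptor_class")
    paths$subset_composition <- .writeTsv(
      composition, file.path(outDir, "subset_composition.tsv"))
    js <- qcStats(cells)$subset_join
    logLines <- c(logLines, sprintf(
      "subset join: %d cells, %d matched, %d unmatched cells, %d unmatched annotations",
      js$n_cells, js$n_matched, js$n_unmatched_cells,
      js$n_unmatched_annotations))
    markDone("subsets")
  }

  ## compare: the group statistics the design supports
  tests <- list()
  addTest <- function(res, metric) {
    tests[[length(tests) + 1L]] <<- data.frame(
      test = res@testName, metric = metric,
      statistic = res@statistic, df1 = res@df[1L],
      df2 = if (length(res@df) > 1L) res@df[2L] else NA_real_,
      p_value = res@pValue, significant = res@pValue < alpha,
      stringsAsFactors = FALSE)
  }
  dualPct <- 100 * summary$n_dual_total / summary$n_paired
  if (all(c("pre_ivig", "post_ivig") %in% summary$group)) {
    pd <- pairedDifferences(summary, manifest)
    if (nrow(pd) >= 2L && stats::sd(pd$diff) > 0)
      addTest(pairedT(pd$before, pd$after), "pct_dual_total_pre_vs_post")
  }
  byGroup <- split(dualPct, summary$group)
  byGroup <- byGroup[lengths(byGroup) >= 2L]
  if (length(byGroup) >= 2L)
    addTest(anovaOneway(byGroup), "pct_dual_total_across_groups")
  if (length(unique(summary$group[!is.na(summary$group)])) >= 2L) {
    tab <- rbind(single = tapply(summary$n_single, summary$group, sum),
                 dual = tapply(summary$n_dual_total, summary$group, sum))
    addTest(chiSquareTest(tab), "single_dual_by_group")
  }
  testsDf <- if (length(tests)) do.call(rbind, tests) else
    data.frame(test = character(0), metric = character(0),
               statistic = numeric(0), df1 = numeric(0), df2 = numeric(0),
               p_value = numeric(0), significant = logical(0))
  paths$tests <- .writeTsv(testsDf, file.path(outDir, "tests.tsv"))
  markDone("compare")

  writeLines(logLines, file.path(outDir, "run_log.txt"))
  paths$run_log <- file.path(outDir, "run_log.txt")
  markDone("report")
  invisible(list(summary = summary, groupStats = groupStats,
                 clonotypes = clonotypes, expansion = expansion,
                 geneUsage = usage, subsetComposition = composition,
                 tests = testsDf, cells = cells, paths = paths))
}
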