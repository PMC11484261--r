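## Published per-sample pairing counts for the GSE168732 cohort and the
## cohort-shaped simulation preset built from them.

#' Published pairing counts for the GSE168732 Kawasaki-disease cohort
#'
#' Per-sample single/dual pairing counts for the 15 single-cell V(D)J
#' samples of the GSE168732 study: 6 Kawasaki-disease patients sampled
#' before and after IVIG treatment plus 3 healthy controls. For each
#' sample the table lists the total annotated barcodes (\code{n_total}),
#' the paired-TCR-cell denominator (\code{n_paired}), the counts of
#' single cells and of the four dual pairing subtypes plus the residual
#' \code{others} class, and the percentages as published
#' (\code{pub_pct_*}). The counts satisfy the partition invariants
#' exactly; two published percentages differ from half-up rounding of
#' count/denominator by 0.01 (truncation in the source), which is why
#' comparisons against \code{pub_pct_*} should allow a +/-0.01 rounding
#' margin.
#'
#' @return A \code{data.frame} with one row per sample.
#' @examples
#' counts <- kdCohortCounts()
#' summaryFromCounts(counts)[, c("sample_id", "pct_dual_total")]
#' @export
kdCohortCounts <- function() {
  path <- system.file("extdata", "gse168732_pairing_counts.tsv",
                      package = "dualTCR", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Manifest for the GSE168732-shaped cohort
#'
#' @return A \code{data.frame} with \code{sample_id}, \code{patient_id},
#'   \code{group} for the 15 cohort samples.
#' @export
kdCohortManifest <- function() {
  kdCohortCounts()[, c("sample_id", "patient_id", "group")]
}

#' Cohort-shaped simulation preset
#'
#' Builds per-sample \code{\link{simConfig}}s emulating the published
#' cohort: 6 pre-IVIG, 6 post-IVIG and 3 control samples at the published
#' paired-cell sizes, with each pre-IVIG and control sample's pairing
#' probabilities taken from its published composition (dual fractions
#' 4.6-15.1\% pre, ~12\% control, two-alpha \code{DUAL_B_A1A2} dominant
#' throughout). Post-IVIG samples plant a uniform dual-fraction increase
#' of \code{dualIncrease} percentage points over the same patient's
#' pre-IVIG fraction - the published cohort's mean shift - with the dual
#' mass split according to the published post-treatment subtype
#' composition. Post-IVIG samples other than patient KD5's also plant two
#' expanded dual clonotypes (sizes 3 and 2), mirroring the reported
#' post-treatment dual-cell expansion. Control samples carry a two-fold
#' (post-IVIG: 1.5-fold) Treg enrichment among dual cells.
#'
#' Contig-level noise defaults: 5\% non-cell, 3\% low-confidence, 5\%
#' non-productive and 5\% duplicate contigs, plus unpaired single-locus
#' cells at each sample's published total/paired ratio.
#'
#' @param seed Master seed; per-sample seeds are derived from it
#'   deterministically.
#' @param nScale Multiplier on the published paired-cell counts, to scale
#'   runtime; the planted effect is scale-free.
#' @param dualIncrease Planted post-IVIG dual-fraction increase in
#'   percentage points (default 4.27, the published cohort mean).
#' @param noise Overrides for the noise rates applied to every sample.
#' @return A list with \code{configs} (named list of
#'   \code{\link{simConfig}}) and \code{manifest}.
#' @examples
#' preset <- kdCohortPreset(seed = 1, nScale = 0.1)
#' cohort <- simulateCohort(preset$configs, preset$manifest)
#' names(cohort$sims)
#' @export
kdCohortPreset <- function(seed = 1L, nScale = 1, dualIncrease = 4.27,
                           noise = list()) {
  counts <- kdCohortCounts()
  manifest <- counts[, c("sample_id", "patient_id", "group")]
  baseNoise <- list(fracNonCell = 0.05, fracLowConf = 0.03,
                    fracNonProductive = 0.05, duplicateContigRate = 0.05)
  baseNoise[names(noise)] <- noise
  configs <- list()
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    subtype <- c(DUAL_A_B1B2 = row$n_dual_a_b1b2,
                 DUAL_B_A1A2 = row$n_dual_b_a1a2,
                 DUAL_A1A2B1B2 = row$n_dual_a1a2b1b2,
                 OTHERS = row$n_others)
    if (row$group == "post_ivig") {
      pre <- counts[counts$patient_id == row$patient_id &
                      counts$group == "pre_ivig", ]
      dualFrac <- pre$n_dual_total / pre$n_paired + dualIncrease / 100
    } else {
      dualFrac <- row$n_dual_total / row$n_paired
    }
    probs <- c(SINGLE_AB = 1 - dualFrac,
               dualFrac * subtype / sum(subtype))
    names(probs) <- c("SINGLE_AB", names(subtype))
    planted <- list()
    if (row$group == "post_ivig" && row$patient_id != "KD5")
      planted <- list(list(size = 3L, pairing = "DUAL_B_A1A2"),
                      list(size = 2L, pairing = "DUAL_B_A1A2"))
    bias <- switch(row$group,
                   control = c(treg = 2),
                   post_ivig = c(treg = 1.5),
                   NULL)
    smpNoise <- c(baseNoise, list(
      unpairedCellRate = (row$n_total - row$n_paired) / row$n_paired))
    configs[[row$sample_id]] <- simConfig(
      nCells = max(10L, round(nScale * row$n_paired)),
      pairingProbs = probs,
      plantedClones = planted,
      dualSubsetBias = bias,
      noise = smpNoise,
      seed = deriveSeed(seed, i),
      sampleId = row$sample_id)
  }
  list(configs = configs, manifest = manifest)
}
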