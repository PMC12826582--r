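#' Analysis configuration
#'
#' Bundles the thresholds used across the pipeline. Defaults are the study's
#' operating values: genes are anchored to the phenotype at the lowest
#' concentration eliciting it (1.33 uM), the benchmark response for gene
#' expression is 1.35 residual standard deviations from control expression,
#' gene BMCs are kept only when the 95% CI ratio BMCu/BMCl is at most 40,
#' differential expression and enrichment use adjusted p <= 0.05, and the
#' enrichment network uses kappa >= 0.35 with 50% gene overlap for group
#' merging. Morphological BMCs are computed at 20% extra risk.
#'
#' @param anchor_uM phenotype-anchoring concentration in uM; gene BMCs at or
#'   below it are called phenotype-associated.
#' @param bmr_sd_multiplier benchmark response in residual SD units.
#' @param ci_ratio_max maximum allowed BMCu/BMCl ratio.
#' @param de_alpha adjusted-p cutoff for the differential-expression screen.
#' @param enrichment_alpha adjusted-p cutoff for term enrichment.
#' @param kappa_threshold minimum kappa for a network edge.
#' @param overlap_threshold minimum shared-gene fraction for merging groups.
#' @param extra_risk extra-risk level for dichotomous endpoint BMCs.
#' @param seed integer seed forwarded to stochastic steps (bootstrap).
#'
#' @return A list of class `phenobmc_config`.
#' @examples
#' cfg <- analysis_config()
#' cfg$anchor_uM
#' @export
analysis_config <- function(anchor_uM = 1.33,
                            bmr_sd_multiplier = 1.35,
                            ci_ratio_max = 40,
                            de_alpha = 0.05,
                            enrichment_alpha = 0.05,
                            kappa_threshold = 0.35,
                            overlap_threshold = 0.5,
                            extra_risk = 0.20,
                            seed = 1L) {
  stopifnot(
    anchor_uM > 0, bmr_sd_multiplier > 0, ci_ratio_max > 0,
    de_alpha > 0, enrichment_alpha > 0,
    kappa_threshold > -1, overlap_threshold > 0,
    extra_risk > 0, extra_risk < 1
  )
  structure(
    list(
      anchor_uM = anchor_uM,
      bmr_sd_multiplier = bmr_sd_multiplier,
      ci_ratio_max = ci_ratio_max,
      de_alpha = de_alpha,
      enrichment_alpha = enrichment_alpha,
      kappa_threshold = kappa_threshold,
      overlap_threshold = overlap_threshold,
      extra_risk = extra_risk,
      seed = as.integer(seed)
    ),
    class = "phenobmc_config"
  )
}

#' @export
print.phenobmc_config <- function(x, ...) {
  cat("<phenobmc analysis config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# declared vocabulary of morphological endpoints (10 binned endpoints)
#' Morphological endpoint vocabulary
#'
#' The ten binned endpoints scored at 120 hpf in the 96-well morphology
#' assay. `read_morphology()` rejects tables whose endpoint names are not in
#' this set.
#'
#' @return Character vector of endpoint names.
#' @export
morphology_endpoints <- function() {
  c(
    "mortality", "cranial", "axis", "edema", "muscular_cardiovascular",
    "lower_trunk", "brain", "skin_pigmentation", "notochord", "x_fin"
  )
}
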