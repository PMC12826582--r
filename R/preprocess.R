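#' Filter genes with low counts
#'
#' Keeps genes with at least `min_reads` reads in at least `min_samples`
#' samples, applied within the sample group being analyzed (typically one
#' timepoint, so per-timepoint gene totals match how the analysis is split).
#'
#' @param counts integer matrix (genes x samples).
#' @param min_reads minimum read count (default 5).
#' @param min_samples minimum number of samples meeting it (default 2).
#' @return Filtered count matrix.
#' @examples
#' m <- rbind(a = c(5, 5, 0), b = c(5, 4, 0))
#' rownames(filter_low_counts(m)) # "a"
#' @export
filter_low_counts <- function(counts, min_reads = 5, min_samples = 2) {
  keep <- rowSums(counts >= min_reads) >= min_samples
  if (!any(keep)) abort("no genes pass the low-count filter")
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (the `calcNormFactors`
#' normalization): the reference sample is the one whose 75th-percentile
#' count fraction is closest to the mean of those; per sample, M and A
#' values are computed on genes positive in both sample and reference, 30%
#' of the M tails and 5% of the A tails are trimmed, and the factor is 2 to
#' the precision-weighted mean of the remaining M values. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts filtered count matrix.
#' @return Named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts) {
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  setNames(as.numeric(f), colnames(counts))
}

#' log2 counts per million
#'
#' `log2((count + prior) / (effective library size + 2 * prior) * 1e6)`
#' where the effective library size is the raw column sum times the TMM
#' factor. The prior keeps zeros finite.
#'
#' @param counts count matrix.
#' @param factors per-sample TMM factors ([tmm_factors()]); defaults to 1.
#' @param prior prior count (default 0.5).
#' @return List of class `normalized_matrix`: `log2cpm` matrix, `factors`,
#'   `effective_lib_size`.
#' @examples
#' m <- matrix(c(100L, 900L), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' log2cpm(m)$log2cpm["a", ]
#' @export
log2cpm <- function(counts, factors = NULL, prior = 0.5) {
  lib <- colSums(counts)
  if (is.null(factors)) factors <- setNames(rep(1, ncol(counts)),
                                            colnames(counts))
  eff <- lib * factors[colnames(counts)]
  lc <- log2(sweep(counts + prior, 2, eff + 2 * prior, "/") * 1e6)
  structure(
    list(log2cpm = lc, factors = factors, effective_lib_size = eff),
    class = "normalized_matrix"
  )
}

#' PCA quality control of normalized expression
#'
#' Centered (unscaled) principal components of samples in log2 CPM space.
#' In whole-embryo developmental data the first component separates
#' timepoints; analyses are then run per timepoint.
#'
#' @param nm a `normalized_matrix` from [log2cpm()], or a log2 CPM matrix.
#' @param metadata optional sample metadata joined onto the scores.
#' @param n_components number of components to return.
#' @return Object of class `pca_qc`: `scores` tibble (sample_id, PC columns,
#'   metadata), `var_explained`, and the loadings (`rotation`).
#' @export
pca_qc <- function(nm, metadata = NULL, n_components = 5) {
  m <- if (inherits(nm, "normalized_matrix")) nm$log2cpm else nm
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores$sample_id <- colnames(m)
  scores <- select(scores, "sample_id", dplyr::everything())
  if (!is.null(metadata)) {
    scores <- left_join(scores, as_tibble(metadata), by = "sample_id")
  }
  structure(
    list(
      scores = scores,
      var_explained = pc$sdev^2 / sum(pc$sdev^2),
      rotation = pc$rotation[, seq_len(k), drop = FALSE]
    ),
    class = "pca_qc"
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.pca_qc <- function(object, colour = NULL, ...) {
  aes <- if (!is.null(colour) && colour %in% names(object$scores)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2,
                 colour = factor(.data[[colour]]))
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(object$scores, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = colour
    ) +
    ggplot2::theme_minimal()
}
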