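#' Phenotype-anchored gene set
#'
#' Genes with a concentration-response relationship (`has_cr`) whose BMC is
#' at or below the anchoring concentration — the lowest concentration
#' eliciting the phenotype. The boundary is inclusive.
#'
#' @param records gene BMC records ([fit_gene_bmc()]) with `gene_id`,
#'   `bmc_uM`, `has_cr`.
#' @param anchor_uM anchoring concentration (uM), default 1.33.
#' @return Character vector of phenotype-associated gene identifiers.
#' @export
anchor_genes <- function(records, anchor_uM = 1.33) {
  rec <- as_tibble(records)
  sort(rec$gene_id[rec$has_cr %in% TRUE &
                     is.finite(rec$bmc_uM) &
                     rec$bmc_uM <= anchor_uM])
}

#' Cross-chemical uniqueness filter
#'
#' Removes from a phenotype-associated gene set every gene that has a
#' concentration-response relationship (`has_cr`) in any comparator
#' chemical, regardless of the comparator's BMC value. Applied at a single
#' timepoint; the headline analysis uses the pre-phenotype timepoint,
#' where expression changes precede the morphological outcome.
#'
#' @param target_set character vector of genes.
#' @param ... one or more comparator record tables (same shape as
#'   [fit_gene_bmc()] output).
#' @return The filtered gene set (subset of `target_set`).
#' @export
unique_filter <- function(target_set, ...) {
  comparators <- list(...)
  excluded <- unique(unlist(lapply(comparators, function(rec) {
    rec <- as_tibble(rec)
    rec$gene_id[rec$has_cr %in% TRUE]
  })))
  sort(setdiff(target_set, excluded))
}

#' Multi-way set overlap (Venn regions)
#'
#' Computes every `2^k` Venn region for `k` named sets: a per-gene
#' membership table and per-region counts with percentages relative to the
#' union.
#'
#' @param ... named character vectors (the sets).
#' @return List with `membership` (tibble: gene, one logical column per
#'   set, `region` label) and `regions` (tibble: region, count, percent).
#' @examples
#' multiway_overlap(a = c("x", "y"), b = c("y", "z"))$regions
#' @export
multiway_overlap <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("all sets must be named")
  }
  universe <- sort(unique(unlist(sets)))
  membership <- tibble(gene_id = universe)
  for (nm in names(sets)) membership[[nm]] <- universe %in% sets[[nm]]
  membership$region <- apply(
    as.matrix(membership[names(sets)]), 1,
    function(row) {
      inn <- names(sets)[row]
      if (length(inn) == 0) "none" else paste(inn, collapse = "&")
    }
  )
  # every region of the 2^k lattice, including empty ones
  combos <- tidyr::expand_grid(!!!setNames(
    rep(list(c(FALSE, TRUE)), length(sets)), names(sets)
  ))
  combos <- combos[rowSums(as.matrix(combos)) > 0, , drop = FALSE]
  region_label <- apply(as.matrix(combos), 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  counts <- vapply(region_label, function(lab) {
    sum(membership$region == lab)
  }, integer(1))
  list(
    membership = membership,
    regions = tibble(
      region = region_label, count = unname(counts),
      percent = if (length(universe) > 0) {
        100 * unname(counts) / length(universe)
      } else {
        rep(NA_real_, length(counts))
      }
    )
  )
}

#' Compare a gene set against external DEG tables
#'
#' Joins a gene set (e.g. the phenotype-unique genes) against one or more
#' externally published differential-expression tables on case-normalized
#' gene symbols, reporting shared and source-unique genes and a log2
#' fold-change matrix across sources for the shared set.
#'
#' @param gene_set character vector of gene symbols.
#' @param external named list of tibbles, each with `gene_id`, `log2fc`
#'   and optionally `padj`.
#' @return List with `shared` (genes present in every external source),
#'   `unique_to_set` (genes in none of them), `overlap` (the
#'   [multiway_overlap()] of the set and all sources) and `log2fc_matrix`
#'   (tibble: gene x source log2 fold changes for the shared genes).
#' @export
compare_external <- function(gene_set, external) {
  if (is.null(names(external)) || any(names(external) == "")) {
    abort("external tables must be named")
  }
  norm <- function(x) tolower(trimws(x))
  set_n <- unique(norm(gene_set))
  ext_n <- lapply(external, function(tab) {
    tab <- as_tibble(tab)
    tab$gene_id <- norm(tab$gene_id)
    tab
  })
  sets <- c(list(query = set_n),
            lapply(ext_n, function(tab) unique(tab$gene_id)))
  ov <- rlang::exec(multiway_overlap, !!!sets)
  in_all <- Reduce(intersect, lapply(ext_n, `[[`, "gene_id"), set_n)
  in_none <- Reduce(setdiff, lapply(ext_n, `[[`, "gene_id"), set_n)
  lfc <- tibble(gene_id = sort(in_all))
  for (nm in names(ext_n)) {
    tab <- ext_n[[nm]]
    lfc[[nm]] <- tab$log2fc[match(lfc$gene_id, tab$gene_id)]
  }
  list(
    shared = sort(in_all),
    unique_to_set = sort(in_none),
    overlap = ov,
    log2fc_matrix = lfc
  )
}
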