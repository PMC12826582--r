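#' Read a morphology incidence table
#'
#' Accepts either per-well CSVs (columns `line`, `chemical`,
#' `concentration_uM`, `timepoint_hpf`, `well`, `endpoint`, `affected` in
#' 0/1) or pre-aggregated CSVs (same keys with `n_affected`, `n_total`).
#' Per-well records are aggregated to incidence counts per
#' line x chemical x concentration x timepoint x endpoint. Endpoint names
#' must come from [morphology_endpoints()].
#'
#' @param path CSV file path.
#' @return Aggregated tibble with columns `line`, `chemical`,
#'   `concentration_uM`, `timepoint_hpf`, `endpoint`, `n_affected`,
#'   `n_total`.
#' @export
read_morphology <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  validate_morphology(tab)
}

#' Validate and aggregate an in-memory morphology table
#'
#' @param tab data frame in either per-well or aggregated form (see
#'   [read_morphology()]).
#' @return Aggregated, validated tibble.
#' @export
validate_morphology <- function(tab) {
  tab <- as_tibble(tab)
  keys <- c("line", "chemical", "concentration_uM", "timepoint_hpf",
            "endpoint")
  missing_keys <- setdiff(keys, names(tab))
  if (length(missing_keys) > 0) {
    abort(paste0("morphology table lacks columns: ",
                 paste(missing_keys, collapse = ", ")))
  }
  bad <- setdiff(unique(tab$endpoint), morphology_endpoints())
  if (length(bad) > 0) {
    abort(paste0(
      "unknown endpoint(s): ", paste(bad, collapse = ", "),
      "; allowed endpoints are: ",
      paste(morphology_endpoints(), collapse = ", ")
    ))
  }
  if (any(tab$concentration_uM < 0)) {
    abort("concentrations must be >= 0")
  }
  if ("affected" %in% names(tab)) {
    if (!all(tab$affected %in% c(0L, 1L))) {
      abort("per-well `affected` must be 0 or 1")
    }
    tab <- tab |>
      group_by(across(dplyr::all_of(keys))) |>
      summarise(
        n_affected = sum(.data$affected),
        n_total = dplyr::n(),
        .groups = "drop"
      )
  }
  if (!all(c("n_affected", "n_total") %in% names(tab))) {
    abort("morphology table needs either `affected` or `n_affected`/`n_total`")
  }
  if (any(tab$n_affected < 0 | tab$n_affected > tab$n_total)) {
    abort("n_affected must lie in [0, n_total]")
  }
  tab$n_affected <- as.integer(tab$n_affected)
  tab$n_total <- as.integer(tab$n_total)
  tab |>
    select(dplyr::all_of(c(keys, "n_affected", "n_total"))) |>
    arrange(.data$endpoint, .data$concentration_uM)
}

#' Write a morphology table to CSV
#'
#' @param tab per-well or aggregated morphology tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphology <- function(tab, path) {
  readr::write_csv(tab, path)
  invisible(path)
}

#' Read a count matrix with sample metadata
#'
#' The counts TSV has gene identifiers in the first column and one column
#' per sample; the metadata TSV has one row per sample with at least
#' `sample_id`, `chemical`, `concentration_uM`, `timepoint_hpf`,
#' `replicate`. Counts must be non-negative integers; every sample column
#' must appear in the metadata.
#'
#' @param path counts TSV path.
#' @param metadata_path sample metadata TSV path.
#' @return List with `counts` (integer matrix) and `metadata` (tibble, in
#'   column order of the matrix, with `lib_size` recomputed as column sums).
#' @export
read_counts <- function(path, metadata_path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  gene_id <- as.character(raw[[1]])
  if (anyDuplicated(gene_id)) {
    abort("duplicate gene identifiers in count matrix")
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) ||
      any(m != round(m))) {
    abort("counts must be finite non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- gene_id
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  need <- c("sample_id", "chemical", "concentration_uM", "timepoint_hpf",
            "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  absent <- setdiff(colnames(m), meta$sample_id)
  if (length(absent) > 0) {
    abort(paste0("samples missing from metadata: ",
                 paste(absent, collapse = ", ")))
  }
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  meta$lib_size <- unname(colSums(m))
  list(counts = m, metadata = as_tibble(meta))
}

#' Write a count matrix and its metadata
#'
#' @param counts integer matrix (genes x samples, rownames = gene ids).
#' @param metadata sample metadata tibble.
#' @param path counts TSV path.
#' @param metadata_path metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, metadata, path, metadata_path) {
  out <- dplyr::bind_cols(
    tibble(gene_id = rownames(counts)),
    as_tibble(as.data.frame(counts))
  )
  readr::write_tsv(out, path)
  readr::write_tsv(metadata, metadata_path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited GMT: term, description, then member genes. Genes
#' duplicated within a term are deduplicated; empty terms are retained with
#' a warning.
#'
#' @param path GMT file path.
#' @return Tibble with columns `term`, `description`, `genes` (list-column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(term = character(), description = character(),
                  genes = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 2
  if (any(short)) abort("GMT lines must have at least term and description")
  term <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  genes <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  if (any(lengths(genes) == 0)) {
    warn(paste0(
      "GMT terms with empty gene lists retained: ",
      paste(term[lengths(genes) == 0], collapse = ", ")
    ))
  }
  tibble(term = term, description = desc, genes = genes)
}

#' Write a GMT gene-set file
#'
#' @param gmt tibble with `term`, `description`, `genes` list-column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gmt, path) {
  lines <- vapply(seq_len(nrow(gmt)), function(i) {
    paste(c(gmt$term[i], gmt$description[i], gmt$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
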