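#' Hypergeometric term enrichment
#'
#' Right-tailed hypergeometric test of each annotation term against a
#' query gene set over an expressed-gene universe (terms are intersected
#' with the universe first), with Benjamini-Hochberg adjustment. The
#' universe should be the genes passing the low-count filter for the
#' analyzed timepoint, guarding against expression-bias inflation.
#'
#' @param query character vector of genes (must lie in the universe).
#' @param gmt annotation tibble from [read_gmt()] / [simulate_gmt()]
#'   (columns `term`, `description`, `genes`), or a named list of gene
#'   vectors.
#' @param universe character vector of all testable genes.
#' @param alpha adjusted-p cutoff for the `enriched` flag.
#' @return Tibble per term: `term`, `n_annotated`, `n_overlap`,
#'   `overlap_genes` (list-column), `pvalue`, `padj`, `enriched`.
#' @export
hypergeom_enrich <- function(query, gmt, universe, alpha = 0.05) {
  if (is.list(gmt) && !is.data.frame(gmt)) {
    gmt <- tibble(term = names(gmt),
                  description = rep("", length(gmt)), genes = unname(gmt))
  }
  universe <- unique(universe)
  query <- unique(query)
  stray <- setdiff(query, universe)
  if (length(stray) > 0) {
    abort(paste0("query genes outside the universe: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  N <- length(universe)
  n <- length(query)
  res <- purrr::map_dfr(seq_len(nrow(gmt)), function(i) {
    ann <- intersect(gmt$genes[[i]], universe)
    ov <- intersect(ann, query)
    K <- length(ann)
    k <- length(ov)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = gmt$term[i], n_annotated = K, n_overlap = k,
           overlap_genes = list(ov), annotated_genes = list(ann),
           pvalue = p)
  })
  res$padj <- p.adjust(res$pvalue, method = "BH")
  res$enriched <- res$padj <= alpha
  arrange(res, .data$pvalue)
}

#' Cohen's kappa between two term memberships
#'
#' Chance-corrected agreement between two binary gene-membership vectors
#' over a universe: with `a = |A intersect B|`, `b = |A \\ B|`,
#' `c = |B \\ A|`, `d = |U| - a - b - c`, observed agreement
#' `Po = (a + d)/|U|`, expected agreement
#' `Pe = ((a+b)(a+c) + (c+d)(b+d))/|U|^2`, kappa is `(Po - Pe)/(1 - Pe)`.
#' Equals 1 for identical non-trivial memberships; can be negative for
#' systematic disagreement.
#'
#' @param set_a,set_b character vectors (gene memberships of two terms).
#' @param universe the gene universe.
#' @return Kappa in `[-1, 1]` (`NA` when `Pe = 1`, i.e. degenerate
#'   memberships).
#' @examples
#' kappa_stat(c("a", "b"), c("a", "b"), letters[1:10]) # 1
#' @export
kappa_stat <- function(set_a, set_b, universe) {
  u <- unique(universe)
  A <- unique(intersect(set_a, u))
  B <- unique(intersect(set_b, u))
  n <- length(u)
  a <- length(intersect(A, B))
  b <- length(setdiff(A, B))
  cc <- length(setdiff(B, A))
  d <- n - a - b - cc
  po <- (a + d) / n
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Kappa-statistic enrichment network
#'
#' Builds the functional-grouping network of enriched terms: nodes are
#' terms flagged enriched, edges connect term pairs whose membership kappa
#' is at least `kappa_threshold`, initial groups are the connected
#' components of that graph, and groups are then merged iteratively
#' (term pairs processed in lexicographic order) whenever the shared
#' fraction of their gene unions is at least `overlap_threshold`. Each
#' group is labeled by its member term with the lowest enrichment p-value.
#'
#' @param enrich result of [hypergeom_enrich()] (uses the `enriched` flag,
#'   `annotated_genes` and `pvalue`).
#' @param universe gene universe used for the kappa computations.
#' @param kappa_threshold minimum kappa for an edge (default 0.35).
#' @param overlap_threshold minimum shared-gene fraction for merging
#'   groups (default 0.5).
#' @return Object of class `kappa_network`: `nodes` (term, pvalue, group,
#'   group label), `edges` (term_a, term_b, kappa), `groups` (group,
#'   label, n_terms, n_genes), and the underlying `igraph` object.
#' @export
build_network <- function(enrich, universe, kappa_threshold = 0.35,
                          overlap_threshold = 0.5) {
  terms <- dplyr::filter(as_tibble(enrich), .data$enriched) |>
    arrange(.data$term)
  empty <- structure(
    list(nodes = tibble(term = character(), pvalue = numeric(),
                        group = integer(), label = character()),
         edges = tibble(term_a = character(), term_b = character(),
                        kappa = numeric()),
         groups = tibble(group = integer(), label = character(),
                         n_terms = integer(), n_genes = integer()),
         graph = igraph::make_empty_graph(0, directed = FALSE)),
    class = "kappa_network"
  )
  if (nrow(terms) == 0) return(empty)
  gene_sets <- setNames(lapply(terms$annotated_genes, intersect,
                               unique(universe)), terms$term)
  pairs <- if (nrow(terms) >= 2) {
    utils::combn(terms$term, 2, simplify = FALSE)
  } else {
    list()
  }
  edges <- purrr::map_dfr(pairs, function(pr) {
    k <- kappa_stat(gene_sets[[pr[1]]], gene_sets[[pr[2]]], universe)
    tibble(term_a = pr[1], term_b = pr[2], kappa = k)
  })
  if (nrow(edges) > 0) {
    edges <- dplyr::filter(edges, !is.na(.data$kappa),
                           .data$kappa >= kappa_threshold)
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges) > 0) edges[, c("term_a", "term_b")] else
      tibble(term_a = character(), term_b = character()),
    directed = FALSE,
    vertices = tibble(name = terms$term)
  )
  if (nrow(edges) > 0) igraph::E(g)$kappa <- edges$kappa
  comp <- igraph::components(g)$membership
  group <- comp[terms$term]

  # iterative merging of groups by shared fraction of their gene unions
  group_genes <- function(grp) {
    split(terms$term, grp) |>
      lapply(function(tt) unique(unlist(gene_sets[tt])))
  }
  repeat {
    gg <- group_genes(group)
    ids <- sort(as.integer(names(gg)))
    merged <- FALSE
    if (length(ids) >= 2) {
      for (i in seq_along(ids)[-length(ids)]) {
        for (j in (i + 1):length(ids)) {
          ga <- gg[[as.character(ids[i])]]
          gb <- gg[[as.character(ids[j])]]
          shared <- length(intersect(ga, gb))
          denom <- length(union(ga, gb))
          if (denom > 0 && shared / denom >= overlap_threshold) {
            group[group == ids[j]] <- ids[i]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  group <- as.integer(factor(group, levels = sort(unique(group))))
  names(group) <- terms$term

  nodes <- tibble(term = terms$term, pvalue = terms$pvalue, group = group)
  groups <- nodes |>
    group_by(.data$group) |>
    summarise(
      label = .data$term[which.min(.data$pvalue)],
      n_terms = dplyr::n(),
      n_genes = length(unique(unlist(gene_sets[.data$term]))),
      .groups = "drop"
    )
  nodes <- left_join(nodes, groups[, c("group", "label")], by = "group")
  structure(
    list(nodes = nodes, edges = edges, groups = groups, graph = g),
    class = "kappa_network"
  )
}

#' Write a kappa network to disk
#'
#' Writes the edge list as TSV and the graph as GraphML next to it.
#'
#' @param net a `kappa_network`.
#' @param edge_path edge-list TSV path.
#' @param graphml_path GraphML path (default: edge_path with .graphml).
#' @return `edge_path`, invisibly.
#' @export
write_kappa_network <- function(net, edge_path,
                                graphml_path = sub("\\.tsv$", ".graphml",
                                                   edge_path)) {
  readr::write_tsv(net$edges, edge_path)
  igraph::write_graph(net$graph, graphml_path, format = "graphml")
  invisible(edge_path)
}

#' @export
print.kappa_network <- function(x, ...) {
  cat(sprintf("<kappa_network: %d terms, %d edges, %d groups>\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$groups)))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.kappa_network <- function(object, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty enrichment network"))
  }
  lay <- igraph::layout_with_fr(object$graph)
  nodes <- object$nodes
  nodes$x <- lay[, 1]
  nodes$y <- lay[, 2]
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(object$edges) > 0) {
    seg <- object$edges
    seg$x <- nodes$x[match(seg$term_a, nodes$term)]
    seg$y <- nodes$y[match(seg$term_a, nodes$term)]
    seg$xend <- nodes$x[match(seg$term_b, nodes$term)]
    seg$yend <- nodes$y[match(seg$term_b, nodes$term)]
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "grey70"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$group)),
                        size = 3) +
    ggplot2::labs(colour = "group") +
    ggplot2::theme_void()
}
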