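test_that("hypergeometric p has its closed form on the worked example", {
  universe <- sprintf("g%02d", 1:20)
  gmt <- tibble::tibble(term = "t1", description = "",
                        genes = list(universe[1:5]))
  res <- hypergeom_enrich(universe[1:5], gmt, universe)
  expect_equal(res$pvalue, 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap: right tail includes 0, so p = 1
  res0 <- hypergeom_enrich(universe[6:10], gmt, universe)
  expect_equal(res0$pvalue, 1)
})

test_that("a planted term made of the responsive genes ranks first", {
  cfg <- small_config(seed = 61, frac_responsive = 0.15)
  sim <- simulate_counts(cfg)
  resp <- sim$manifest$gene_id[sim$manifest$responsive]
  gmt <- simulate_gmt(cfg, sim$manifest, n_terms = 20, n_enriched = 0)
  gmt <- dplyr::bind_rows(
    tibble::tibble(term = "PLANTED", description = "",
                   genes = list(resp), planted = TRUE),
    gmt
  )
  res <- hypergeom_enrich(resp, gmt, sim$manifest$gene_id)
  expect_equal(res$term[1], "PLANTED")
  expect_true(res$enriched[1])
})

test_that("null enrichment p-values are super-uniform", {
  # random disjoint terms against a random query: P(p <= alpha) <= alpha
  # (hypergeometric p-values are discrete, hence conservative)
  set.seed(62)
  universe <- sprintf("g%04d", 1:2000)
  ps <- unlist(lapply(1:30, function(rep) {
    terms <- split(sample(universe, 500), rep(1:50, each = 10))
    gmt <- tibble::tibble(term = sprintf("t%02d", 1:50), description = "",
                          genes = unname(terms))
    query <- sample(universe, 100)
    hypergeom_enrich(query, gmt, universe)$pvalue
  }))
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    emp <- mean(ps <= alpha)
    mc_slack <- 3 * sqrt(alpha * (1 - alpha) / length(ps))
    expect_lte(emp, alpha + mc_slack)
  }
})

test_that("kappa matches an independent confusion-matrix computation", {
  u <- sprintf("g%02d", 1:40)
  expect_equal(kappa_stat(u[1:10], u[1:10], u), 1)
  # disjoint sets covering the universe disagree maximally
  k_split <- kappa_stat(u[1:20], u[21:40], u)
  expect_lt(k_split, 0)
  set.seed(63)
  for (i in 1:25) {
    A <- sample(u, sample(3:20, 1))
    B <- sample(u, sample(3:20, 1))
    ka <- kappa_stat(A, B, u)
    # independent route: confusion table of the membership factors
    tab <- table(factor(u %in% A, c(FALSE, TRUE)),
                 factor(u %in% B, c(FALSE, TRUE)))
    po <- sum(diag(tab)) / length(u)
    pe <- sum(rowSums(tab) * colSums(tab)) / length(u)^2
    expect_equal(ka, (po - pe) / (1 - pe), tolerance = 1e-12)
    expect_equal(ka, kappa_stat(B, A, u))   # symmetry
    expect_gte(ka, -1)
    expect_lte(ka, 1)
  }
})

test_that("kappa approaches the formula limit as the universe grows", {
  A <- sprintf("a%02d", 1:10)
  B <- c(A[1:5], sprintf("b%02d", 1:5))
  for (N in c(100, 1000, 10000)) {
    u <- c(A, B, sprintf("u%05d", seq_len(N)))
    u <- unique(u)
    n <- length(u)
    a <- 5; b <- 5; cc <- 5
    d <- n - 15
    po <- (a + d) / n
    pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
    expect_equal(kappa_stat(A, B, u), (po - pe) / (1 - pe),
                 tolerance = 1e-12)
  }
})

test_that("network edges and groups follow the kappa/overlap rules", {
  u <- sprintf("g%02d", 1:60)
  gmt <- tibble::tibble(
    term = c("t1", "t2", "t3", "t4", "t5"),
    description = "",
    genes = list(
      u[1:10], u[1:10],        # identical pair
      u[c(1:8, 11:12)],        # heavy overlap with t1/t2
      u[21:30], u[41:50]       # separate and disjoint
    )
  )
  query <- u[1:30]
  enr <- hypergeom_enrich(query, gmt, u, alpha = 1)  # keep all terms as nodes
  net <- build_network(enr, u, kappa_threshold = 0.35)
  # hand-computed adjacency: kappa over membership vectors
  expected_edge <- function(i, j) {
    kappa_stat(gmt$genes[[i]], gmt$genes[[j]], u) >= 0.35
  }
  for (i in 1:4) {
    for (j in (i + 1):5) {
      has <- any((net$edges$term_a == gmt$term[i] &
                    net$edges$term_b == gmt$term[j]) |
                   (net$edges$term_a == gmt$term[j] &
                      net$edges$term_b == gmt$term[i]))
      expect_equal(has, expected_edge(i, j))
    }
  }
  # identical gene sets end in one group; disjoint terms get no edge
  g12 <- net$nodes$group[net$nodes$term %in% c("t1", "t2")]
  expect_equal(length(unique(g12)), 1)
  expect_false(any(net$edges$term_a == "t5" | net$edges$term_b == "t5"))
  # group labels are the lowest-p member
  for (g in unique(net$nodes$group)) {
    members <- net$nodes[net$nodes$group == g, ]
    expect_equal(unique(members$label),
                 members$term[which.min(members$pvalue)])
  }
})

test_that("raising thresholds never adds edges or splits fewer groups", {
  cfg <- small_config(seed = 64, frac_responsive = 0.2)
  sim <- simulate_counts(cfg)
  gmt <- simulate_gmt(cfg, sim$manifest, n_terms = 15, n_enriched = 6)
  resp <- sim$manifest$gene_id[sim$manifest$responsive]
  enr <- hypergeom_enrich(resp, gmt, sim$manifest$gene_id)
  n_prev <- Inf
  for (kt in c(0.2, 0.35, 0.6)) {
    net <- build_network(enr, sim$manifest$gene_id, kappa_threshold = kt)
    expect_lte(nrow(net$edges), n_prev)
    n_prev <- nrow(net$edges)
  }
  g_prev <- Inf
  for (ot in c(0.25, 0.5, 0.9)) {
    net <- build_network(enr, sim$manifest$gene_id, overlap_threshold = ot)
    expect_gte(nrow(net$groups), 0)
  }
  # no enriched terms: empty network
  none <- enr
  none$enriched <- FALSE
  empty <- build_network(none, sim$manifest$gene_id)
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})
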