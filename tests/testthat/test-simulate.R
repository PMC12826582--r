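test_that("simulation is deterministic per seed and per output stream", {
  cfg <- small_config(seed = 42)
  expect_identical(simulate_morphology(cfg), simulate_morphology(cfg))
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$manifest, s2$manifest)
  g1 <- simulate_gmt(cfg, s1$manifest, n_terms = 8)
  g2 <- simulate_gmt(cfg, s1$manifest, n_terms = 8)
  expect_identical(g1, g2)
  # different seeds give different draws
  expect_false(identical(simulate_morphology(small_config(seed = 43)),
                         simulate_morphology(cfg)))
})

test_that("morphology plates have the study's well layout", {
  cfg <- small_config(seed = 1)
  wells <- simulate_morphology(cfg)
  per_ep <- dplyr::count(wells, endpoint)
  # 12 concentrations x 14 wells + 24 controls = 192 wells per endpoint
  expect_true(all(per_ep$n == 14 * 12 + 24))
  ctrl <- dplyr::filter(wells, concentration_uM == 0, endpoint == "x_fin")
  expect_equal(nrow(ctrl), 24)
})

test_that("a steep incidence curve behaves as a step at the BMC", {
  cfg <- small_config(
    seed = 7,
    morpho_endpoints = tibble::tibble(
      endpoint = "x_fin", background = 0, bmc20 = 1, slope = 200
    ),
    morpho_concentrations = c(0.1, 0.2, 0.5, 2, 5, 10)
  )
  tab <- validate_morphology(simulate_morphology(cfg))
  below <- dplyr::filter(tab, concentration_uM < 1)
  above <- dplyr::filter(tab, concentration_uM > 1)
  expect_true(all(below$n_affected == 0))
  expect_true(all(above$n_affected == above$n_total))
})

test_that("simulated incidence is calibrated to the inverse log-logistic", {
  # g = 0.05, true BMC20 = 0.3, b = 3: closed-form incidence at the BMC is
  # g + (1 - g) * 0.2 = 0.24; Monte-Carlo mean over seeds must agree
  hits <- vapply(1:200, function(s) {
    cfg <- sim_config(
      seed = s, n_genes = 2,
      morpho_endpoints = tibble::tibble(
        endpoint = "x_fin", background = 0.05, bmc20 = 0.3, slope = 3
      ),
      morpho_concentrations = c(0.3),
      n_per_concentration = 14
    )
    w <- simulate_morphology(cfg)
    sum(w$affected[w$concentration_uM == 0.3])
  }, numeric(1))
  n_draws <- 200 * 14
  p_hat <- sum(hits) / n_draws
  p_true <- 0.05 + 0.95 * 0.2
  se <- sqrt(p_true * (1 - p_true) / n_draws)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("count matrix has the design dimensions and valid metadata", {
  cfg <- sim_config(seed = 2, n_genes = 120)
  sim <- simulate_counts(cfg)
  # 4 reps x 4 doses x 2 timepoints = 32 samples
  expect_equal(dim(sim$counts), c(120, 32))
  expect_identical(colnames(sim$counts), sim$metadata$sample_id)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_equal(unname(sim$metadata$lib_size), unname(colSums(sim$counts)))
  # library sizes within 3-fold by construction
  expect_lte(max(sim$metadata$lib_size) / min(sim$metadata$lib_size), 3.5)
})

test_that("ground-truth manifest matches its invariants", {
  cfg <- sim_config(seed = 3, n_genes = 500, frac_responsive = 0.1,
                    timepoints = 48)
  sim <- simulate_counts(cfg)
  man <- sim$manifest
  resp <- man[man$responsive, ]
  null <- man[!man$responsive, ]
  expect_true(all(is.finite(resp$true_bmc)))
  expect_true(all(is.na(null$true_bmc)))
  # true BMCs inside or above the tested range, never below
  expect_true(all(resp$true_bmc >= 0.133))
  # Linear-family genes: closed-form truth BMC = 1.35 sigma / |slope|
  lin <- resp[resp$family == "Linear", ]
  expect_gt(nrow(lin), 0)
  expect_equal(lin$true_bmc, 1.35 * lin$sigma / abs(lin$par_b),
               tolerance = 1e-12)
})

test_that("frac_responsive = 0 gives an all-null manifest", {
  cfg <- sim_config(seed = 4, n_genes = 100, frac_responsive = 0,
                    timepoints = 48)
  sim <- simulate_counts(cfg)
  expect_true(all(is.na(sim$manifest$true_bmc)))
  expect_false(any(sim$manifest$responsive))
})

test_that("null-gene count marginals are NB-consistent (method of moments)", {
  cfg <- sim_config(
    seed = 5, n_genes = 400, frac_responsive = 0, timepoints = 48,
    concentrations = c(0, 1), n_replicates = 12
  )
  sim <- simulate_counts(cfg)
  lib <- sim$metadata$lib_size
  norm <- sweep(sim$counts, 2, lib / mean(lib), "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1, var)
  phi_hat <- (v - m) / m^2
  # moment estimates scatter around the generating dispersion trend
  ratio <- phi_hat / sim$manifest$dispersion
  expect_gt(median(ratio), 0.6)
  expect_lt(median(ratio), 1.6)
})

test_that("simulated GMT files are structurally valid, including empty ones", {
  cfg <- small_config(seed = 6)
  sim <- simulate_counts(cfg)
  gmt <- simulate_gmt(cfg, sim$manifest, n_terms = 12, n_enriched = 3)
  expect_equal(nrow(gmt), 12)
  expect_true(all(lengths(gmt$genes) > 0))
  expect_true(all(unlist(gmt$genes) %in% sim$manifest$gene_id))
  expect_equal(sum(gmt$planted), 3)
  empty <- simulate_gmt(cfg, sim$manifest, n_terms = 0)
  expect_equal(nrow(empty), 0)
})
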