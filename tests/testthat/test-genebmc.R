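test_that("noise-free linear data is recovered exactly with vanishing s", {
  d <- study_doses()
  y <- 1 + 2 * d
  fit <- fit_family(y, d, "Linear")
  expect_equal(unname(fit$par["a"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$par["b"]), 2, tolerance = 1e-10)
  expect_lt(fit$s, 1e-8)
})

test_that("constant response yields no benchmark concentration", {
  d <- study_doses()
  y <- rep(5, length(d))
  fit <- fit_family(y, d, "Linear")
  res <- compute_bmc_sd(fit)
  expect_true(is.na(res$bmc))
  expect_false(res$in_range)
})

test_that("numeric BMC matches the closed form for monotone families", {
  set.seed(41)
  d <- study_doses()
  for (i in 1:60) {
    sigma <- runif(1, 0.1, 0.6)
    fam <- sample(c("Linear", "Power", "Exp2"), 1)
    y <- switch(fam,
      Linear = runif(1, 2, 8) + runif(1, 0.05, 0.5) * d,
      Power = runif(1, 2, 8) + runif(1, 0.02, 0.3) * d^runif(1, 1, 2.5),
      Exp2 = runif(1, 2, 8) * exp(runif(1, 0.01, 0.15) * d)
    ) + rnorm(length(d), sd = sigma)
    fit <- fit_family(y, d, fam)
    num <- compute_bmc_sd(fit, d_max = max(d))
    if (is.na(num$bmc)) next
    target <- 1.35 * fit$s
    ana <- switch(fam,
      Linear = target / abs(fit$par[["b"]]),
      Power = (target / abs(fit$par[["b"]]))^(1 / fit$par[["g"]]),
      Exp2 = {
        a <- fit$par[["a"]]
        b <- fit$par[["b"]]
        if (b > 0) log(1 + target / a) / b else -log(1 - target / a) / b
      }
    )
    expect_lt(abs(num$bmc - ana) / ana, 1e-9)
  }
})

test_that("AIC selection is parsimonious and never picks a dominated fit", {
  d <- study_doses()
  set.seed(42)
  y <- 3 + 0.2 * d + rnorm(length(d), sd = 0.3)
  fits <- fit_all_families(y, d)
  single <- select_best_aic(fits["Linear"])
  expect_equal(single$family, "Linear")
  best <- select_best_aic(fits)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  expect_equal(best$aic, min(aics))
  # a fit with lower log-likelihood and equal k can never win
  same_k <- fits[vapply(fits, `[[`, numeric(1), "k") == best$k]
  expect_true(all(vapply(same_k, `[[`, numeric(1), "loglik") <=
                    best$loglik + 1e-9))
})

test_that("AIC prefers Linear over Poly2 on linear truth", {
  d <- rep(c(0, 0.133, 1.33, 13.3), each = 8) # n = 32
  wins <- vapply(1:500, function(s) {
    set.seed(s)
    y <- 2 + 0.15 * d + rnorm(length(d), sd = 0.2)
    select_best_aic(fit_all_families(y, d, c("Linear", "Poly2")))$family
  }, character(1))
  expect_gte(mean(wins == "Linear"), 0.7)
})

test_that("Exp4 truth keeps Exp4 competitive under AIC", {
  d <- study_doses()
  ok <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    y <- 8 * (1.5 - 0.5 * exp(-1 * d)) + rnorm(length(d), sd = 0.1)
    fits <- fit_all_families(y, d)
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    aics[["Exp4"]] <= min(aics) + 2
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("bootstrap CIs are deterministic and track sampling variability", {
  d <- study_doses()
  set.seed(43)
  y <- 4 + 0.2 * d + rnorm(length(d), sd = 0.3)
  fit <- fit_family(y, d, "Linear")
  bmc <- compute_bmc_sd(fit)$bmc
  ci1 <- bootstrap_ci(y, d, "Linear", B = 100, seed = 5)
  ci2 <- bootstrap_ci(y, d, "Linear", B = 100, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(ci1$defined)
  expect_lt(ci1$bmcl, bmc * 1.05)
  expect_gt(ci1$bmcu, bmc * 0.95)
  # replicate-identical (zero-noise) data has no resampling variability:
  # every refit is flat-residual, the BMC is undefined and so is the CI
  y0 <- 4 + 0.2 * d
  ci0 <- bootstrap_ci(y0, d, "Linear", B = 50, seed = 5)
  expect_false(ci0$defined)
})

test_that("BMCs are equivariant under dose rescaling", {
  d <- study_doses()
  set.seed(44)
  y <- 5 + 0.12 * d + rnorm(length(d), sd = 0.3)
  kappa <- 3
  for (fam in c("Linear", "Power")) {
    f1 <- fit_family(y, d, fam)
    f2 <- fit_family(y, kappa * d, fam)
    b1 <- compute_bmc_sd(f1, d_max = max(d))
    b2 <- compute_bmc_sd(f2, d_max = kappa * max(d))
    expect_equal(b2$bmc, kappa * b1$bmc, tolerance = 1e-6)
  }
  c1 <- bootstrap_ci(y, d, "Linear", B = 60, seed = 6)
  c2 <- bootstrap_ci(y, kappa * d, "Linear", B = 60, seed = 6,
                     d_max = kappa * max(d))
  expect_equal(c2$bmcl, kappa * c1$bmcl, tolerance = 1e-6)
  expect_equal(c2$bmcu, kappa * c1$bmcu, tolerance = 1e-6)
})

test_that("the filter cascade applies the three printed rules exactly", {
  rec <- tibble::tibble(
    gene_id = c("ratio45", "ratio40", "poly2", "out_of_range", "good"),
    best_model = c("Linear", "Exp2", "Poly2", "Linear", "Power"),
    bmc_uM = c(1, 1, 1, 20, 2),
    bmcl_uM = c(0.1, 0.1, 0.5, 5, 1),
    bmcu_uM = c(4.5, 4.0, 1.5, 60, 3)
  )
  out <- apply_cr_filters(rec, d_max = 13.3)
  expect_false(out$ci_ok[out$gene_id == "ratio45"])   # 45 > 40
  expect_true(out$ci_ok[out$gene_id == "ratio40"])    # boundary inclusive
  expect_false(out$monotonic_ok[out$gene_id == "poly2"])
  expect_false(out$in_range[out$gene_id == "out_of_range"])
  expect_true(out$has_cr[out$gene_id == "good"])
  expect_equal(out$has_cr,
               out$in_range & out$ci_ok & out$monotonic_ok)
})

test_that("fit_gene_bmc returns coherent records on simulated genes", {
  cfg <- sim_config(seed = 45, n_genes = 80, frac_responsive = 0.2,
                    timepoints = 48)
  sim <- simulate_counts(cfg)
  nm <- log2cpm(filter_low_counts(sim$counts), tmm_factors(
    filter_low_counts(sim$counts)
  ))
  genes <- sim$manifest$gene_id[sim$manifest$responsive][1:6]
  rec <- fit_gene_bmc(nm$log2cpm, sim$metadata$concentration_uM,
                      genes = genes, B = 60, seed = 2)
  expect_equal(rec$gene_id, genes)
  fin <- is.finite(rec$bmcl_uM) & is.finite(rec$bmcu_uM) &
    is.finite(rec$bmc_uM)
  expect_true(all(rec$bmcl_uM[fin] <= rec$bmc_uM[fin] * (1 + 1e-9)))
  expect_true(all(rec$bmc_uM[fin] <= rec$bmcu_uM[fin] * (1 + 1e-9)))
})
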