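test_that("low-count filter applies the >=5-reads-in->=2-samples rule", {
  m <- rbind(
    keep_boundary = c(5L, 5L, 0L, 0L),
    drop_boundary = c(5L, 4L, 0L, 0L),
    all_zero = c(0L, 0L, 0L, 0L),
    keep_high = c(100L, 80L, 60L, 40L)
  )
  colnames(m) <- paste0("s", 1:4)
  kept <- filter_low_counts(m)
  expect_setequal(rownames(kept), c("keep_boundary", "keep_high"))
  expect_error(filter_low_counts(m[3, , drop = FALSE]), "no genes")
})

test_that("low-count filter matches a brute-force scan on random matrices", {
  set.seed(21)
  m <- matrix(rnbinom(300 * 6, mu = 3, size = 1), 300, 6,
              dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:6)))
  kept <- rownames(filter_low_counts(m))
  oracle <- rownames(m)[vapply(seq_len(nrow(m)), function(i) {
    sum(m[i, ] >= 5) >= 2
  }, logical(1))]
  expect_identical(kept, oracle)
})

test_that("TMM factors are composition-neutral and geometric-mean one", {
  set.seed(22)
  base <- rnbinom(50, mu = 100, size = 10) + 1L
  m <- cbind(s1 = base, s2 = base, s3 = base)
  expect_equal(unname(tmm_factors(m)), rep(1, 3))
  # doubling every count is pure library-size scaling: factors stay 1
  m2 <- cbind(s1 = base, s2 = 2L * base)
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
  cfg <- small_config(seed = 23)
  sim <- simulate_counts(cfg)
  f <- tmm_factors(filter_low_counts(sim$counts))
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("TMM factors equal a hand computation of the trimmed weighted mean", {
  set.seed(7)
  m <- matrix(rnbinom(20 * 3, mu = 200, size = 5) + 1L, 20, 3,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  lib <- colSums(m)
  uq <- apply(m, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  hand_pair <- function(obs, ref_c, No, Nr) {
    keep <- obs > 0 & ref_c > 0
    obs <- obs[keep]
    ref_c <- ref_c[keep]
    M <- log2((obs / No) / (ref_c / Nr))
    A <- 0.5 * log2((obs / No) * (ref_c / Nr))
    v <- (No - obs) / (No * obs) + (Nr - ref_c) / (Nr * ref_c)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1
    hiA <- n + 1 - loA
    tk <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[tk] / v[tk]) / sum(1 / v[tk]))
  }
  f_hand <- vapply(1:3, function(j) {
    hand_pair(m[, j], m[, ref], lib[j], lib[ref])
  }, numeric(1))
  f_hand <- f_hand / exp(mean(log(f_hand)))
  expect_equal(unname(tmm_factors(m)), f_hand, tolerance = 1e-10)
})

test_that("log2 CPM follows its defining formula and is monotone", {
  m <- matrix(c(100L, 0L, 5L), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  # force the library to 1e6 by padding a pseudo-gene
  m <- rbind(m, filler = 1e6L - 105L)
  nm <- log2cpm(m, prior = 0.5)
  expect_equal(unname(nm$log2cpm["a", 1]),
               log2(100.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_true(all(is.finite(nm$log2cpm)))
  # monotone in counts within a sample
  expect_true(nm$log2cpm["a", 1] > nm$log2cpm["c", 1])
  expect_true(nm$log2cpm["c", 1] > nm$log2cpm["b", 1])
})

test_that("log2 CPM is stable under joint count/library doubling", {
  set.seed(24)
  counts <- matrix(rnbinom(100, mu = 500, size = 10) + 100L, 100, 1,
                   dimnames = list(sprintf("g%03d", 1:100), "s1"))
  a <- log2cpm(counts)$log2cpm
  b <- log2cpm(2L * counts)$log2cpm
  # only the prior breaks exact invariance; counts >= 100 keep it tiny
  expect_lt(max(abs(a - b)), 0.01)
})

test_that("PCA QC separates timepoints and keeps orthonormal loadings", {
  cfg <- sim_config(seed = 25, n_genes = 300, tp_shift_sd = 2)
  sim <- simulate_counts(cfg)
  nm <- log2cpm(filter_low_counts(sim$counts))
  pc <- pca_qc(nm, sim$metadata)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-8)
  expect_true(all(abs(crossprod(pc$rotation) - diag(ncol(pc$rotation))) <
                    1e-8))
  # the two timepoint blocks separate on PC1
  s48 <- pc$scores$PC1[pc$scores$timepoint_hpf == 48]
  s72 <- pc$scores$PC1[pc$scores$timepoint_hpf == 72]
  expect_true(max(s48) < min(s72) || min(s48) > max(s72))
})

test_that("duplicated samples coincide in PCA space", {
  set.seed(26)
  m <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  m <- cbind(m, s5 = m[, 1])
  pc <- pca_qc(m)
  expect_lt(max(abs(pc$scores[pc$scores$sample_id == "s1", 2:4] -
                      pc$scores[pc$scores$sample_id == "s5", 2:4])), 1e-8)
})
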