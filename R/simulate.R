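#' Simulation configuration
#'
#' Describes one synthetic study: a pooled-embryo RNA-seq design (one
#' chemical at several concentrations and timepoints, replicate pools of
#' embryos) plus 96-well dichotomous morphology plates. Defaults mirror the
#' study design the package targets: 4 replicate pools of 6 embryos per
#' chemical x concentration (0, 0.133, 1.33, 13.3 uM) x timepoint (48, 72
#' hpf), ~18,000 expressed genes of which a small fraction carry a monotonic
#' concentration response with known BMC, and morphology plates with 12
#' concentrations at n = 14 wells each plus n = 24 controls.
#'
#' @param seed integer; fixes every random draw. Each output type uses its
#'   own RNG stream derived from `(seed, tag)`, so generating one output
#'   never perturbs another.
#' @param n_genes number of genes.
#' @param concentrations exposure concentrations in uM, strictly increasing,
#'   first entry 0 (control).
#' @param timepoints sampling timepoints in hpf.
#' @param n_replicates replicate pools per concentration x timepoint.
#' @param pool_size embryos per pool (metadata only; pooling noise is folded
#'   into the dispersion).
#' @param frac_responsive fraction of genes with a true dose-response.
#' @param model_mix named proportions over the six model families; only
#'   monotone families carry weight by default (Poly2 responses are
#'   non-monotonic and the emulated truth is monotone).
#' @param true_bmc_range range (uM) from which true gene BMCs are drawn
#'   (log-uniform).
#' @param dispersion_params `c(asymptotic, trend)`: NB dispersion
#'   `phi(mu) = asymptotic + trend / mu`, decreasing in the mean.
#' @param morpho_endpoints data frame with columns `endpoint`, `background`
#'   (rate g in `[0,1)`), `bmc20` (true BMC at 20% extra risk, uM) and
#'   `slope` (log-logistic slope b > 0).
#' @param morpho_concentrations nonzero plate concentrations (uM).
#' @param n_per_concentration wells per nonzero concentration.
#' @param n_controls control wells.
#' @param chemical,line labels carried into outputs.
#' @param baseline_log2cpm range of baseline gene expression (log2 CPM).
#' @param libsize_range range of library sizes; at most 3-fold spread.
#' @param tp_shift_sd SD of developmental (timepoint) log2 shifts applied to
#'   half of the genes; drives the timepoint separation seen in PCA QC.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 500)
#' cfg$n_replicates
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 18000L,
                       concentrations = c(0, 0.133, 1.33, 13.3),
                       timepoints = c(48, 72),
                       n_replicates = 4L,
                       pool_size = 6L,
                       frac_responsive = 0.05,
                       model_mix = c(
                         Exp2 = 0.2, Exp3 = 0.2, Exp4 = 0.2,
                         Linear = 0.2, Poly2 = 0, Power = 0.2
                       ),
                       true_bmc_range = c(0.15, 10),
                       dispersion_params = c(asymptotic = 0.01, trend = 3),
                       morpho_endpoints = default_morpho_endpoints(),
                       morpho_concentrations = signif(
                         10^seq(log10(0.1), log10(13.3), length.out = 12), 3
                       ),
                       n_per_concentration = 14L,
                       n_controls = 24L,
                       chemical = "chemA",
                       line = "wildtype",
                       baseline_log2cpm = c(2, 9),
                       libsize_range = c(4e6, 1.2e7),
                       tp_shift_sd = 1) {
  morpho_endpoints <- as_tibble(morpho_endpoints)
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_genes >= 1,
    length(concentrations) >= 2,
    all(diff(concentrations) > 0),
    concentrations[1] >= 0,
    frac_responsive >= 0, frac_responsive <= 1,
    all(model_mix >= 0), sum(model_mix) > 0,
    length(true_bmc_range) == 2, true_bmc_range[1] > 0,
    true_bmc_range[2] >= true_bmc_range[1],
    all(dispersion_params >= 0),
    all(c("endpoint", "background", "bmc20", "slope") %in%
      names(morpho_endpoints)),
    all(morpho_endpoints$background >= 0),
    all(morpho_endpoints$background < 1),
    all(morpho_endpoints$bmc20 > 0),
    all(morpho_concentrations > 0),
    n_per_concentration >= 1, n_controls >= 1,
    libsize_range[1] > 0,
    libsize_range[2] / libsize_range[1] <= 3 + 1e-9
  )
  if (any(morpho_endpoints$slope <= 0)) {
    abort("morphology endpoint slopes must be positive (b > 0)")
  }
  mix <- model_mix / sum(model_mix)
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      concentrations = concentrations, timepoints = timepoints,
      n_replicates = as.integer(n_replicates),
      pool_size = as.integer(pool_size),
      frac_responsive = frac_responsive, model_mix = mix,
      true_bmc_range = true_bmc_range,
      dispersion_params = unname(dispersion_params),
      morpho_endpoints = morpho_endpoints,
      morpho_concentrations = morpho_concentrations,
      n_per_concentration = as.integer(n_per_concentration),
      n_controls = as.integer(n_controls),
      chemical = chemical, line = line,
      baseline_log2cpm = baseline_log2cpm,
      libsize_range = libsize_range,
      tp_shift_sd = tp_shift_sd
    ),
    class = "sim_config"
  )
}

#' Default morphology endpoint truth
#'
#' Five endpoints with above-background incidence, parameterized near the
#' potencies observed for the active chemical: the caudal-fin duplication
#' (x-fin) phenotype is the most potent endpoint, with edema, cranial and
#' axis malformations and mortality appearing at higher concentrations.
#'
#' @return Tibble with columns `endpoint`, `background`, `bmc20`, `slope`.
#' @export
default_morpho_endpoints <- function() {
  tibble(
    endpoint = c("x_fin", "edema", "cranial", "axis", "mortality"),
    background = c(0.01, 0.02, 0.02, 0.03, 0.04),
    bmc20 = c(0.28, 4, 6, 8, 10),
    slope = c(3, 3, 3, 2.5, 2.5)
  )
}

# Exact SD of log2(count + prior) for NB(mu, size = 1/phi), by pmf
# summation (delta-method fallback for very large means, where the
# approximation is excellent). This is the noise scale on which the
# generator defines the benchmark response, so the true BMC sits exactly
# at the 1.35-SD crossing on the fitted (log2 CPM) scale.
sigma_log2_nb <- function(mu, phi, prior = 0.5) {
  vapply(seq_along(mu), function(i) {
    m <- mu[i]
    ph <- phi[i]
    if (m > 5000) {
      return(sqrt(m + ph * m^2) / ((m + prior) * log(2)))
    }
    kmax <- stats::qnbinom(1e-12, size = 1 / ph, mu = m,
                           lower.tail = FALSE)
    k <- 0:kmax
    w <- stats::dnbinom(k, size = 1 / ph, mu = m)
    x <- log2(k + prior)
    ex <- sum(w * x)
    sqrt(max(sum(w * x^2) - ex^2, 0))
  }, numeric(1))
}

# log-logistic incidence: p(d) = g + (1-g) / (1 + exp(-a - b log d)), p(0)=g
# a is recovered from (bmc20, b) by the extra-risk identity at R = 0.2.
loglogistic_p <- function(d, g, a, b) {
  p <- rep(g, length(d))
  pos <- d > 0
  p[pos] <- g + (1 - g) * plogis(a + b * log(d[pos]))
  p
}

intercept_from_bmc <- function(bmc, b, R = 0.2) {
  log(R / (1 - R)) - b * log(bmc)
}

#' Simulate dichotomous morphology plates
#'
#' Draws per-well affected/unaffected outcomes for each endpoint from a
#' three-parameter log-logistic incidence curve
#' `p(d) = g + (1 - g) / (1 + exp(-a - b log d))` with `p(0) = g`, where the
#' intercept `a` is derived from the endpoint's true BMC20 and slope through
#' the extra-risk identity. Wells are independent; there are no plate
#' effects.
#'
#' @param config a [sim_config()].
#' @return Tibble with one row per well x endpoint: `line`, `chemical`,
#'   `concentration_uM`, `timepoint_hpf`, `well`, `endpoint`, `affected`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' wells <- simulate_morphology(cfg)
#' nrow(wells) # wells per endpoint x endpoints
#' @export
simulate_morphology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  doses <- c(0, config$morpho_concentrations)
  n_wells <- c(config$n_controls,
               rep(config$n_per_concentration,
                   length(config$morpho_concentrations)))
  with_stream(config$seed, "morphology", {
    purrr::pmap_dfr(config$morpho_endpoints, function(endpoint, background,
                                                      bmc20, slope, ...) {
      a <- intercept_from_bmc(bmc20, slope)
      p <- loglogistic_p(doses, background, a, slope)
      tibble(
        line = config$line,
        chemical = config$chemical,
        concentration_uM = rep(doses, n_wells),
        timepoint_hpf = 120,
        well = unlist(lapply(n_wells, seq_len)),
        endpoint = endpoint,
        affected = rbinom(sum(n_wells), 1L, rep(p, n_wells))
      )
    })
  })
}

# Deviation-from-baseline dose curves used by the generator; `delta` is the
# benchmark response 1.35 * sigma attained exactly at the true BMC.
#
# Parameters are drawn so the implied deviation at the top tested dose
# stays below `a_max` log2 units: unbounded shapes (Linear, Power,
# upward exponentials) are only feasible for genes whose BMC is large
# enough relative to the dose range; potent genes fall back to the
# saturating Exp4 shape, mirroring how strongly responding genes plateau
# in real dose-response transcriptomics.
truth_family_feasible <- function(family, base, delta, bmc, direction,
                                  dmax, a_max) {
  r <- dmax / bmc
  up <- direction > 0
  switch(family,
    Linear = delta * r <= a_max,
    Power = delta * r <= a_max,                      # minimal growth at g = 1
    Poly2 = delta * r^2 / 2 <= a_max,
    Exp2 = if (up) base * ((1 + delta / base)^r - 1) <= a_max else TRUE,
    Exp3 = if (up) base * ((1 + delta / base)^r - 1) <= a_max else TRUE,
    Exp4 = TRUE
  )
}

gene_truth_params <- function(family, base, delta, bmc, direction,
                              dmax, a_max = 6) {
  up <- direction > 0
  r <- dmax / bmc
  switch(family,
    Linear = list(b = direction * delta / bmc, g = NA_real_, c = NA_real_),
    Power = {
      g_hi <- if (r > 1) {
        min(3, log(a_max / delta) / log(r))
      } else {
        3
      }
      g <- runif(1, 1, max(1, g_hi))
      list(b = direction * delta / bmc^g, g = g, c = NA_real_)
    },
    Exp2 = {
      b <- if (up) log(1 + delta / base) / bmc else {
        -log(1 - pmin(delta / base, 0.8)) / bmc
      }
      list(b = direction * b, g = NA_real_, c = NA_real_)
    },
    Exp3 = {
      target <- if (up) log(1 + delta / base) else {
        -log(1 - pmin(delta / base, 0.8))
      }
      g_hi <- if (up && r > 1) {
        min(3, log(log(1 + a_max / base) / target) / log(r))
      } else {
        3
      }
      g <- runif(1, 1, max(1, g_hi))
      list(b = direction * target^(1 / g) / bmc, g = g, c = NA_real_)
    },
    Exp4 = {
      p_hi <- if (up) max(2.5 * delta, min(a_max, 4)) else {
        max(1.5 * delta, min(0.8 * base, 4))
      }
      plateau <- runif(1, 1.5 * delta, max(1.5 * delta, p_hi))
      b <- -log(1 - delta / plateau) / bmc
      cc <- if (up) 1 + plateau / base else 1 - plateau / base
      list(b = b, g = NA_real_, c = cc)
    },
    Poly2 = {
      # non-monotonic: rises to a peak at 2 * bmc then returns; crosses
      # delta exactly at bmc
      bb <- 2 * delta / bmc
      list(b = direction * bb, g = NA_real_, c = -direction * bb / (4 * bmc))
    },
    abort(paste0("unknown model family: ", family))
  )
}

gene_truth_curve <- function(d, family, base, b, g, cc) {
  switch(family,
    Linear = base + b * d,
    Power = base + b * d^g,
    Exp2 = base * exp(sign(b) * abs(b) * d),
    Exp3 = base * exp(sign(b) * (abs(b) * d)^g),
    Exp4 = base * (cc - (cc - 1) * exp(-b * d)),
    Poly2 = base + b * d + cc * d^2
  )
}

#' Simulate a pooled-embryo count matrix with known dose-response truth
#'
#' Generates a gene-by-sample raw count matrix for one chemical. Baseline
#' log2 CPM is uniform over `config$baseline_log2cpm`; a fraction
#' `frac_responsive` of genes is assigned a monotone model family whose
#' parameters are chosen so the log2 expression deviation at the gene's true
#' BMC equals `1.35 * sigma_g`, where `sigma_g` is the per-gene residual SD
#' implied by the NB dispersion trend (delta method on log2 counts). Counts
#' are negative binomial with dispersion `phi(mu) = asymptotic + trend/mu`;
#' library sizes vary at most 3-fold. Half of the genes receive a
#' developmental (timepoint) shift so timepoints separate in PCA, as in real
#' whole-embryo data.
#'
#' @param config a [sim_config()].
#' @return List with `counts` (integer matrix, genes x samples), `metadata`
#'   (tibble: `sample_id`, `chemical`, `concentration_uM`, `timepoint_hpf`,
#'   `replicate`, `lib_size`) and `manifest` (tibble of per-gene truth:
#'   family, parameters, `true_bmc` in uM or `NA` for non-responsive genes,
#'   baseline, `sigma`, `dispersion`).
#' @examples
#' sim <- simulate_counts(sim_config(seed = 1, n_genes = 200))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_resp <- round(config$frac_responsive * config$n_genes)
  if (config$frac_responsive > 0 && n_resp < 1) {
    warn("frac_responsive * n_genes < 1; generating an all-null matrix")
    n_resp <- 0
  }
  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
  doses <- config$concentrations
  tps <- config$timepoints
  n_rep <- config$n_replicates
  mean_lib <- mean(config$libsize_range)

  with_stream(config$seed, "counts", {
    base <- runif(config$n_genes, config$baseline_log2cpm[1],
                  config$baseline_log2cpm[2])
    mu0 <- 2^base * mean_lib / 1e6
    phi <- config$dispersion_params[1] + config$dispersion_params[2] / mu0
    sigma <- sigma_log2_nb(mu0, phi)

    responsive <- sort(sample.int(config$n_genes, n_resp))
    is_resp <- seq_len(config$n_genes) %in% responsive
    family <- rep(NA_character_, config$n_genes)
    true_bmc <- rep(NA_real_, config$n_genes)
    direction <- rep(NA_real_, config$n_genes)
    par_b <- par_g <- par_c <- rep(NA_real_, config$n_genes)
    if (n_resp > 0) {
      fam_pool <- names(config$model_mix)
      dmax <- max(doses)
      family[responsive] <- sample(fam_pool, n_resp, replace = TRUE,
                                   prob = config$model_mix)
      true_bmc[responsive] <- exp(runif(
        n_resp, log(config$true_bmc_range[1]), log(config$true_bmc_range[2])
      ))
      direction[responsive] <- sample(c(-1, 1), n_resp, replace = TRUE)
      for (i in responsive) {
        if (!truth_family_feasible(family[i], base[i], 1.35 * sigma[i],
                                   true_bmc[i], direction[i], dmax, 6)) {
          family[i] <- "Exp4"
        }
        pars <- gene_truth_params(
          family[i], base[i], 1.35 * sigma[i], true_bmc[i], direction[i],
          dmax
        )
        par_b[i] <- pars$b; par_g[i] <- pars$g; par_c[i] <- pars$c
      }
    }

    design <- tidyr::expand_grid(
      timepoint_hpf = tps, concentration_uM = doses,
      replicate = seq_len(n_rep)
    )
    design$sample_id <- sprintf(
      "%s_t%g_c%g_r%d", config$chemical, design$timepoint_hpf,
      design$concentration_uM, design$replicate
    )
    lib <- runif(nrow(design), config$libsize_range[1],
                 config$libsize_range[2])

    # developmental shift per gene x timepoint (first timepoint = reference)
    shifted <- runif(config$n_genes) < 0.5
    tp_shift <- matrix(0, config$n_genes, length(tps))
    if (length(tps) > 1) {
      for (k in 2:length(tps)) {
        tp_shift[shifted, k] <- rnorm(sum(shifted), 0, config$tp_shift_sd)
      }
    }

    counts <- matrix(0L, config$n_genes, nrow(design),
                     dimnames = list(gene_ids, design$sample_id))
    for (j in seq_len(nrow(design))) {
      d <- design$concentration_uM[j]
      k <- match(design$timepoint_hpf[j], tps)
      mu_log2 <- base + tp_shift[, k]
      if (n_resp > 0) {
        for (i in responsive) {
          dev <- gene_truth_curve(
            d, family[i], base[i], par_b[i], par_g[i], par_c[i]
          ) - base[i]
          # numeric guard only; parameter draws keep |dev| <= 6 by design
          mu_log2[i] <- base[i] + tp_shift[i, k] + pmin(pmax(dev, -10), 10)
        }
      }
      mu_count <- 2^mu_log2 * lib[j] / 1e6
      counts[, j] <- as.integer(
        rnbinom(config$n_genes, mu = mu_count, size = 1 / phi)
      )
    }

    manifest <- tibble(
      gene_id = gene_ids, responsive = is_resp, family = family,
      true_bmc = true_bmc, direction = direction,
      par_b = par_b, par_g = par_g, par_c = par_c,
      base_log2cpm = base, sigma = sigma, dispersion = phi
    )
    list(
      counts = counts,
      metadata = tibble(
        sample_id = design$sample_id, chemical = config$chemical,
        concentration_uM = design$concentration_uM,
        timepoint_hpf = design$timepoint_hpf, replicate = design$replicate,
        lib_size = unname(colSums(counts))
      ),
      manifest = manifest
    )
  })
}

#' Simulate a gene-set annotation (GMT)
#'
#' Builds a term-to-gene-set annotation over the simulated gene universe.
#' `n_enriched` terms are planted in the responsive-gene pool (each drawn
#' mostly from responsive genes) so that downstream enrichment of the
#' responsive set recovers them; the remaining terms are random draws from
#' the whole universe and behave as null terms.
#'
#' @param config a [sim_config()].
#' @param manifest per-gene truth from [simulate_counts()]; computed from
#'   `config` if omitted.
#' @param n_terms total number of terms.
#' @param n_enriched number of planted (truly enriched) terms.
#' @param term_size range of term sizes.
#' @param planted_frac fraction of each planted term drawn from responsive
#'   genes.
#' @return Tibble with columns `term`, `description`, `genes` (list-column),
#'   and a logical `planted` flag.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 300)
#' sim <- simulate_counts(cfg)
#' gmt <- simulate_gmt(cfg, sim$manifest, n_terms = 10)
#' @export
simulate_gmt <- function(config, manifest = NULL, n_terms = 50,
                         n_enriched = 5, term_size = c(10, 60),
                         planted_frac = 0.8) {
  stopifnot(inherits(config, "sim_config"), n_terms >= 0)
  n_enriched <- min(n_enriched, n_terms)
  if (is.null(manifest)) manifest <- simulate_counts(config)$manifest
  genes <- manifest$gene_id
  resp <- manifest$gene_id[manifest$responsive]
  with_stream(config$seed, "gmt", {
    if (n_terms == 0) {
      return(tibble(term = character(), description = character(),
                    genes = list(), planted = logical()))
    }
    sizes <- sample(seq(term_size[1], term_size[2]), n_terms, replace = TRUE)
    planted <- seq_len(n_terms) <= n_enriched & length(resp) > 0
    sets <- lapply(seq_len(n_terms), function(i) {
      if (planted[i]) {
        k_resp <- min(length(resp), max(1, round(planted_frac * sizes[i])))
        unique(c(
          sample(resp, k_resp),
          sample(genes, sizes[i] - k_resp)
        ))
      } else {
        sample(genes, sizes[i])
      }
    })
    tibble(
      term = sprintf("TERM%03d", seq_len(n_terms)),
      description = ifelse(planted, "planted responsive-pool term",
                           "random background term"),
      genes = sets,
      planted = planted
    )
  })
}
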