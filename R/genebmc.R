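# Continuous dose-response model families (benchmark-dose conventions):
#   Linear  mu = a + b d
#   Poly2   mu = a + b d + c d^2
#   Power   mu = a + b d^g,                g in [1, 18]
#   Exp2    mu = a exp(b d),               a > 0 (b signed by trend)
#   Exp3    mu = a exp(s (b d)^g),         a > 0, b > 0, s = +/-1, g in [1, 18]
#   Exp4    mu = a (c - (c - 1) exp(-b d)), a > 0, b > 0, c > 0
# All are fitted by least squares (maximum likelihood under homoscedastic
# Normal errors with a per-gene variance).

bmd_families <- function() c("Exp2", "Exp3", "Exp4", "Linear", "Poly2", "Power")

family_mu <- function(d, family, par) {
  switch(family,
    Linear = par[["a"]] + par[["b"]] * d,
    Poly2 = par[["a"]] + par[["b"]] * d + par[["c"]] * d^2,
    Power = par[["a"]] + par[["b"]] * d^par[["g"]],
    Exp2 = par[["a"]] * exp(par[["b"]] * d),
    Exp3 = par[["a"]] * exp(par[["s"]] * (par[["b"]] * d)^par[["g"]]),
    Exp4 = par[["a"]] * (par[["c"]] - (par[["c"]] - 1) * exp(-par[["b"]] * d)),
    abort(paste0("unknown family: ", family))
  )
}

n_mean_params <- function(family) {
  switch(family, Linear = 2, Exp2 = 2, Power = 3, Exp3 = 3, Exp4 = 3,
         Poly2 = 3)
}

make_fit <- function(family, par, y, d, converged) {
  mu <- family_mu(d, family, par)
  sse <- sum((y - mu)^2)
  n <- length(y)
  k_mean <- n_mean_params(family)
  sigma2_mle <- max(sse / n, 1e-300)
  loglik <- -n / 2 * (log(2 * pi * sigma2_mle) + 1)
  s <- sqrt(sse / max(n - k_mean, 1))
  direction <- sign(family_mu(max(d), family, par) -
                      family_mu(0, family, par))
  structure(
    list(
      family = family, par = par, s = s, sse = sse, n = n,
      loglik = loglik, k = k_mean + 1,
      aic = 2 * (k_mean + 1) - 2 * loglik,
      direction = direction, converged = converged,
      doses = d, y = y
    ),
    class = "dose_response_fit"
  )
}

#' Fit one continuous dose-response model family to a gene
#'
#' Least-squares (Gaussian maximum-likelihood) fit of one of the six
#' benchmark-dose model families to per-sample expression values
#' (log2 CPM). Linear and quadratic families are solved exactly; the
#' nonlinear families use bounded quasi-Newton optimization from several
#' deterministic starts (coarse grids over the nonlinear parameters with
#' the linear ones profiled out at the start values). The sign of the
#' exponential families follows the observed dose trend.
#'
#' @param y numeric response per sample (log2 CPM).
#' @param doses dose per sample (uM), including 0 controls.
#' @param family one of `"Linear"`, `"Poly2"`, `"Power"`, `"Exp2"`,
#'   `"Exp3"`, `"Exp4"`.
#' @param start optional named start values (used by the bootstrap for warm
#'   restarts).
#' @return A `dose_response_fit`: family, parameters, residual SD `s`,
#'   log-likelihood, `aic` (`2k - 2 logLik` with `k` counting the variance
#'   parameter), response direction and convergence flag.
#' @examples
#' d <- rep(c(0, 0.133, 1.33, 13.3), each = 4)
#' y <- 1 + 2 * d + rnorm(16, sd = 0.1)
#' fit_family(y, d, "Linear")$par
#' @export
fit_family <- function(y, doses, family, start = NULL) {
  stopifnot(length(y) == length(doses), all(doses >= 0))
  if (length(unique(doses)) < 4 || !any(doses == 0)) {
    abort("need a control plus at least 3 nonzero dose groups")
  }
  d <- doses
  dmax <- max(d)
  # least-squares by QR on the raw design; lm() formula overhead matters
  # here because the bootstrap refits these models tens of thousands of
  # times
  ls_fit <- function(X) .lm.fit(cbind(1, X), y)$coefficients
  trend <- stats::cov(d, y) / stats::var(d)
  s_dir <- if (is.na(trend) || trend >= 0) 1 else -1

  if (family == "Linear") {
    cf <- ls_fit(d)
    return(make_fit("Linear", c(a = cf[1], b = cf[2]), y, d, TRUE))
  }
  if (family == "Poly2") {
    cf <- ls_fit(cbind(d, d^2))
    return(make_fit("Poly2", c(a = cf[1], b = cf[2], c = cf[3]),
                    y, d, TRUE))
  }
  if (family == "Power") {
    fit_g <- function(g) {
      dg <- d^g
      cf <- ls_fit(dg)
      sse <- sum((y - cf[1] - cf[2] * dg)^2)
      list(par = c(a = cf[1], b = cf[2], g = g), sse = sse)
    }
    gs <- if (!is.null(start)) start[["g"]] else c(1, 1.5, 2, 3, 5, 8)
    cands <- lapply(gs, fit_g)
    # polish the exponent around the best grid value
    best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "sse"))]]
    opt <- optimize(function(g) fit_g(g)$sse,
                    c(max(1, best$par[["g"]] - 1.5),
                      min(18, best$par[["g"]] + 1.5)), tol = 1e-10)
    final <- fit_g(opt$minimum)
    if (best$sse < final$sse) final <- best
    return(make_fit("Power", final$par, y, d, TRUE))
  }

  # exponential families: optimize transformed parameters with bounds
  a0 <- mean(y[d == 0])
  if (!is.finite(a0) || a0 <= 0) a0 <- max(mean(y), 1e-3)
  ytop <- mean(y[d == dmax])
  rel <- if (a0 > 0 && ytop > 0) log(ytop / a0) else 0

  sse_of <- function(par) {
    mu <- family_mu(d, family, par)
    if (any(!is.finite(mu))) return(1e30)
    sse <- sum((y - mu)^2)
    if (!is.finite(sse)) 1e30 else min(sse, 1e30)
  }

  if (family == "Exp2") {
    b0s <- if (!is.null(start)) abs(start[["b"]]) else {
      unique(pmax(pmin(c(abs(rel) / dmax, 0.1 / dmax, 1 / dmax,
                         4 / dmax, 10 / dmax, 40 / dmax), 1e3), 1e-8))
    }
    obj <- function(th) sse_of(c(a = exp(th[1]), b = s_dir * exp(th[2])))
    fits <- lapply(b0s, function(b0) {
      optim(c(log(a0), log(b0)), obj, method = "L-BFGS-B",
            lower = c(log(1e-6), log(1e-8)), upper = c(log(1e6), log(1e3)),
            control = list(maxit = 500))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    par <- c(a = exp(best$par[1]), b = s_dir * exp(best$par[2]))
    return(make_fit("Exp2", par, y, d, any(
      vapply(fits, function(f) f$convergence == 0, logical(1))
    )))
  }
  if (family == "Exp3") {
    starts <- if (!is.null(start)) {
      list(c(log(max(start[["a"]], 1e-6)), log(max(abs(start[["b"]]), 1e-8)),
             start[["g"]]))
    } else {
      grid <- tidyr::expand_grid(b0 = c(0.3, 1, 5, 20) / dmax, g0 = c(1, 2, 3))
      purrr::pmap(grid, function(b0, g0) c(log(a0), log(b0), g0))
    }
    obj <- function(th) {
      sse_of(c(a = exp(th[1]), b = exp(th[2]), g = th[3], s = s_dir))
    }
    fits <- lapply(starts, function(th0) {
      optim(th0, obj, method = "L-BFGS-B",
            lower = c(log(1e-6), log(1e-8), 1),
            upper = c(log(1e6), log(1e3), 18),
            control = list(maxit = 500))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    par <- c(a = exp(best$par[1]), b = exp(best$par[2]), g = best$par[3],
             s = s_dir)
    return(make_fit("Exp3", par, y, d, any(
      vapply(fits, function(f) f$convergence == 0, logical(1))
    )))
  }
  if (family == "Exp4") {
    c0 <- if (a0 > 0 && ytop > 0) ytop / a0 else 1.5
    c0 <- min(max(c0, 1e-3), 1e3)
    if (abs(c0 - 1) < 1e-3) c0 <- if (s_dir > 0) 1.2 else 0.8
    starts <- if (!is.null(start)) {
      list(c(log(max(start[["a"]], 1e-6)), log(max(start[["b"]], 1e-8)),
             log(max(start[["c"]], 1e-6))))
    } else {
      lapply(c(0.3, 1, 5, 20, 80, 300) / dmax,
             function(b0) c(log(a0), log(b0), log(c0)))
    }
    obj <- function(th) {
      sse_of(c(a = exp(th[1]), b = exp(th[2]), c = exp(th[3])))
    }
    fits <- lapply(starts, function(th0) {
      optim(th0, obj, method = "L-BFGS-B",
            lower = c(log(1e-6), log(1e-8), log(1e-6)),
            upper = c(log(1e6), log(1e4), log(1e6)),
            control = list(maxit = 500))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    par <- c(a = exp(best$par[1]), b = exp(best$par[2]),
             c = exp(best$par[3]))
    return(make_fit("Exp4", par, y, d, any(
      vapply(fits, function(f) f$convergence == 0, logical(1))
    )))
  }
  abort(paste0("unknown family: ", family))
}

#' Fit all six families to one gene
#'
#' @inheritParams fit_family
#' @param families families to fit (default all six).
#' @return Named list of `dose_response_fit` objects (failed fits are kept
#'   with `converged = FALSE`).
#' @export
fit_all_families <- function(y, doses, families = bmd_families()) {
  setNames(lapply(families, function(f) {
    tryCatch(fit_family(y, doses, f),
             error = function(e) NULL)
  }), families) |> purrr::compact()
}

#' Select the best model by AIC
#'
#' Minimum AIC among converged fits; ties (within `tol`) are broken by
#' fewer parameters, then by a fixed family order (Exp2, Exp3, Exp4,
#' Linear, Poly2, Power).
#'
#' @param fits list of `dose_response_fit` objects.
#' @param tol AIC difference treated as a tie.
#' @return The selected `dose_response_fit`, or `NULL` if none converged.
#' @export
select_best_aic <- function(fits, tol = 1e-9) {
  fits <- purrr::keep(fits, function(f) isTRUE(f$converged) &&
                        is.finite(f$aic))
  if (length(fits) == 0) return(NULL)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "k")
  fam <- vapply(fits, `[[`, character(1), "family")
  ord <- order(pmax(aic, -1e300), k, match(fam, bmd_families()))
  best <- ord[1]
  # resolve near-ties explicitly in favor of parsimony
  ties <- which(aic - aic[best] <= tol)
  if (length(ties) > 1) {
    ties <- ties[order(k[ties], match(fam[ties], bmd_families()))]
    best <- ties[1]
  }
  fits[[best]]
}

#' Benchmark concentration from a fitted gene model
#'
#' The smallest dose at which the fitted mean departs from its control
#' value by `bmr_mult` residual standard deviations, found by bracketing on
#' a fine dose grid followed by high-precision root refinement. Monotone
#' families admit closed forms, which the numeric root reproduces to about
#' 1e-9 relative error (they are used as cross-checks in the tests). The
#' search covers the tested range and a bounded extrapolation above it
#' (`extend` times the top dose); a BMC above the top tested dose is
#' reported with `in_range = FALSE`.
#'
#' @param fit a `dose_response_fit`.
#' @param bmr_mult benchmark response in residual-SD units (default 1.35).
#' @param d_max top tested dose; defaults to the fit's maximum dose.
#' @param extend extrapolation bound as a multiple of `d_max`.
#' @return List with `bmc` (uM, `NA` if the benchmark response is never
#'   attained within `extend * d_max`) and `in_range`.
#' @export
compute_bmc_sd <- function(fit, bmr_mult = 1.35, d_max = NULL, extend = 10) {
  stopifnot(inherits(fit, "dose_response_fit"))
  d_max <- d_max %||% max(fit$doses)
  # a residual SD at floating-point noise level is an exact fit: the
  # benchmark response is zero and the BMC undefined
  s_tol <- 1e-12 * max(1, diff(range(fit$y)))
  if (!isTRUE(fit$converged) || fit$s <= s_tol) {
    return(list(bmc = NA_real_, in_range = FALSE))
  }
  target <- bmr_mult * fit$s
  mu0 <- family_mu(0, fit$family, fit$par)
  f <- function(d) abs(family_mu(d, fit$family, fit$par) - mu0) - target
  hi_all <- d_max * extend
  grid <- c(0, exp(seq(log(d_max * 1e-8), log(hi_all), length.out = 600)))
  fv <- f(grid)
  cross <- which(fv[-1] > 0 & fv[-length(fv)] <= 0)
  if (length(cross) == 0) return(list(bmc = NA_real_, in_range = FALSE))
  lo <- grid[cross[1]]
  hi <- grid[cross[1] + 1]
  root <- uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.9)$root
  list(bmc = root, in_range = root <= d_max)
}

#' Bootstrap confidence interval for a gene BMC
#'
#' Nonparametric bootstrap within dose groups: replicate responses are
#' resampled with replacement within each dose group (deviations from the
#' group mean rescaled by `sqrt(n_g / (n_g - 1))`, the standard correction
#' for the resampling variance shrink at small group sizes), the best
#' family is refitted (warm-started at the original parameters) and the
#' BMC recomputed. The interval is a t interval on the log-BMC scale:
#' `exp(log BMC +/- t_{df} * sd(log BMC*))`, with `df` the residual
#' degrees of freedom. The log scale matches the positive, ratio-like
#' nature of the BMC; the bootstrap supplies the standard error. If fewer
#' than half of the replicates yield a finite BMC the interval is
#' undefined.
#'
#' @param y,doses data as in [fit_family()].
#' @param family best-fit family to resample under.
#' @param B bootstrap replicates (default 250).
#' @param seed integer seed (fixed seed gives identical intervals).
#' @param bmr_mult benchmark response multiplier.
#' @param d_max top tested dose (defaults to `max(doses)`).
#' @param level confidence level.
#' @param start warm-start parameters (the original fit's).
#' @return List with `bmcl`, `bmcu`, `n_finite`, `defined`.
#' @export
bootstrap_ci <- function(y, doses, family, B = 250, seed = 1,
                         bmr_mult = 1.35, d_max = NULL, level = 0.95,
                         start = NULL) {
  d_max <- d_max %||% max(doses)
  groups <- split(seq_along(doses), doses)
  gmeans <- lapply(groups, function(g) mean(y[g]))
  d_boot <- unlist(lapply(groups, function(g) doses[g]), use.names = FALSE)
  fit0 <- tryCatch(fit_family(y, doses, family, start = start),
                   error = function(e) NULL)
  bmc0 <- if (is.null(fit0)) NA_real_ else {
    compute_bmc_sd(fit0, bmr_mult, d_max = d_max)$bmc
  }
  undefined <- list(bmcl = NA_real_, bmcu = NA_real_, n_finite = 0L,
                    defined = FALSE)
  if (!is.finite(bmc0)) return(undefined)
  with_stream(seed, "bootstrap", {
    reps <- vapply(seq_len(B), function(b) {
      ystar <- unlist(lapply(seq_along(groups), function(k) {
        g <- groups[[k]]
        n_g <- length(g)
        pick <- g[sample.int(n_g, n_g, replace = TRUE)]
        if (n_g < 2) return(y[pick])
        gmeans[[k]] + sqrt(n_g / (n_g - 1)) * (y[pick] - gmeans[[k]])
      }), use.names = FALSE)
      fit_b <- tryCatch(
        fit_family(ystar, d_boot, family, start = start),
        error = function(e) NULL
      )
      if (is.null(fit_b)) return(NA_real_)
      res <- compute_bmc_sd(fit_b, bmr_mult, d_max = d_max)
      if (is.na(res$bmc)) NA_real_ else res$bmc
    }, numeric(1))
    n_finite <- sum(is.finite(reps))
    if (n_finite < B / 2) {
      undefined$n_finite <- n_finite
      undefined
    } else {
      df <- max(length(y) - n_mean_params(family), 1)
      se_log <- sd(log(reps[is.finite(reps)]))
      half <- stats::qt(1 - (1 - level) / 2, df) * se_log
      list(bmcl = bmc0 * exp(-half), bmcu = bmc0 * exp(half),
           n_finite = n_finite, defined = TRUE)
    }
  })
}

#' Apply the concentration-response filter cascade
#'
#' Sets the three filter flags on a table of per-gene BMC records:
#' `in_range` (BMC within the tested concentration range), `ci_ok`
#' (`BMCu/BMCl` at most `ci_ratio_max`), `monotonic_ok` (best model not
#' Poly2, whose responses are non-monotonic), and their conjunction
#' `has_cr` — the definition of "gene with a concentration-response
#' relationship".
#'
#' @param records tibble with columns `bmc_uM`, `bmcl_uM`, `bmcu_uM`,
#'   `best_model`, and optionally a pre-set `in_range`.
#' @param d_max top tested dose, used when `in_range` is absent.
#' @param ci_ratio_max maximum CI ratio (default 40).
#' @return The records with `ci_ratio`, the three flags and `has_cr`.
#' @export
apply_cr_filters <- function(records, d_max = NULL, ci_ratio_max = 40) {
  rec <- as_tibble(records)
  if (!"in_range" %in% names(rec)) {
    if (is.null(d_max)) abort("d_max needed when records lack `in_range`")
    rec$in_range <- is.finite(rec$bmc_uM) & rec$bmc_uM <= d_max
  }
  rec$in_range <- rec$in_range & is.finite(rec$bmc_uM)
  rec$ci_ratio <- rec$bmcu_uM / rec$bmcl_uM
  rec$ci_ok <- is.finite(rec$ci_ratio) & rec$ci_ratio <= ci_ratio_max
  rec$monotonic_ok <- !is.na(rec$best_model) & rec$best_model != "Poly2"
  rec$has_cr <- rec$in_range & rec$ci_ok & rec$monotonic_ok
  rec
}

#' Per-gene concentration-response modeling over a set of genes
#'
#' Runs the full gene-level benchmark-concentration workflow on a
#' normalized matrix: for each requested gene, fits the six model families,
#' selects the best by AIC, computes the SD-based BMC and (optionally) its
#' bootstrap confidence interval, and applies the filter cascade. Genes are
#' usually pre-gated to those differentially expressed in at least one
#' concentration (see [nb_wald_de()]).
#'
#' @param log2cpm_matrix numeric matrix of log2 CPM (genes x samples).
#' @param doses dose per sample (uM), aligned with the columns.
#' @param genes gene identifiers to model (default: all rows).
#' @param bmr_mult benchmark response in residual-SD units.
#' @param ci if `TRUE`, bootstrap CIs are computed for genes with a finite
#'   BMC.
#' @param B bootstrap replicates.
#' @param seed integer seed for the bootstrap streams.
#' @param ci_ratio_max CI-ratio filter threshold.
#' @return Tibble of `gene_bmc` records: gene, best model, parameters
#'   (list-column), residual SD, AIC, BMC and CI (uM), `ci_ratio` and the
#'   filter flags including `has_cr`.
#' @export
fit_gene_bmc <- function(log2cpm_matrix, doses, genes = NULL,
                         bmr_mult = 1.35, ci = TRUE, B = 250, seed = 1,
                         ci_ratio_max = 40) {
  genes <- genes %||% rownames(log2cpm_matrix)
  genes <- intersect(genes, rownames(log2cpm_matrix))
  d_max <- max(doses)
  rows <- purrr::map_dfr(genes, function(g) {
    y <- log2cpm_matrix[g, ]
    fits <- fit_all_families(y, doses)
    best <- select_best_aic(fits)
    if (is.null(best)) {
      return(tibble(
        gene_id = g, best_model = NA_character_, par = list(NULL),
        s = NA_real_, aic = NA_real_, bmc_uM = NA_real_,
        bmcl_uM = NA_real_, bmcu_uM = NA_real_, in_range = FALSE
      ))
    }
    bmc <- compute_bmc_sd(best, bmr_mult, d_max = d_max)
    ci_res <- list(bmcl = NA_real_, bmcu = NA_real_)
    if (ci && is.finite(bmc$bmc)) {
      ci_res <- bootstrap_ci(y, doses, best$family, B = B,
                             seed = derive_seed(seed, g),
                             bmr_mult = bmr_mult, d_max = d_max,
                             start = best$par)
      if (isTRUE(ci_res$defined)) {
        # percentile intervals are widened, if needed, to bracket the
        # point estimate, so BMCl <= BMC <= BMCu always holds
        ci_res$bmcl <- min(ci_res$bmcl, bmc$bmc)
        ci_res$bmcu <- max(ci_res$bmcu, bmc$bmc)
      }
    }
    tibble(
      gene_id = g, best_model = best$family, par = list(best$par),
      s = best$s, aic = best$aic, bmc_uM = bmc$bmc,
      bmcl_uM = ci_res$bmcl, bmcu_uM = ci_res$bmcu,
      in_range = bmc$in_range
    )
  })
  apply_cr_filters(rows, d_max = d_max, ci_ratio_max = ci_ratio_max)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit: %s>\n", x$family))
  cat("  params:", paste(sprintf("%s=%.4g", names(x$par), x$par),
                         collapse = ", "), "\n")
  cat(sprintf("  s = %.4g, AIC = %.3f, converged: %s, direction: %+d\n",
              x$s, x$aic, x$converged, x$direction))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = unname(x$par))
}

#' @exportS3Method generics::glance
glance.dose_response_fit <- function(x, ...) {
  tibble(
    family = x$family, sigma = x$s, logLik = x$loglik, AIC = x$aic,
    nobs = x$n, converged = x$converged, direction = x$direction
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.dose_response_fit <- function(object, bmr_mult = 1.35, ...) {
  obs <- tibble(dose = object$doses, y = object$y)
  dmax <- max(object$doses)
  grid <- seq(0, dmax, length.out = 200)
  curve_df <- tibble(dose = grid,
                     y = family_mu(grid, object$family, object$par))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$dose, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve_df) +
    ggplot2::labs(x = "concentration (uM)", y = "log2 CPM",
                  title = paste0(object$family, " fit")) +
    ggplot2::theme_minimal()
}
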