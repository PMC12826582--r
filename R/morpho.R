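#' Fit a three-parameter log-logistic model to one dichotomous endpoint
#'
#' Maximizes the binomial log-likelihood of
#' `p(d) = g + (1 - g) / (1 + exp(-a - b log d))`, `p(0) = g`, over
#' background `g`, intercept `a` and slope `b > 0` (the slope is optimized
#' on the log scale, so the fitted incidence curve is always nondecreasing
#' in dose). Optimization is bounded quasi-Newton from eight deterministic
#' starts on a coarse grid; the reported optimum is the best across starts.
#'
#' @param table aggregated morphology tibble (see [read_morphology()]); it
#'   should contain a single chemical x line x timepoint series for the
#'   endpoint, with a 0-dose control group and at least three distinct
#'   nonzero concentrations.
#' @param endpoint endpoint name to fit.
#' @param extra_risk extra-risk level for the reported BMC (default 20%).
#' @param slope_min lower bound for the slope; the default keeps only
#'   positivity. Some dichotomous benchmark-dose conventions restrict the
#'   slope to be at least 1; set `slope_min = 1` to enable that.
#' @return Object of class `endpoint_bmc`: fitted `g`, `a`, `b`, the
#'   log-likelihood, convergence and estimability flags, the BMC at
#'   `extra_risk` and an `in_range` flag (BMC at or below the top tested
#'   concentration).
#' @examples
#' cfg <- sim_config(seed = 2)
#' tab <- validate_morphology(simulate_morphology(cfg))
#' fit <- fit_log_logistic_3p(tab, "x_fin")
#' fit$bmc
#' @export
fit_log_logistic_3p <- function(table, endpoint, extra_risk = 0.2,
                                slope_min = 1e-3) {
  stopifnot(extra_risk > 0, extra_risk < 1)
  tab <- dplyr::filter(as_tibble(table), .data$endpoint == !!endpoint)
  if (nrow(tab) == 0) abort(paste0("no rows for endpoint ", endpoint))
  d <- tab$concentration_uM
  y <- tab$n_affected
  n <- tab$n_total
  if (!any(d == 0)) abort("a 0-dose control group is required")
  if (length(unique(d[d > 0])) < 3) {
    abort("need at least 3 distinct nonzero concentrations")
  }

  out <- list(
    endpoint = endpoint, data = tibble(concentration_uM = d, n_affected = y,
                                       n_total = n),
    g = NA_real_, a = NA_real_, b = NA_real_, loglik = NA_real_,
    converged = FALSE, estimable = TRUE, extra_risk = extra_risk,
    bmc = NA_real_, in_range = NA, max_dose = max(d)
  )
  class(out) <- "endpoint_bmc"

  # degenerate incidence: nothing to estimate
  if (sum(y) == 0 || sum(y) == sum(n)) {
    out$estimable <- FALSE
    return(out)
  }

  nll <- function(theta) {
    g <- theta[1]
    p <- loglogistic_p(d, g, theta[2], exp(theta[3]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (n - y) * log(1 - p))
  }

  g0 <- max(sum(y[d == 0]) / max(sum(n[d == 0]), 1), 0.01)
  d_mid <- exp(median(log(d[d > 0])))
  starts <- tidyr::expand_grid(b = c(0.5, 1, 2, 4), shift = c(0, 1))
  fits <- purrr::pmap(starts, function(b, shift) {
    theta0 <- c(min(g0, 0.9), -b * log(d_mid) + shift, log(b))
    optim(
      theta0, nll,
      method = "L-BFGS-B",
      lower = c(1e-8, -50, log(slope_min)),
      upper = c(0.999, 50, log(1e3)),
      control = list(maxit = 500)
    )
  })
  ok <- vapply(fits, function(f) f$convergence == 0, logical(1))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]

  out$g <- best$par[1]
  out$a <- best$par[2]
  out$b <- exp(best$par[3])
  out$loglik <- -best$value
  out$converged <- any(ok) && is.finite(best$value)
  if (out$converged) {
    out$bmc <- bmc_extra_risk(out, extra_risk)
    out$in_range <- is.finite(out$bmc) && out$bmc <= out$max_dose
  }
  out
}

#' Benchmark concentration at a given extra risk
#'
#' Inverts the fitted log-logistic curve at extra risk
#' `(p(d) - g) / (1 - g) = R`, giving
#' `d* = exp((log(R/(1-R)) - a) / b)`. Extra risk cancels the background, so
#' the result does not depend on `g`.
#'
#' @param fit an `endpoint_bmc` object, or any list with elements `a` and
#'   `b`.
#' @param R extra-risk level in (0, 1).
#' @return Concentration (same units as the doses, uM here).
#' @examples
#' bmc_extra_risk(list(a = 0, b = 1), 0.2) # 0.25
#' @export
bmc_extra_risk <- function(fit, R = 0.2) {
  stopifnot(R > 0, R < 1)
  if (!is.numeric(fit$b) || is.na(fit$b) || fit$b <= 0) {
    abort("slope b must be positive to invert the curve")
  }
  exp((log(R / (1 - R)) - fit$a) / fit$b)
}

#' Fit all endpoints of a morphology table
#'
#' Applies [fit_log_logistic_3p()] to each endpoint present and collects
#' results into the standard output table. Out-of-range BMCs (above the top
#' tested concentration) are reported with `in_range = FALSE`; set
#' `suppress_out_of_range = TRUE` to blank them, which is how summary
#' heatmaps of endpoint potencies are usually displayed.
#'
#' @param table aggregated morphology tibble.
#' @param extra_risk extra-risk level (default 20%).
#' @param suppress_out_of_range replace out-of-range BMCs with `NA`.
#' @return Tibble with one row per endpoint: `endpoint`, `g`, `a`, `b`,
#'   `loglik`, `converged`, `bmc_uM`, `in_range`, plus a `fit` list-column
#'   of `endpoint_bmc` objects.
#' @export
fit_morphology_bmc <- function(table, extra_risk = 0.2,
                               suppress_out_of_range = FALSE) {
  eps <- unique(as_tibble(table)$endpoint)
  fits <- lapply(eps, function(e) fit_log_logistic_3p(table, e, extra_risk))
  res <- purrr::map_dfr(fits, function(f) {
    tibble(
      endpoint = f$endpoint, g = f$g, a = f$a, b = f$b, loglik = f$loglik,
      converged = f$converged, bmc_uM = f$bmc,
      in_range = f$in_range %||% NA
    )
  })
  if (suppress_out_of_range) {
    res$bmc_uM[!res$in_range %in% TRUE] <- NA_real_
  }
  res$fit <- fits
  res
}

#' Fisher/Holm incidence time course
#'
#' For every endpoint x concentration x timepoint cell with a matching
#' same-timepoint control, computes a two-sided conditional Fisher exact
#' p-value on the 2x2 table (affected/unaffected x treated/control), then
#' applies Holm's step-down correction across the whole family of tests
#' (all endpoint x concentration x timepoint cells analyzed together).
#'
#' @param table aggregated morphology tibble, possibly spanning several
#'   timepoints.
#' @param alpha significance level on the adjusted p-value.
#' @return Tibble with one row per test: endpoint, timepoint, concentration,
#'   treated and control incidence, `p_value`, `p_holm`, `significant`.
#' @export
fisher_holm_timecourse <- function(table, alpha = 0.05) {
  tab <- as_tibble(table)
  controls <- dplyr::filter(tab, .data$concentration_uM == 0) |>
    group_by(.data$endpoint, .data$timepoint_hpf) |>
    summarise(
      control_affected = sum(.data$n_affected),
      control_total = sum(.data$n_total), .groups = "drop"
    )
  treated <- dplyr::filter(tab, .data$concentration_uM > 0) |>
    group_by(.data$endpoint, .data$timepoint_hpf, .data$concentration_uM) |>
    summarise(
      n_affected = sum(.data$n_affected),
      n_total = sum(.data$n_total), .groups = "drop"
    )
  res <- inner_join(treated, controls,
                    by = c("endpoint", "timepoint_hpf"))
  if (nrow(res) < nrow(treated)) {
    warn("treated cells without a matched same-timepoint control were dropped")
  }
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    if (res$n_total[i] == 0 || res$control_total[i] == 0) {
      warn("zero-total cell; p set to 1")
      return(1)
    }
    fisher_p_two_sided(res$n_affected[i], res$n_total[i],
                       res$control_affected[i], res$control_total[i])
  }, numeric(1))
  res$p_holm <- p.adjust(res$p_value, method = "holm")
  res$significant <- res$p_holm <= alpha
  res
}

#' @export
print.endpoint_bmc <- function(x, ...) {
  cat(sprintf("<endpoint_bmc: %s>\n", x$endpoint))
  if (!x$estimable) {
    cat("  non-estimable (degenerate incidence)\n")
    return(invisible(x))
  }
  cat(sprintf("  g = %.4f, a = %.4f, b = %.4f (logLik %.3f, converged: %s)\n",
              x$g, x$a, x$b, x$loglik, x$converged))
  cat(sprintf("  BMC at %.0f%% extra risk: %.4g uM (%s range)\n",
              100 * x$extra_risk, x$bmc,
              if (isTRUE(x$in_range)) "within" else "outside"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.endpoint_bmc <- function(x, ...) {
  tibble(
    term = c("g", "a", "b"),
    estimate = c(x$g, x$a, x$b)
  )
}

#' @exportS3Method generics::glance
glance.endpoint_bmc <- function(x, ...) {
  tibble(
    endpoint = x$endpoint, logLik = x$loglik, converged = x$converged,
    estimable = x$estimable, extra_risk = x$extra_risk, bmc = x$bmc,
    in_range = x$in_range %||% NA
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.endpoint_bmc <- function(object, ...) {
  obs <- object$data |>
    group_by(.data$concentration_uM) |>
    summarise(rate = sum(.data$n_affected) / sum(.data$n_total),
              .groups = "drop")
  p <- ggplot2::ggplot(obs,
                       ggplot2::aes(x = .data$concentration_uM,
                                    y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "concentration (uM)", y = "incidence",
      title = paste0(object$endpoint, " concentration response")
    ) +
    ggplot2::theme_minimal()
  if (isTRUE(object$converged)) {
    dmax <- max(obs$concentration_uM)
    dmin <- min(obs$concentration_uM[obs$concentration_uM > 0])
    grid <- exp(seq(log(dmin / 2), log(dmax), length.out = 200))
    curve_df <- tibble(
      concentration_uM = grid,
      rate = loglogistic_p(grid, object$g, object$a, object$b)
    )
    p <- p +
      ggplot2::geom_line(data = curve_df) +
      ggplot2::geom_vline(xintercept = object$bmc, linetype = "dashed")
  }
  p + ggplot2::scale_x_continuous(
    trans = "log10",
    limits = c(NA, NA)
  )
}
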