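# shared fixture builders; everything is generated in code at test time

small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 200, timepoints = 48, ...)
}

# aggregated morphology table with exact incidence counts on a known curve
morpho_table_exact <- function(g, a, b, doses, n, n0 = n) {
  p <- g + (1 - g) * stats::plogis(a + b * log(doses))
  tibble::tibble(
    line = "wildtype", chemical = "chemA",
    concentration_uM = c(0, doses), timepoint_hpf = 120,
    endpoint = "x_fin",
    n_affected = c(round(n0 * g), round(n * p)),
    n_total = c(n0, rep(n, length(doses)))
  )
}

# study-design doses for gene modeling (4 doses incl. control, 4 reps)
study_doses <- function(n_rep = 4) rep(c(0, 0.133, 1.33, 13.3), each = n_rep)
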