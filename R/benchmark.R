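#' Benchmark adjusted and baseline methods on simulated data
#'
#' Runs each requested method on each simulated configuration and scores it
#' against the ground truth: confusion metrics at the `alpha` cutoff
#' ([evaluate_calls()]), fold-change error summaries among the truly
#' differential PTMs (bias relative to the true adjusted change, and the
#' interquartile range of the estimates), and, for the ratio-based
#' baselines, the fraction of protein and PTM run summaries discarded
#' because the other side of the ratio was missing.
#'
#' @param configs a list of [sim_config()] objects.
#' @param methods subset of `"polish_adjusted"` (median-polish
#'   summarization, per-target models, protein adjustment),
#'   `"polish_unadjusted"` (same without adjustment), `"anova_unadj"`,
#'   `"anova_ratio"`, `"limma_unadj"`, `"limma_ratio"`.
#' @param alpha FDR-adjusted p-value cutoff.
#' @param contrast the evaluated condition contrast (default `C2 - C1`).
#' @return a `ptm_benchmark` tibble, one row per (config, method): config
#'   descriptors, confusion metrics, `fc_bias`, `fc_iqr`,
#'   `frac_protein_discarded`, `frac_ptm_discarded`.
#' @export
run_benchmark <- function(configs,
                          methods = c("polish_adjusted", "polish_unadjusted",
                                      "anova_unadj", "anova_ratio",
                                      "limma_unadj", "limma_ratio"),
                          alpha = 0.05, contrast = c("C2", "C1")) {
  if (inherits(configs, "ptm_sim_config")) configs <- list(configs)
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("polish_adjusted", "polish_unadjusted",
                                   "anova_unadj", "anova_ratio",
                                   "limma_unadj", "limma_ratio"))
  rows <- purrr::imap(configs, function(cfg, idx) {
    sim <- simulate_ptm(cfg)
    purrr::map(methods, function(m) {
      res <- run_method(m, sim$enriched, sim$global, contrast)
      score_method(res, sim$truth, alpha, cfg, idx, m)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("ptm_benchmark", class(out))
  out
}

run_method <- function(method, enriched, global, contrast) {
  switch(
    method,
    polish_adjusted = ptm_differential(enriched, global,
                                      contrasts = list(contrast)),
    polish_unadjusted = ptm_differential(enriched, global = NULL,
                                        contrasts = list(contrast)),
    fit_baseline(method, clean_enriched(enriched), global, contrast)
  )
}

score_method <- function(res, truth, alpha, cfg, idx, method) {
  metrics <- evaluate_calls(res, truth, alpha)
  joined <- dplyr::left_join(
    truth, res[, c("protein", "estimate")], by = "protein"
  )
  diff <- joined$truth_class %in% c("diff_direct", "diff_masked")
  est <- joined$estimate[diff]
  loss <- attr(res, "loss")
  dplyr::bind_cols(
    tibble::tibble(
      config = idx, preset = cfg$preset, n_conditions = cfg$n_conditions,
      n_replicates = cfg$n_replicates, sigma2 = cfg$sigma2,
      missing_rate = cfg$missing_rate, seed = cfg$seed, method = method
    ),
    metrics,
    tibble::tibble(
      fc_bias = mean(est - joined$true_delta_adj[diff], na.rm = TRUE),
      fc_iqr = IQR(est, na.rm = TRUE),
      frac_protein_discarded = if (!is.null(loss)) {
        loss$n_protein_discarded / loss$n_protein_total
      } else NA_real_,
      frac_ptm_discarded = if (!is.null(loss)) {
        loss$n_ptm_discarded / loss$n_ptm_total
      } else NA_real_
    )
  )
}
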