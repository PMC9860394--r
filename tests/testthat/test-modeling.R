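test_that("one-way fits recover hand-computed least squares", {
  s <- make_summaries(c(1.0, 1.2, 2.0, 2.4), c("C1", "C1", "C2", "C2"))
  fit <- fit_oneway(s)
  expect_equal(fit$means[[1]], c(C1 = 1.1, C2 = 2.2))
  expect_equal(fit$resid_var, 0.05)  # (0.02 + 0.08) / 2
  expect_equal(fit$resid_df, 2)      # I(J-1), balanced
  res <- estimate_contrast(fit, c("C2", "C1"))
  expect_equal(res$estimate, 1.1)
  expect_equal(res$se, sqrt(0.05))   # sqrt(2 * 0.05 / 2)
  rev <- estimate_contrast(fit, c("C1", "C2"))
  expect_equal(rev$estimate, -1.1)   # antisymmetry
  expect_equal(rev$se, res$se)
  expect_equal(rev$pvalue, res$pvalue)
})

test_that("balanced one-way inference matches a pooled t-test oracle", {
  set.seed(2024)
  for (i in 1:100) {
    J <- sample(3:8, 1)
    y1 <- rnorm(J, 10, 0.5); y2 <- rnorm(J, 10.5, 0.5)
    s <- make_summaries(c(y1, y2), rep(c("C1", "C2"), each = J))
    res <- estimate_contrast(fit_oneway(s), c("C2", "C1"))
    tt <- t.test(y2, y1, var.equal = TRUE)
    expect_equal(res$estimate, unname(diff(rev(tt$estimate))),
                 tolerance = 1e-10)
    expect_equal(res$tstat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(res$pvalue, tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate designs are flagged, not silently tested", {
  singletons <- make_summaries(c(1, 2), c("C1", "C2"))
  res <- estimate_contrast(fit_oneway(singletons), c("C2", "C1"))
  expect_equal(res$issue, "inestimable")
  expect_true(is.na(res$pvalue))
  expect_equal(res$estimate, 1)   # the point estimate survives
  absent <- make_summaries(c(1, 2, 3), c("C1", "C1", "C1"))
  res2 <- estimate_contrast(fit_oneway(absent), c("C2", "C1"))
  expect_equal(res2$issue, "single_condition")
})

test_that("zero residual variance uses the degenerate-t convention", {
  const <- make_summaries(rep(2, 4), c("C1", "C1", "C2", "C2"))
  res <- estimate_contrast(fit_oneway(const), c("C2", "C1"))
  expect_equal(res$estimate, 0)
  expect_equal(res$pvalue, 1)
  shifted <- make_summaries(c(1, 1, 2, 2), c("C1", "C1", "C2", "C2"))
  expect_warning(
    res2 <- estimate_contrast(fit_oneway(shifted), c("C2", "C1")),
    "variance"
  )
  expect_equal(res2$pvalue, 0)
})

sim_tmt_summaries <- function(n_mix, n_rep, sigma_m2, sigma2, delta = 0.5,
                              seed = 1) {
  set.seed(seed)
  g <- tidyr::expand_grid(mix = seq_len(n_mix), cond = c("C1", "C2"),
                          rep = seq_len(n_rep))
  mix_eff <- rnorm(n_mix, 0, sqrt(sigma_m2))
  vals <- 20 + ifelse(g$cond == "C2", delta, 0) + mix_eff[g$mix] +
    rnorm(nrow(g), 0, sqrt(sigma2))
  tibble::tibble(
    protein = "P1", site = "S10", target_type = "site",
    run = sprintf("M%d", g$mix),
    channel = sprintf("ch%s_%d", g$cond, g$rep),
    condition = g$cond, mixture = sprintf("M%d", g$mix),
    replicate = paste0(g$mix, "_", g$cond, g$rep),
    log2inty = vals, n_features = 1L, method = "median_polish"
  )
}

test_that("the mixed model nests the one-way model", {
  # a single mixture falls back to the one-way fit, exactly
  s1 <- sim_tmt_summaries(1, 4, 0, 0.2)
  mixed <- fit_tmt_mixed(s1)
  expect_equal(mixed$design, "fallback_oneway")
  expect_equal(mixed$means, fit_oneway(s1)$means)
  # data with no mixture effect: variance component near 0, means agree
  s0 <- sim_tmt_summaries(4, 6, 0, 0.2, seed = 5)
  m <- fit_models(s0, design = "tmt_mixed")
  expect_equal(m$design, "tmt_mixed")
  expect_lt(m$mixture_var, 0.05)
  ow <- fit_oneway(s0)
  expect_equal(m$means[[1]], ow$means[[1]], tolerance = 0.05)
})

test_that("REML variance components match method-of-moments on balanced
           data", {
  s <- sim_tmt_summaries(12, 8, 0.5, 0.2, seed = 42)
  m <- fit_models(s, design = "tmt_mixed")
  # method-of-moments from the balanced two-way ANOVA mean squares
  a <- stats::aov(log2inty ~ condition + mixture, data = s)
  ms <- summary(a)[[1]][["Mean Sq"]]
  n_per_mix <- 16
  mom_sigma2 <- ms[3]
  mom_sigma_m2 <- max((ms[2] - ms[3]) / n_per_mix, 0)
  expect_equal(m$resid_var, mom_sigma2, tolerance = 0.1)
  expect_equal(m$mixture_var, mom_sigma_m2, tolerance = 0.15)
})

test_that("mixed-model contrasts carry Satterthwaite df matching the
           balanced closed form", {
  s <- sim_tmt_summaries(3, 4, 0.3, 0.2, seed = 11)
  m <- fit_models(s, design = "tmt_mixed")
  res <- estimate_contrast(m, c("C2", "C1"))
  # balanced, condition orthogonal to mixture: residual df = N - I - M + 1
  expect_equal(res$df, nrow(s) - 2 - 3 + 1, tolerance = 0.1)
  expect_false(is.na(res$pvalue))
})

test_that("a condition confined to one mixture is still estimable", {
  s <- sim_tmt_summaries(3, 4, 0.3, 0.2, seed = 13)
  s <- s[!(s$condition == "C2" & s$mixture != "M1"), ]
  m <- fit_models(s, design = "tmt_mixed")
  res <- estimate_contrast(m, c("C2", "C1"))
  expect_false(is.na(res$estimate))
  full <- estimate_contrast(fit_models(sim_tmt_summaries(3, 4, 0.3, 0.2,
                                                         seed = 13),
                                       design = "tmt_mixed"),
                            c("C2", "C1"))
  expect_lt(res$df, full$df)  # information loss shows up as reduced df
})

test_that("variance moderation shrinks toward the consensus and keeps
           ordering", {
  set.seed(99)
  d0 <- 4; s02 <- 0.3; df <- 4; n <- 2000
  true_var <- s02 * d0 / stats::rchisq(n, d0)
  sample_var <- true_var * stats::rchisq(n, df) / df
  model <- tibble::tibble(
    protein = sprintf("P%04d", 1:n), site = "S1", target_type = "site",
    design = "oneway_fixed", resid_var = sample_var, resid_df = df,
    mixture_var = NA_real_, n_runs = 10L, converged = TRUE,
    means = replicate(n, c(C1 = 0, C2 = 0), simplify = FALSE),
    ns = replicate(n, c(C1 = 5L, C2 = 5L), simplify = FALSE),
    fit = vector("list", n)
  )
  class(model) <- c("ptm_model", class(model))
  mod <- moderate_variance(model)
  expect_equal(attr(mod, "df_prior"), d0, tolerance = 0.15)
  expect_equal(attr(mod, "var_prior"), s02, tolerance = 0.15)
  expect_equal(mod$resid_df, rep(df + attr(mod, "df_prior"), n))
  # posterior mean formula
  expect_equal(
    mod$resid_var,
    (attr(mod, "df_prior") * attr(mod, "var_prior") + df * sample_var) /
      (attr(mod, "df_prior") + df)
  )
  # monotone map of the raw variances at fixed df
  ord <- order(sample_var)
  expect_true(all(diff(mod$resid_var[ord]) >= 0))
})

test_that("identical sample variances moderate to the common value", {
  model <- fit_oneway(dplyr::bind_rows(
    make_summaries(c(1, 2, 3, 4), c("C1", "C1", "C2", "C2"), protein = "P1"),
    make_summaries(c(5, 6, 7, 8), c("C1", "C1", "C2", "C2"), protein = "P2")
  ))
  expect_equal(model$resid_var, c(0.5, 0.5))
  mod <- suppressWarnings(moderate_variance(model))
  expect_equal(mod$resid_var, c(0.5, 0.5))
})

test_that("baseline methods agree with their building blocks", {
  sim <- simulate_ptm(sim_config("sim1", n_proteins = 40, n_replicates = 4,
                                 seed = 21))
  enriched <- clean_enriched(sim$enriched)
  base <- fit_baseline("anova_unadj", enriched, contrast = c("C2", "C1"))
  direct <- estimate_contrast(
    fit_oneway(summarize_runs(enriched, method = "log_sum")), c("C2", "C1")
  )
  expect_equal(base$estimate, direct$estimate)
  expect_equal(base$pvalue, direct$pvalue)

  # ratio baseline cancels changes shared by both feature types (near the
  # noise-free limit the cancellation is essentially exact)
  simq <- simulate_ptm(sim_config("sim1", n_proteins = 40, n_replicates = 4,
                                  sigma2 = 1e-3, seed = 22))
  base_r <- fit_baseline("anova_ratio", clean_enriched(simq$enriched),
                         simq$global, c("C2", "C1"))
  drv <- simq$truth$protein[simq$truth$truth_class == "null_protein_driven"]
  expect_lt(max(abs(base_r$estimate[base_r$protein %in% drv])), 0.05)

  # moderated p-values drop where the variance is shrunk downward
  lim <- fit_baseline("limma_unadj", enriched, contrast = c("C2", "C1"))
  m_raw <- fit_oneway(summarize_runs(enriched, method = "log_sum"))
  m_mod <- moderate_variance(m_raw)
  shrunk_dn <- m_mod$resid_var < m_raw$resid_var
  p_raw <- estimate_contrast(m_raw, c("C2", "C1"))$pvalue
  expect_true(all(lim$pvalue[shrunk_dn] <= p_raw[shrunk_dn]))
})
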