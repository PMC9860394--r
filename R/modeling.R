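#' Fit per-target models to run summaries
#'
#' Fits one model per target (PTM site or protein) to its run summaries.
#' Label-free group-comparison designs use a one-way fixed-effects model
#' (condition means with iid Gaussian error), estimated by least squares
#' with a pooled residual variance; `resid_df = sum(J_i - 1)`, which equals
#' `I(J-1)` in balanced designs. Multi-mixture TMT designs add a random
#' mixture intercept estimated by REML ([lmerTest::lmer()]). When a model is
#' not estimable for a target (a single mixture, or non-convergence) the fit
#' falls back down the ladder `tmt_mixed -> oneway`, recorded in `design`.
#'
#' @param summaries run summaries from [summarize_runs()] (one target type,
#'   or a mix; each target is fit separately).
#' @param design `"auto"` (mixed model when >= 2 mixtures are present),
#'   `"oneway"`, or `"tmt_mixed"`.
#' @return a `ptm_model` tibble, one row per target: `protein`, `site`,
#'   `target_type`, `design`, `means` (named list-column of condition
#'   means), `ns` (replicates per condition), `resid_var`, `resid_df`,
#'   `mixture_var`, `n_runs`, `converged`, `fit` (the merMod object for
#'   mixed fits, else `NULL`).
#' @export
fit_models <- function(summaries, design = c("auto", "oneway", "tmt_mixed")) {
  design <- match.arg(design)
  stopifnot(nrow(summaries) > 0)
  n_mix <- length(unique(summaries$mixture[!is.na(summaries$mixture)]))
  if (design == "auto") {
    design <- if (n_mix >= 2) "tmt_mixed" else "oneway"
  }
  if (design == "oneway") return(fit_oneway_vectorized(summaries))
  key <- c("protein", "site", "target_type")
  nested <- tidyr::nest(dplyr::group_by(summaries, .data$protein, .data$site,
                                        .data$target_type))
  nested <- dplyr::ungroup(nested)
  fits <- purrr::map(nested$data, fit_one_target, design = design)
  out <- dplyr::bind_cols(nested[, key], dplyr::bind_rows(
    purrr::map(fits, ~ .x[c("design", "resid_var", "resid_df", "mixture_var",
                            "n_runs", "converged")])
  ))
  out$means <- purrr::map(fits, "means")
  out$ns <- purrr::map(fits, "ns")
  out$fit <- purrr::map(fits, "fit")
  class(out) <- c("ptm_model", class(out))
  out
}

# One-way least squares for every target in one grouped pass (identical to
# fit_target_oneway, vectorized over thousands of targets).
fit_oneway_vectorized <- function(summaries) {
  s <- summaries[!is.na(summaries$log2inty), ]
  tgt <- paste(s$protein, s$site, s$target_type, sep = "\r")
  grp <- paste(tgt, s$condition, sep = "\r")
  gkey <- !duplicated(grp)
  gid <- match(grp, grp[gkey])
  n <- tabulate(gid)
  sum_y <- rowsum(s$log2inty, gid)[, 1]
  sum_y2 <- rowsum(s$log2inty^2, gid)[, 1]
  m <- sum_y / n
  ss <- pmax(sum_y2 - n * m^2, 0)
  g_tgt <- tgt[gkey]
  g_cond <- s$condition[gkey]
  tkey <- !duplicated(g_tgt)
  tid <- match(g_tgt, g_tgt[tkey])
  resid_df <- rowsum(n - 1, tid)[, 1]
  resid_var <- ifelse(resid_df > 0, rowsum(ss, tid)[, 1] / resid_df,
                      NA_real_)
  n_runs <- rowsum(n, tid)[, 1]
  ord <- order(tid)
  means <- split(setNames(m, g_cond)[ord], tid[ord])
  ns <- split(setNames(n, g_cond)[ord], tid[ord])
  meta <- s[!duplicated(tgt), c("protein", "site", "target_type")]
  out <- tibble::tibble(
    protein = meta$protein, site = meta$site,
    target_type = meta$target_type,
    design = "oneway_fixed",
    resid_var = unname(resid_var), resid_df = as.numeric(resid_df),
    mixture_var = NA_real_, n_runs = as.integer(n_runs), converged = TRUE,
    means = unname(means), ns = unname(ns),
    fit = vector("list", nrow(meta))
  )
  class(out) <- c("ptm_model", class(out))
  out
}

#' @rdname fit_models
#' @export
fit_oneway <- function(summaries) fit_models(summaries, design = "oneway")

#' @rdname fit_models
#' @export
fit_tmt_mixed <- function(summaries) fit_models(summaries, design = "tmt_mixed")

fit_one_target <- function(df, design) {
  df <- df[!is.na(df$log2inty), ]
  if (design == "tmt_mixed") {
    n_mix <- length(unique(df$mixture[!is.na(df$mixture)]))
    if (n_mix >= 2) {
      fit <- fit_target_mixed(df)
      if (!is.null(fit) && fit$converged) return(fit)
    }
    fb <- fit_target_oneway(df, fallback = TRUE)
    if (n_mix >= 2) fb$converged <- FALSE
    return(fb)
  }
  fit_target_oneway(df)
}

fit_target_oneway <- function(df, fallback = FALSE) {
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$condition),
    m = mean(.data$log2inty), n = dplyr::n(),
    ss = sum((.data$log2inty - mean(.data$log2inty))^2),
    .groups = "drop"
  )
  resid_df <- sum(agg$n - 1)
  resid_var <- if (resid_df > 0) sum(agg$ss) / resid_df else NA_real_
  list(
    design = if (fallback) "fallback_oneway" else "oneway_fixed",
    means = setNames(agg$m, agg$condition),
    ns = setNames(agg$n, agg$condition),
    resid_var = resid_var, resid_df = as.numeric(resid_df),
    mixture_var = NA_real_, n_runs = nrow(df), converged = TRUE,
    fit = NULL
  )
}

fit_target_mixed <- function(df) {
  df$condition <- factor(df$condition)
  df$mixture <- factor(df$mixture)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(log2inty ~ 0 + condition + (1 | mixture), data = df,
                     REML = TRUE)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_m2 <- vc$vcov[vc$grp == "mixture"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  coefs <- lme4::fixef(fit)
  conds <- sub("^condition", "", names(coefs))
  conv <- length(unlist(fit@optinfo$conv$lme4)) == 0
  list(
    design = "tmt_mixed",
    means = setNames(as.numeric(coefs), conds),
    ns = setNames(as.integer(table(df$condition)[conds]), conds),
    resid_var = max(sigma2, 0), resid_df = NA_real_,
    mixture_var = max(sigma_m2, 0), n_runs = nrow(df), converged = conv,
    fit = fit
  )
}

#' Estimate a pairwise condition contrast from fitted models
#'
#' For every target in a `ptm_model`, estimates the log2 fold change between
#' two conditions, its standard error, degrees of freedom (residual df for
#' one-way fits; Satterthwaite df for mixed fits), t statistic and two-sided
#' Student-t p-value. Residual variances below `1e-12` are treated as 0:
#' p = 0 for a non-zero estimate (with a warning) and p = 1 otherwise.
#'
#' @param model a `ptm_model` from [fit_models()].
#' @param contrast character of length 2, `c(i, i_prime)`; the estimate is
#'   `mean(i) - mean(i_prime)`.
#' @return a tibble, one row per target: `protein`, `site`, `label`
#'   (`"PTM"` for site targets, `"PROTEIN"` for protein targets),
#'   `contrast`, `estimate`, `se`, `df`, `tstat`, `pvalue`, `issue`
#'   (`NA`, `"single_condition"`, or `"inestimable"`).
#' @export
estimate_contrast <- function(model, contrast) {
  stopifnot(length(contrast) == 2)
  a <- contrast[1]; b <- contrast[2]
  zero_var <- FALSE
  one <- function(i) {
    means <- model$means[[i]]
    ns <- model$ns[[i]]
    if (!(a %in% names(means)) || !(b %in% names(means))) {
      return(list(estimate = NA_real_, se = NA_real_, df = NA_real_,
                  tstat = NA_real_, pvalue = NA_real_,
                  issue = "single_condition"))
    }
    est <- unname(means[a] - means[b])
    if (model$design[i] == "tmt_mixed" && !is.null(model$fit[[i]])) {
      fit <- model$fit[[i]]
      cn <- sub("^condition", "", names(lme4::fixef(fit)))
      L <- as.numeric(cn == a) - as.numeric(cn == b)
      ct <- tryCatch(lmerTest::contest1D(fit, L), error = function(e) NULL)
      if (is.null(ct)) {
        return(list(estimate = est, se = NA_real_, df = NA_real_,
                    tstat = NA_real_, pvalue = NA_real_,
                    issue = "inestimable"))
      }
      return(list(estimate = ct$Estimate, se = ct$`Std. Error`, df = ct$df,
                  tstat = ct$`t value`, pvalue = ct$`Pr(>|t|)`,
                  issue = NA_character_))
    }
    v <- model$resid_var[i]
    dfree <- model$resid_df[i]
    if (is.na(v) || dfree <= 0) {
      return(list(estimate = est, se = NA_real_, df = NA_real_,
                  tstat = NA_real_, pvalue = NA_real_,
                  issue = "inestimable"))
    }
    if (v < 1e-12) {
      if (abs(est) > 0) zero_var <<- TRUE
      p <- if (abs(est) > 0) 0 else 1
      return(list(estimate = est, se = 0, df = dfree,
                  tstat = if (abs(est) > 0) sign(est) * Inf else 0,
                  pvalue = p, issue = NA_character_))
    }
    se <- sqrt(v * (1 / ns[a] + 1 / ns[b]))
    t <- est / se
    list(estimate = est, se = unname(se), df = dfree, tstat = unname(t),
         pvalue = unname(2 * pt(-abs(t), dfree)), issue = NA_character_)
  }
  rows <- purrr::map(seq_len(nrow(model)), one)
  out <- dplyr::bind_cols(
    tibble::tibble(
      protein = model$protein, site = model$site,
      label = ifelse(model$target_type == "site", "PTM", "PROTEIN"),
      contrast = paste(a, "vs", b)
    ),
    dplyr::bind_rows(purrr::map(rows, tibble::as_tibble))
  )
  if (zero_var) {
    warn("residual variance ~ 0 for some target(s); p-values set to 0/1")
  }
  out
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-target residual variances toward a consensus value by fitting
#' a scaled inverse-chi-square prior (`d0`, `s0^2`) across targets by
#' marginal maximum likelihood ([limma::squeezeVar()]). Each variance is
#' replaced by the posterior mean `(d0*s0^2 + df*s^2) / (d0 + df)` and each
#' residual df by `df + d0`. When all variances coincide, `d0` is infinite
#' and every moderated variance equals the common value.
#'
#' @param model a `ptm_model` with one-way fits (moderation of mixed fits is
#'   not supported; their variances are left untouched with a warning).
#' @return the `ptm_model` with moderated `resid_var`/`resid_df`;
#'   hyperparameters in attributes `var_prior` and `df_prior`.
#' @export
moderate_variance <- function(model) {
  ok <- !is.na(model$resid_var) & !is.na(model$resid_df) &
    model$resid_df > 0 & model$design != "tmt_mixed"
  if (any(model$design == "tmt_mixed")) {
    warn("mixed-model fits are not moderated")
  }
  if (sum(ok) < 2) {
    abort("need >= 2 targets with positive residual df to moderate",
          class = "ptm_model_error")
  }
  sq <- limma::squeezeVar(model$resid_var[ok], model$resid_df[ok])
  model$resid_var[ok] <- sq$var.post
  model$resid_df[ok] <- model$resid_df[ok] + sq$df.prior
  attr(model, "var_prior") <- sq$var.prior
  attr(model, "df_prior") <- sq$df.prior
  model
}

#' Baseline differential-PTM methods
#'
#' The comparison methods the protein-adjusted analysis is benchmarked
#' against. Unadjusted variants (`anova_unadj`, `limma_unadj`) model log-sum
#' site summaries and test the raw PTM change; ratio variants
#' (`anova_ratio`, `limma_ratio`) model the replicate-wise log2 ratio of
#' site over protein summaries, losing any run observed on only one side
#' (the loss is returned in the `"loss"` attribute). `limma_*` variants
#' apply [moderate_variance()] across targets before testing. BH correction
#' is applied per contrast.
#'
#' @param method one of `"anova_unadj"`, `"anova_ratio"`, `"limma_unadj"`,
#'   `"limma_ratio"`.
#' @param enriched cleaned enriched feature table.
#' @param global global feature table (required by ratio methods).
#' @param contrast character of length 2, as in [estimate_contrast()].
#' @return a comparison-results tibble (columns of [estimate_contrast()]
#'   plus `adj_pvalue`), labelled `"PTM"` for unadjusted and `"ADJUSTED"`
#'   for ratio methods.
#' @export
fit_baseline <- function(method = c("anova_unadj", "anova_ratio",
                                    "limma_unadj", "limma_ratio"),
                         enriched, global = NULL, contrast) {
  method <- match.arg(method)
  ratio <- grepl("ratio", method)
  moderated <- grepl("limma", method)
  ptm_sum <- summarize_runs(enriched, method = "log_sum")
  if (ratio) {
    if (is.null(global)) {
      abort("ratio-based baselines require a global feature table",
            class = "ptm_model_error")
    }
    prot_sum <- summarize_runs(global, method = "log_sum")
    u <- ratio_summaries(ptm_sum, prot_sum)
    loss <- attr(u, "loss")
    input <- u
  } else {
    input <- ptm_sum
    loss <- NULL
  }
  model <- fit_models(input, design = "oneway")
  if (moderated) model <- moderate_variance(model)
  res <- estimate_contrast(model, contrast)
  if (ratio) res$label <- "ADJUSTED"
  res$adj_pvalue <- bh_adjust(res$pvalue)
  if (!is.null(loss)) attr(res, "loss") <- loss
  res
}
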