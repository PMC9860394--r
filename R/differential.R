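#' Protein-adjusted differential PTM analysis
#'
#' The headline end-to-end analysis: summarize feature intensities per site
#' and per protein (Tukey median polish by default), fit per-target models,
#' estimate each requested contrast for both levels, and adjust every PTM
#' fold change for the corresponding protein-level change
#' ([adjust_all()]). Sites without global profiling information are passed
#' through unadjusted and flagged. BH correction is applied within each
#' contrast.
#'
#' @param enriched canonical feature table of the enriched runs (unmodified
#'   background features are removed internally via [clean_enriched()]).
#' @param global canonical feature table of the global profiling runs, or
#'   `NULL` when the experiment has none (all sites are then tested
#'   unadjusted).
#' @param contrasts `"all-pairwise"`, or a list of length-2 character
#'   vectors `c(i, i_prime)` (each estimate is `i - i_prime`).
#' @param summarization `"median_polish"` (default) or `"log_sum"`.
#' @param moderate apply empirical-Bayes variance moderation
#'   ([moderate_variance()]) to both models before testing. Off by default:
#'   the headline adjusted analysis is unmoderated.
#' @param impute `"off"` or `"protein"`, passed to [summarize_runs()].
#' @param design model design, passed to [fit_models()].
#' @return a `ptm_results` tibble, one row per (site, contrast), with
#'   attributes `ptm_model` and `protein_model`.
#' @export
ptm_differential <- function(enriched, global = NULL,
                             contrasts = "all-pairwise",
                             summarization = c("median_polish", "log_sum"),
                             moderate = FALSE, impute = c("off", "protein"),
                             design = c("auto", "oneway", "tmt_mixed")) {
  summarization <- match.arg(summarization)
  impute <- match.arg(impute)
  design <- match.arg(design)
  enriched <- clean_enriched(enriched)
  ptm_sum <- summarize_runs(enriched, method = summarization, impute = "off")
  ptm_model <- fit_models(ptm_sum, design = design)
  prot_model <- NULL
  if (!is.null(global) && nrow(global) > 0) {
    prot_sum <- summarize_runs(global, method = summarization,
                               impute = impute)
    prot_model <- fit_models(prot_sum, design = design)
  }
  if (moderate) {
    ptm_model <- moderate_variance(ptm_model)
    if (!is.null(prot_model)) prot_model <- moderate_variance(prot_model)
  }
  pairs <- expand_contrasts(contrasts, unique(enriched$condition))
  per_contrast <- purrr::map(pairs, function(pr) {
    ptm_res <- estimate_contrast(ptm_model, pr)
    prot_res <- if (!is.null(prot_model)) {
      estimate_contrast(prot_model, pr)
    }
    list(ptm = ptm_res, prot = prot_res)
  })
  ptm_res <- dplyr::bind_rows(purrr::map(per_contrast, "ptm"))
  prot_res <- dplyr::bind_rows(purrr::map(per_contrast, "prot"))
  out <- adjust_all(ptm_res,
                    if (nrow(prot_res) > 0) prot_res else NULL)
  attr(out, "ptm_model") <- ptm_model
  attr(out, "protein_model") <- prot_model
  out
}

expand_contrasts <- function(contrasts, conditions) {
  if (identical(contrasts, "all-pairwise")) {
    conds <- sort(unique(conditions))
    if (length(conds) < 2) {
      abort("need >= 2 conditions for a contrast", class = "ptm_model_error")
    }
    cmb <- utils::combn(conds, 2, simplify = FALSE)
    return(purrr::map(cmb, ~ c(.x[2], .x[1])))
  }
  if (is.character(contrasts) && length(contrasts) == 2) {
    return(list(contrasts))
  }
  stopifnot(is.list(contrasts), all(lengths(contrasts) == 2))
  contrasts
}
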