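#' Tidy per-target condition means
#'
#' @param x a `ptm_model` from [fit_models()].
#' @param ... unused.
#' @return a tibble with one row per (target, condition): `protein`,
#'   `site`, `target_type`, `condition`, `estimate`, `n`.
#' @exportS3Method generics::tidy
tidy.ptm_model <- function(x, ...) {
  out <- tibble::tibble(
    protein = rep(x$protein, lengths(x$means)),
    site = rep(x$site, lengths(x$means)),
    target_type = rep(x$target_type, lengths(x$means)),
    condition = unlist(purrr::map(x$means, names)),
    estimate = unlist(x$means, use.names = FALSE),
    n = unlist(x$ns, use.names = FALSE)
  )
  out
}

#' One-row-per-target fit summary
#'
#' @param x a `ptm_model` from [fit_models()].
#' @param ... unused.
#' @return a tibble with `protein`, `site`, `target_type`, `design`,
#'   `resid_var`, `resid_df`, `mixture_var`, `n_runs`, `converged`.
#' @exportS3Method generics::glance
glance.ptm_model <- function(x, ...) {
  tibble::tibble(
    protein = x$protein, site = x$site, target_type = x$target_type,
    design = x$design, resid_var = x$resid_var, resid_df = x$resid_df,
    mixture_var = x$mixture_var, n_runs = x$n_runs, converged = x$converged
  )
}

#' Tidy differential-PTM results
#'
#' @param x a `ptm_results` tibble from [adjust_all()] or
#'   [ptm_differential()].
#' @param ... unused.
#' @return the results as a plain tibble (one row per site and contrast).
#' @exportS3Method generics::tidy
tidy.ptm_results <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summary counts of a differential-PTM analysis
#'
#' @param x a `ptm_results` tibble.
#' @param alpha FDR cutoff used for the significance count.
#' @param ... unused.
#' @return one row per contrast: numbers of tested, adjusted,
#'   passed-through and significant sites.
#' @exportS3Method generics::glance
glance.ptm_results <- function(x, alpha = 0.05, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$contrast),
    n_sites = dplyr::n(),
    n_adjusted = sum(.data$label == "ADJUSTED"),
    n_unadjusted = sum(.data$label == "PTM"),
    n_untestable = sum(is.na(.data$pvalue)),
    n_significant = sum(.data$adj_pvalue <= alpha, na.rm = TRUE),
    .groups = "drop"
  )
}
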