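#' Satterthwaite degrees of freedom for a combined contrast
#'
#' Effective degrees of freedom of the sum of two independent squared
#' standard errors: `(se1^2 + se2^2)^2 / (se1^4/df1 + se2^4/df2)`. When one
#' standard error is 0, the limit is the other component's df.
#'
#' @param se1,df1 standard error and df of the first component.
#' @param se2,df2 standard error and df of the second component.
#' @return degrees of freedom (vectorized).
#' @export
satterthwaite_df <- function(se1, df1, se2, df2) {
  combine_df(se1, df1, se2, df2)
}

#' Protein-adjusted PTM contrast
#'
#' Combines a PTM-level and a protein-level contrast inference for the same
#' condition pair into the adjusted test: the change in modification
#' abundance beyond the overall change in protein abundance. The estimate is
#' the exact difference of log2 fold changes, the standard error pools the
#' two model fits (`sqrt(se_ptm^2 + se_prot^2)`, the two experiments being
#' independent), and the df come from the Satterthwaite approximation.
#'
#' @param ptm one-row comparison result for the site (label `"PTM"`).
#' @param protein one-row comparison result for the parent protein.
#' @return a one-row tibble with label `"ADJUSTED"`, the combined
#'   `estimate`, `se`, `df`, `tstat`, `pvalue`, and the contributing
#'   components as `ptm_estimate`/`ptm_se`/`ptm_df` and
#'   `protein_estimate`/`protein_se`/`protein_df`.
#' @export
adjust_contrast <- function(ptm, protein) {
  if (!identical(ptm$contrast, protein$contrast)) {
    abort("PTM and protein results are for different contrasts",
          class = "ptm_contract_error")
  }
  est <- ptm$estimate - protein$estimate
  se <- sqrt(ptm$se^2 + protein$se^2)
  df <- combine_df(ptm$se, ptm$df, protein$se, protein$df)
  t <- ifelse(se > 0, est / se,
              ifelse(abs(est) > 0, sign(est) * Inf, 0))
  p <- ifelse(se > 0, 2 * pt(-abs(t), df), ifelse(abs(est) > 0, 0, 1))
  out <- tibble::tibble(
    protein = ptm$protein, site = ptm$site, label = "ADJUSTED",
    contrast = ptm$contrast, estimate = est, se = se, df = df,
    tstat = t, pvalue = p, issue = NA_character_
  )
  out$ptm_estimate <- ptm$estimate
  out$ptm_se <- ptm$se
  out$ptm_df <- ptm$df
  out$protein_estimate <- protein$estimate
  out$protein_se <- protein$se
  out$protein_df <- protein$df
  out
}

# Satterthwaite combination with the se -> 0 limits (vectorized).
combine_df <- function(se1, df1, se2, df2) {
  v1 <- se1^2; v2 <- se2^2
  df <- (v1 + v2)^2 / (v1^2 / df1 + v2^2 / df2)
  df <- ifelse(se1 == 0 & se2 == 0, df1 + df2,
               ifelse(se1 == 0, df2, ifelse(se2 == 0, df1, df)))
  df
}

#' Adjust all PTM results for protein-level changes
#'
#' Joins site-level and protein-level comparison results by (protein
#' accession, contrast) and applies [adjust_contrast()] wherever a protein
#' match with a testable fit exists. Sites lacking global profiling
#' information cannot be adjusted; their unadjusted PTM test is passed
#' through with `issue = "no_protein_match"` and label `"PTM"`. BH
#' correction is then applied, by default separately within each contrast
#' (adjusted and passed-through results form one family, since they appear
#' in one results table).
#'
#' @param ptm_results comparison results for site targets
#'   ([estimate_contrast()] on the PTM model).
#' @param protein_results comparison results for protein targets, or `NULL`
#'   (every site is then passed through unadjusted).
#' @param p_adjust_family `"per_contrast"` (default) or `"global"`.
#' @return a `ptm_results` tibble with one row per (site, contrast),
#'   including `adj_pvalue`.
#' @export
adjust_all <- function(ptm_results, protein_results = NULL,
                       p_adjust_family = c("per_contrast", "global")) {
  p_adjust_family <- match.arg(p_adjust_family)
  ptm <- dplyr::filter(ptm_results, .data$label == "PTM")
  if (!is.null(protein_results) && nrow(protein_results) > 0) {
    prot <- dplyr::filter(protein_results, .data$label == "PROTEIN")
    prot <- prot[, c("protein", "contrast", "estimate", "se", "df")]
    names(prot) <- c("protein", "contrast", "protein_estimate", "protein_se",
                     "protein_df")
    joined <- dplyr::left_join(ptm, prot, by = c("protein", "contrast"))
  } else {
    joined <- ptm
    joined$protein_estimate <- NA_real_
    joined$protein_se <- NA_real_
    joined$protein_df <- NA_real_
  }
  adjustable <- !is.na(joined$protein_estimate) & !is.na(joined$protein_se) &
    !is.na(joined$estimate) & !is.na(joined$se)
  out <- joined
  out$ptm_estimate <- joined$estimate
  out$ptm_se <- joined$se
  out$ptm_df <- joined$df
  idx <- which(adjustable)
  if (length(idx) > 0) {
    est <- joined$estimate[idx] - joined$protein_estimate[idx]
    se <- sqrt(joined$se[idx]^2 + joined$protein_se[idx]^2)
    df <- combine_df(joined$se[idx], joined$df[idx],
                     joined$protein_se[idx], joined$protein_df[idx])
    t <- ifelse(se > 0, est / se, ifelse(abs(est) > 0, Inf * sign(est), 0))
    p <- ifelse(se > 0, 2 * pt(-abs(t), df),
                ifelse(abs(est) > 0, 0, 1))
    out$estimate[idx] <- est
    out$se[idx] <- se
    out$df[idx] <- df
    out$tstat[idx] <- t
    out$pvalue[idx] <- p
    out$label[idx] <- "ADJUSTED"
  }
  no_match <- !adjustable & is.na(out$issue)
  out$issue[no_match] <- "no_protein_match"
  if (p_adjust_family == "per_contrast") {
    out <- dplyr::mutate(dplyr::group_by(out, .data$contrast),
                         adj_pvalue = bh_adjust(.data$pvalue))
    out <- dplyr::ungroup(out)
  } else {
    out$adj_pvalue <- bh_adjust(out$pvalue)
  }
  class(out) <- c("ptm_results", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment; missing p-values are excluded from the family size
#' and returned as `NA`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}
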