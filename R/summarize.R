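#' Log-sum summary of feature intensities
#'
#' Sums feature intensities on the original scale and returns the log2 of the
#' sum: `log2(sum(2^x))` over the non-missing entries. This is the
#' summarization underlying the ratio-based baseline methods.
#'
#' @param x numeric vector of log2 intensities, possibly with `NA`s.
#' @return a single log2 value, or `NA_real_` when every entry is missing
#'   (the run is then skipped, never zero-filled).
#' @export
summarize_log_sum <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  log2(sum(2^x))
}

#' Ratio summary for one run
#'
#' The replicate-wise log2 ratio of summed modified over summed unmodified
#' intensities: `summarize_log_sum(mod) - summarize_log_sum(unmod)`. Runs
#' lacking either side yield `NA` and are discarded by the ratio-based
#' baselines (a tracked loss; see [ratio_summaries()]).
#'
#' @param mod_values log2 intensities of the modified features in the run.
#' @param unmod_values log2 intensities of the unmodified features.
#' @return a single log2 ratio, or `NA_real_`.
#' @export
ratio_summarize <- function(mod_values, unmod_values) {
  summarize_log_sum(mod_values) - summarize_log_sum(unmod_values)
}

#' Median-polish run summaries for one target
#'
#' Runs Tukey's two-way median polish (overall + feature + run effects,
#' medians ignoring missing cells; at most 10 iterations, converged when the
#' change in total absolute residual falls below 1e-4 of its value) and
#' returns, per run, overall effect + that run's column effect. Columns with
#' no observed value are dropped, never zero-filled.
#'
#' @param mat numeric matrix, features in rows, runs (or run-channel cells)
#'   in columns; `NA` for missing.
#' @return named numeric vector of run summaries (names = kept column names).
#' @export
median_polish_summarize <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  keep <- colSums(!is.na(mat)) > 0
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) == 0 || nrow(mat) == 0) return(setNames(numeric(0), character(0)))
  if (nrow(mat) == 1) {
    return(setNames(as.numeric(mat[1, ]), colnames(mat)))
  }
  if (ncol(mat) == 1) {
    return(setNames(median(mat[, 1], na.rm = TRUE), colnames(mat)))
  }
  mp <- suppressWarnings(
    medpolish(mat, eps = 1e-4, maxiter = 10L, trace.iter = FALSE,
              na.rm = TRUE)
  )
  setNames(mp$overall + mp$col, colnames(mat))
}

#' Group features by summarization target
#'
#' Modified features are grouped per site (protein + site label); peptides
#' carrying several modification sites form their own composite-site target
#' and are never merged into single-site groups. Unmodified features are
#' grouped per protein.
#'
#' @param table a canonical feature table.
#' @return a nested tibble with one row per target: `protein`, `site`
#'   (`NA` for protein-level targets), `target_type` (`"site"` or
#'   `"protein"`), and `data`, the target's feature records.
#' @export
group_targets <- function(table) {
  validate_feature_table(table)
  if (nrow(table) == 0) {
    return(tibble::tibble(protein = character(), site = character(),
                          target_type = character(), data = list()))
  }
  tab <- dplyr::mutate(
    table,
    site = ifelse(.data$is_mod, .data$site, NA_character_),
    target_type = ifelse(.data$is_mod, "site", "protein")
  )
  tidyr::nest(dplyr::group_by(tab, .data$protein, .data$site,
                              .data$target_type))
}

run_cell <- function(run, channel) {
  ifelse(is.na(channel), run, paste(run, channel, sep = "::"))
}

#' Summarize feature intensities into per-run target abundances
#'
#' Collapses the feature-level log2 intensities of each target (PTM site or
#' protein) into one value per run -- per (run, channel) cell for TMT -- by
#' Tukey median polish (robust, the default) or log-sum. Runs with no
#' observed feature for a target yield no summary.
#'
#' @param table a canonical feature table (enriched tables should be passed
#'   through [clean_enriched()] first).
#' @param method `"median_polish"` or `"log_sum"`.
#' @param impute `"off"` (default) or `"protein"`: apply AFT imputation
#'   ([impute_aft()]) to unmodified-protein feature matrices before
#'   summarization. Imputation of enriched features is deliberately not
#'   offered: with few features per site the censored model is rarely
#'   identifiable.
#' @return a tibble of run summaries: `protein`, `site`, `target_type`,
#'   `run`, `channel`, `condition`, `mixture`, `replicate`, `log2inty`,
#'   `n_features`, `method`.
#' @export
summarize_runs <- function(table, method = c("median_polish", "log_sum"),
                           impute = c("off", "protein")) {
  method <- match.arg(method)
  impute <- match.arg(impute)
  if (method == "log_sum" && impute == "off") {
    return(summarize_runs_log_sum(table))
  }
  nested <- group_targets(table)
  if (nrow(nested) == 0) {
    return(tibble::tibble(
      protein = character(), site = character(), target_type = character(),
      run = character(), channel = character(), condition = character(),
      mixture = character(), replicate = character(), log2inty = double(),
      n_features = integer(), method = character()
    ))
  }

  summarize_one <- function(df, target_type) {
    cell <- run_cell(df$run, df$channel)
    feats <- unique(df$feature)
    cells <- unique(cell)
    mat <- matrix(NA_real_, length(feats), length(cells),
                  dimnames = list(feats, cells))
    mat[cbind(match(df$feature, feats), match(cell, cells))] <- df$log2inty
    if (impute == "protein" && target_type == "protein") {
      mat <- impute_aft(mat)
    }
    vals <- if (method == "median_polish") {
      median_polish_summarize(mat)
    } else {
      keep <- colSums(!is.na(mat)) > 0
      m2 <- mat[, keep, drop = FALSE]
      setNames(apply(m2, 2, summarize_log_sum), colnames(m2))
    }
    first <- !duplicated(cell)
    meta <- df[first, c("run", "channel", "condition", "mixture",
                        "replicate")]
    out <- meta[match(names(vals), cell[first]), ]
    out$log2inty <- as.numeric(vals)
    out$n_features <- nrow(mat)
    out
  }

  nested <- dplyr::ungroup(nested)
  out <- nested[, c("protein", "site", "target_type")]
  out$data <- purrr::map2(nested$data, nested$target_type, summarize_one)
  out <- tidyr::unnest(out, "data")
  out$method <- method
  out[, c("protein", "site", "target_type", "run", "channel", "condition",
          "mixture", "replicate", "log2inty", "n_features", "method")]
}

# Grouped log-sum summarization in one pass over the table (equivalent to
# the per-target route, but vectorized; exercised heavily by benchmarks).
summarize_runs_log_sum <- function(table) {
  validate_feature_table(table)
  tab <- dplyr::mutate(
    table,
    site = ifelse(.data$is_mod, .data$site, NA_character_),
    target_type = ifelse(.data$is_mod, "site", "protein")
  )
  n_feat <- dplyr::summarise(
    dplyr::group_by(tab, .data$protein, .data$site, .data$target_type),
    n_features = dplyr::n_distinct(.data$feature), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$protein, .data$site, .data$target_type,
                    .data$run, .data$channel, .data$condition,
                    .data$mixture, .data$replicate),
    log2inty = summarize_log_sum(.data$log2inty), .groups = "drop"
  )
  out <- dplyr::filter(out, !is.na(.data$log2inty))
  out <- dplyr::left_join(out, n_feat,
                          by = c("protein", "site", "target_type"))
  out$method <- "log_sum"
  out[, c("protein", "site", "target_type", "run", "channel", "condition",
          "mixture", "replicate", "log2inty", "n_features", "method")]
}

#' Join site and protein run summaries into replicate-wise ratios
#'
#' Builds the per-run log2 ratio `u_ij` consumed by the ratio-based baseline
#' methods: site summary minus the same run's protein summary. Runs present
#' on only one side are dropped; the attrition is returned in the `"loss"`
#' attribute, since this data loss is itself a quantity of interest when
#' comparing methods under missingness.
#'
#' @param ptm_summaries run summaries of site targets ([summarize_runs()]).
#' @param protein_summaries run summaries of protein targets.
#' @return a tibble with one row per (site, run) having both summaries:
#'   columns as in [summarize_runs()] plus `log2ratio`. Attribute `"loss"`
#'   is a one-row tibble with `n_protein_total`, `n_protein_discarded`
#'   (protein run summaries without a matching site summary),
#'   `n_ptm_total`, `n_ptm_discarded`.
#' @export
ratio_summaries <- function(ptm_summaries, protein_summaries) {
  ptm <- dplyr::filter(ptm_summaries, .data$target_type == "site")
  prot <- dplyr::filter(protein_summaries, .data$target_type == "protein")
  prot_small <- prot[, c("protein", "run", "channel", "log2inty")]
  names(prot_small)[names(prot_small) == "log2inty"] <- "log2inty_protein"
  joined <- dplyr::left_join(ptm, prot_small,
                             by = c("protein", "run", "channel"))
  kept <- dplyr::filter(joined, !is.na(.data$log2inty_protein))
  kept$log2ratio <- kept$log2inty - kept$log2inty_protein
  # protein summaries discarded: per site-target run slot where the protein
  # summary exists but the site summary does not
  slots <- dplyr::distinct(ptm, .data$protein, .data$site)
  prot_slots <- dplyr::inner_join(slots, prot_small, by = "protein")
  ptm_key <- paste(ptm$protein, ptm$site, ptm$run,
                   ifelse(is.na(ptm$channel), "", ptm$channel))
  prot_key <- paste(prot_slots$protein, prot_slots$site, prot_slots$run,
                    ifelse(is.na(prot_slots$channel), "", prot_slots$channel))
  n_prot_total <- nrow(prot_slots)
  n_prot_disc <- sum(!prot_key %in% ptm_key)
  n_ptm_total <- nrow(ptm)
  n_ptm_disc <- nrow(joined) - nrow(kept)
  loss <- tibble::tibble(
    n_protein_total = n_prot_total, n_protein_discarded = n_prot_disc,
    n_ptm_total = n_ptm_total, n_ptm_discarded = n_ptm_disc
  )
  out <- kept
  out$log2inty <- out$log2ratio
  out$log2ratio <- NULL
  out$log2inty_protein <- NULL
  out$method <- "ratio"
  attr(out, "loss") <- loss
  out
}

#' Impute missing intensities with an accelerated failure time model
#'
#' Treats each missing cell as left-censored at its feature's observed
#' minimum and fits a Gaussian AFT model (censored regression) with additive
#' feature and run effects on the log2 scale by maximum likelihood
#' ([survival::survreg()]). Missing cells are replaced by model predictions
#' capped at the censoring bound. Intended for unmodified-protein feature
#' matrices, where censoring (low abundance) is the plausible missingness
#' mechanism; use with care, it is off by default throughout the package.
#'
#' @param mat numeric matrix, features in rows and runs in columns, `NA`
#'   for missing cells.
#' @param enabled set `FALSE` for a no-op (convenience for pipelines).
#' @return the matrix with imputable missing cells filled in. Cells that
#'   cannot be imputed (feature never observed, model not identifiable) are
#'   left missing with a warning.
#' @export
impute_aft <- function(mat, enabled = TRUE) {
  if (!enabled || !anyNA(mat) || nrow(mat) < 2 || ncol(mat) < 2) return(mat)
  feat_min <- apply(mat, 1, function(x) suppressWarnings(min(x, na.rm = TRUE)))
  if (any(!is.finite(feat_min))) {
    warn("features with no observed value left unimputed")
  }
  long <- expand.grid(feature = seq_len(nrow(mat)), run = seq_len(ncol(mat)))
  long$y <- mat[cbind(long$feature, long$run)]
  long$bound <- feat_min[long$feature]
  long$observed <- !is.na(long$y)
  fit_data <- long[is.finite(long$bound), ]
  fit_data$time <- ifelse(fit_data$observed, fit_data$y, fit_data$bound)
  fit_data$feature <- factor(fit_data$feature)
  fit_data$run <- factor(fit_data$run)
  fit <- tryCatch(
    survival::survreg(
      survival::Surv(time, observed, type = "left") ~ feature + run,
      data = fit_data, dist = "gaussian"
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("AFT imputation model not identifiable; missing cells left as is")
    return(mat)
  }
  need <- fit_data[!fit_data$observed, ]
  if (nrow(need) == 0) return(mat)
  pred <- tryCatch(predict(fit, newdata = need), error = function(e) NULL)
  if (is.null(pred)) {
    warn("AFT prediction failed; missing cells left as is")
    return(mat)
  }
  imputed <- pmin(pred, need$bound)
  mat[cbind(as.integer(as.character(need$feature)),
            as.integer(as.character(need$run)))] <- imputed
  mat
}
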