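#' Configuration for a ground-truth PTM simulation
#'
#' Describes one simulated label-free group-comparison experiment with known
#' ground truth. Two presets reproduce the package's benchmark designs:
#' `"sim1"` is the clean case (10 modified and 10 unmodified features per
#' protein, no missing values), `"sim2"` the realistic case (2 modified
#' features, 20% of observations missing completely at random). In both,
#' each protein carries exactly one PTM site, and the proteins split evenly
#' into four truth classes:
#' \describe{
#'   \item{diff_direct}{the observed PTM abundance shifts by `effect`
#'     between the reference and every other condition; the protein is
#'     flat. Truly differential.}
#'   \item{diff_masked}{the observed PTM abundance is flat while the
#'     protein shifts by `-effect`: the modification change is fully masked
#'     by the protein change, so the adjusted change equals `effect`.
#'     Truly differential, invisible to unadjusted tests.}
#'   \item{null_flat}{both flat. Truly null.}
#'   \item{null_protein_driven}{both shift by `effect`: the apparent PTM
#'     change is entirely protein-driven, the adjusted change is 0. Truly
#'     null, a false positive for unadjusted tests.}
#' }
#'
#' @param preset `"sim1"` or `"sim2"`.
#' @param n_conditions number of conditions I (the effect is applied between
#'   condition 1 and every other condition).
#' @param n_replicates biological replicates J per condition.
#' @param sigma2 feature-level Gaussian noise variance (log2 scale).
#' @param n_proteins number of proteins (one PTM site each).
#' @param effect true log2 fold change of differential PTMs.
#' @param n_mod_features,n_unmod_features features per site / per protein
#'   (preset defaults: 10/10 for sim1, 2/10 for sim2).
#' @param missing_rate MCAR missingness probability per observation, applied
#'   independently to enriched and global tables (0 for sim1, 0.2 for sim2).
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution of
#'   proteins and sites.
#' @param feature_sd spread of fixed per-feature intensity offsets.
#' @param masked_sign sign of the protein shift in the masked class
#'   (default -1: the protein decreases while the modification holds).
#' @param seed integer seed; identical seeds give byte-identical tables.
#' @return a `ptm_sim_config` list.
#' @export
sim_config <- function(preset = c("sim1", "sim2"), n_conditions = 2,
                       n_replicates = 10, sigma2 = 0.2, n_proteins = 1000,
                       effect = 0.75, n_mod_features = NULL,
                       n_unmod_features = 10, missing_rate = NULL,
                       baseline_mean = 25, baseline_sd = 2, feature_sd = 1,
                       masked_sign = -1, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(n_mod_features)) {
    n_mod_features <- if (preset == "sim1") 10L else 2L
  }
  if (is.null(missing_rate)) {
    missing_rate <- if (preset == "sim1") 0 else 0.2
  }
  stopifnot(n_proteins > 0, n_conditions >= 2, n_replicates >= 2,
            n_mod_features > 0, n_unmod_features > 0, sigma2 > 0,
            missing_rate >= 0, missing_rate < 1)
  structure(
    list(preset = preset, n_proteins = as.integer(n_proteins),
         n_conditions = as.integer(n_conditions),
         n_replicates = as.integer(n_replicates), sigma2 = sigma2,
         effect = effect, n_mod_features = as.integer(n_mod_features),
         n_unmod_features = as.integer(n_unmod_features),
         missing_rate = missing_rate, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, feature_sd = feature_sd,
         masked_sign = masked_sign, seed = as.integer(seed)),
    class = "ptm_sim_config"
  )
}

truth_classes <- c("diff_direct", "diff_masked", "null_flat",
                   "null_protein_driven")

#' Simulate a PTM experiment with known ground truth
#'
#' Generates enriched and global feature tables in the canonical layout
#' (see [feature_table]) plus a ground-truth table. Per protein, a log2
#' baseline and fixed per-feature offsets are drawn; truth-class condition
#' shifts are applied to conditions 2..I; iid Gaussian noise
#' `N(0, sigma2)` is added to every observation; observations are then
#' deleted independently with probability `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return a list with `enriched`, `global` (canonical feature tables) and
#'   `truth` (tibble: `protein`, `site`, `truth_class`,
#'   `true_delta_ptm_observed`, `true_delta_protein`, `true_delta_adj`,
#'   for the contrast of any non-reference condition vs condition 1).
#' @export
simulate_ptm <- function(config) {
  stopifnot(inherits(config, "ptm_sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  I <- config$n_conditions
  J <- config$n_replicates
  K <- config$n_mod_features
  L <- config$n_unmod_features

  proteins <- sprintf("P%05d", seq_len(n))
  cls <- rep(truth_classes, length.out = n)
  base_prot <- rnorm(n, config$baseline_mean, config$baseline_sd)
  base_ptm <- rnorm(n, config$baseline_mean, config$baseline_sd)
  site_pos <- sample(10:500, n, replace = TRUE)
  sites <- paste0("S", site_pos)
  off_mod <- matrix(rnorm(n * K, 0, config$feature_sd), n, K)
  off_unmod <- matrix(rnorm(n * L, 0, config$feature_sd), n, L)

  e <- config$effect
  shift_ptm <- c(diff_direct = e, diff_masked = 0, null_flat = 0,
                 null_protein_driven = e)
  shift_prot <- c(diff_direct = 0, diff_masked = config$masked_sign * e,
                  null_flat = 0, null_protein_driven = e)

  conds <- sprintf("C%d", seq_len(I))
  make_table <- function(n_feat, base, off, shift, modified) {
    g <- tidyr::expand_grid(
      p = seq_len(n), k = seq_len(n_feat), ci = seq_len(I),
      j = seq_len(J)
    )
    val <- base[g$p] + off[cbind(g$p, g$k)] +
      ifelse(g$ci > 1, shift[cls[g$p]], 0) +
      rnorm(nrow(g), 0, sqrt(config$sigma2))
    if (config$missing_rate > 0) {
      val[runif(nrow(g)) < config$missing_rate] <- NA_real_
    }
    pep <- paste0(if (modified) "MODPEP" else "PEP", proteins[g$p], "_", g$k,
                  if (modified) "S*K" else "K")
    tibble::tibble(
      protein = proteins[g$p],
      site = if (modified) sites[g$p] else NA_character_,
      peptide = pep,
      charge = 2L,
      feature = paste(pep, 2L, sep = "_"),
      run = sprintf("R_%s_%02d", conds[g$ci], g$j),
      condition = conds[g$ci],
      mixture = NA_character_,
      channel = NA_character_,
      replicate = sprintf("%s_%02d", conds[g$ci], g$j),
      log2inty = val,
      is_mod = modified,
      origin = if (modified) "enriched" else "global"
    )
  }

  enriched <- make_table(K, base_ptm, off_mod, shift_ptm, TRUE)
  global <- make_table(L, base_prot, off_unmod, shift_prot, FALSE)
  truth <- tibble::tibble(
    protein = proteins, site = sites, truth_class = cls,
    true_delta_ptm_observed = unname(shift_ptm[cls]),
    true_delta_protein = unname(shift_prot[cls]),
    true_delta_adj = unname(shift_ptm[cls] - shift_prot[cls])
  )
  list(enriched = enriched, global = global, truth = truth)
}

#' Confusion metrics of differential-PTM calls against ground truth
#'
#' Calls a PTM positive when its BH-adjusted p-value is at or below `alpha`;
#' the truth positives are the `diff_direct` and `diff_masked` classes
#' (changes distinct from the overall protein change). PTMs without a
#' testable result count as negatives and are tracked in `n_untestable`.
#'
#' @param results a comparison-results tibble with `adj_pvalue` for a
#'   single contrast (e.g. from [adjust_all()] or [fit_baseline()]).
#' @param truth the `truth` table from [simulate_ptm()].
#' @param alpha FDR-adjusted p-value cutoff (default 0.05).
#' @return a one-row tibble: `TP`, `FP`, `TN`, `FN`, `accuracy`, `recall`,
#'   `efdr` (`FP/(TP+FP)`, defined as 0 when nothing is called),
#'   `n_untestable`.
#' @export
evaluate_calls <- function(results, truth, alpha = 0.05) {
  res <- results[, c("protein", "adj_pvalue")]
  joined <- dplyr::left_join(truth, res, by = "protein")
  positive <- !is.na(joined$adj_pvalue) & joined$adj_pvalue <= alpha
  truth_pos <- joined$truth_class %in% c("diff_direct", "diff_masked")
  TP <- sum(positive & truth_pos)
  FP <- sum(positive & !truth_pos)
  TN <- sum(!positive & !truth_pos)
  FN <- sum(!positive & truth_pos)
  tibble::tibble(
    TP = TP, FP = FP, TN = TN, FN = FN,
    accuracy = (TP + TN) / (TP + TN + FP + FN),
    recall = if (TP + FN > 0) TP / (TP + FN) else 0,
    efdr = if (TP + FP > 0) FP / (TP + FP) else 0,
    n_untestable = sum(is.na(joined$adj_pvalue))
  )
}
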