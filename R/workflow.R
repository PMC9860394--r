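#' Run the full differential-PTM workflow from a configuration
#'
#' Orchestrates convert -> (site localization) -> clean -> summarize ->
#' model -> adjust -> report, writing all intermediates, the final results
#' table, a warning-count summary and a machine-readable manifest (seed,
#' package version, full configuration echo) to the output directory.
#'
#' @param config a named list, or the path to a YAML file, with entries:
#'   \describe{
#'     \item{enriched}{path to the enriched feature table (required)}
#'     \item{global}{path to the global feature table (optional; without it
#'       every site is tested unadjusted and flagged)}
#'     \item{dialect}{input dialect, default `"generic_long"`}
#'     \item{intensity_scale}{`"raw"` (default) or `"log2"`}
#'     \item{fasta}{optional FASTA path for site localization}
#'     \item{mod_residues}{optional amino-acid letters for localization}
#'     \item{summarization}{`"median_polish"` (default) or `"log_sum"`}
#'     \item{impute}{`"off"` (default) or `"protein"`}
#'     \item{moderate}{logical, default `FALSE`}
#'     \item{contrasts}{`"all-pairwise"` (default) or a list of pairs}
#'     \item{alpha}{FDR cutoff used in the report summary, default 0.05}
#'     \item{output_dir}{output directory (required)}
#'     \item{seed}{integer seed recorded in the manifest, default 1}
#'   }
#' @return the results tibble, invisibly; side effect: files
#'   `summaries_ptm.csv`, `summaries_protein.csv`, `model_fits.csv`,
#'   `results.csv`, `issue_summary.csv`, `manifest.json` under
#'   `output_dir`.
#' @export
run_ptm_workflow <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(dialect = "generic_long", intensity_scale = "raw",
                   summarization = "median_polish",
                   impute = "off", moderate = FALSE,
                   contrasts = "all-pairwise", alpha = 0.05, seed = 1L)
  config <- utils::modifyList(defaults, config)
  for (req in c("enriched", "output_dir")) {
    if (is.null(config[[req]])) {
      abort(paste0("workflow config is missing '", req, "'"),
            class = "ptm_config_error")
    }
  }
  stopifnot(config$alpha > 0, config$alpha < 1)
  for (f in c("enriched", "global", "fasta")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      abort(paste0("workflow stage 'validate': file not found: ",
                   config[[f]]), class = "ptm_config_error")
    }
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("workflow stage '", name, "' failed: ",
                   conditionMessage(e)), class = "ptm_workflow_error")
    })
  }

  enriched <- stage("convert", read_feature_table(
    config$enriched, dialect = config$dialect, origin = "enriched",
    intensity_scale = config$intensity_scale
  ))
  global <- if (!is.null(config$global)) {
    stage("convert", read_feature_table(
      config$global, dialect = config$dialect, origin = "global",
      intensity_scale = config$intensity_scale
    ))
  }
  if (!is.null(config$fasta)) {
    enriched <- stage("locate_sites", locate_sites(
      enriched, config$fasta, mod_residues = config$mod_residues
    ))
  }
  if (is.list(config$contrasts)) {
    config$contrasts <- purrr::map(config$contrasts, as.character)
  }
  results <- stage("analyze", ptm_differential(
    enriched, global, contrasts = config$contrasts,
    summarization = config$summarization, moderate = config$moderate,
    impute = config$impute
  ))

  ptm_model <- attr(results, "ptm_model")
  prot_model <- attr(results, "protein_model")
  out <- function(name) file.path(config$output_dir, name)
  readr::write_csv(summarize_runs(clean_enriched(enriched),
                                  method = config$summarization),
                   out("summaries_ptm.csv"), progress = FALSE)
  if (!is.null(global)) {
    readr::write_csv(summarize_runs(global, method = config$summarization,
                                    impute = config$impute),
                     out("summaries_protein.csv"), progress = FALSE)
  }
  fits <- dplyr::bind_rows(glance(ptm_model),
                           if (!is.null(prot_model)) glance(prot_model))
  readr::write_csv(fits, out("model_fits.csv"), progress = FALSE)
  readr::write_csv(as.data.frame(results), out("results.csv"),
                   progress = FALSE)
  issues <- dplyr::count(
    dplyr::mutate(results, issue = tidyr::replace_na(.data$issue, "none")),
    .data$contrast, .data$label, .data$issue, name = "n_targets"
  )
  readr::write_csv(issues, out("issue_summary.csv"), progress = FALSE)
  manifest <- list(
    package = "ptmquant",
    version = as.character(utils::packageVersion("ptmquant")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "output_dir")],
    n_sites = length(unique(paste(results$protein, results$site))),
    n_significant = sum(results$adj_pvalue <= config$alpha, na.rm = TRUE)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(results)
}
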