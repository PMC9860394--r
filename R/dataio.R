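#' Canonical feature-table columns
#'
#' A feature table holds one quantified spectral feature (peptide ion) per
#' run (and TMT channel, if any), on the log2 scale. All ptmquant functions
#' consume and return this canonical layout.
#'
#' @format Columns of a canonical feature table:
#' \describe{
#'   \item{protein}{protein accession}
#'   \item{site}{modification site label such as `"S70"`, `"S70+T81"` for
#'     multi-site peptides, or `NA` for unmodified features}
#'   \item{peptide}{(modified) peptide sequence as reported upstream}
#'   \item{charge}{precursor charge state}
#'   \item{feature}{feature identifier, `peptide_charge`}
#'   \item{run}{MS run identifier}
#'   \item{condition}{experimental condition}
#'   \item{mixture}{TMT mixture identifier or `NA` (label-free)}
#'   \item{channel}{TMT channel or `NA` (label-free)}
#'   \item{replicate}{biological replicate / subject identifier}
#'   \item{log2inty}{log2 intensity, `NA` when missing}
#'   \item{is_mod}{whether the feature carries the modification}
#'   \item{origin}{`"enriched"` or `"global"`}
#' }
#' @name feature_table
NULL

ft_cols <- c(
  "protein", "site", "peptide", "charge", "feature", "run", "condition",
  "mixture", "channel", "replicate", "log2inty", "is_mod", "origin"
)

dialect_maps <- list(
  generic_long = c(
    protein = "ProteinName", peptide = "PeptideSequence",
    charge = "PrecursorCharge", run = "Run", condition = "Condition",
    replicate = "BioReplicate", intensity = "Intensity",
    site = "Site", mixture = "Mixture", channel = "Channel"
  ),
  maxquant_sites = c(
    protein = "Proteins", peptide = "Modified.sequence", charge = "Charge",
    run = "Raw.file", condition = "Condition", replicate = "BioReplicate",
    intensity = "Intensity", site = "Site", mixture = "Mixture",
    channel = "Channel"
  ),
  spectronaut = c(
    protein = "PG.ProteinAccessions", peptide = "EG.ModifiedSequence",
    charge = "FG.Charge", run = "R.FileName", condition = "R.Condition",
    replicate = "R.Replicate", intensity = "FG.Quantity",
    site = "Site", mixture = "Mixture", channel = "Channel"
  )
)

#' Read a feature-level quantification table
#'
#' Reads a long-format delimited table exported by an upstream spectral
#' processing tool and converts it to the canonical layout (see
#' [feature_table]). Non-positive and non-finite intensities become missing;
#' raw-scale intensities are log2-transformed.
#'
#' @param path path to a CSV/TSV file.
#' @param dialect column-naming convention of the input:
#'   `"generic_long"`, `"maxquant_sites"`, or `"spectronaut"`.
#' @param origin `"enriched"` (modification-enriched runs) or `"global"`
#'   (global profiling runs).
#' @param intensity_scale `"raw"` (default; intensities are log2-transformed
#'   on read) or `"log2"` (taken as-is).
#' @param mod_marker regular expression matching the in-sequence modification
#'   marker placed after the modified residue (default `"\\*"`, i.e.
#'   `"ABS*CK"` marks the serine).
#' @return a canonical feature-table tibble with `origin` stamped.
#' @export
read_feature_table <- function(path,
                               dialect = c("generic_long", "maxquant_sites",
                                           "spectronaut"),
                               origin = c("enriched", "global"),
                               intensity_scale = c("raw", "log2"),
                               mod_marker = "\\*") {
  dialect <- match.arg(dialect)
  origin <- match.arg(origin)
  intensity_scale <- match.arg(intensity_scale)
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "ptm_io_error")
  }
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = c("", "NA", "NaN"))
  map <- dialect_maps[[dialect]]
  required <- map[c("protein", "peptide", "charge", "run", "condition",
                    "replicate", "intensity")]
  missing_cols <- setdiff(unname(required), names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required column(s) for dialect '", dialect, "': ",
             paste(missing_cols, collapse = ", ")),
      class = "ptm_schema_error"
    )
  }
  get_col <- function(key, default = NA_character_) {
    nm <- map[[key]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else
      rep(default, nrow(raw))
  }
  inty <- suppressWarnings(as.numeric(raw[[map[["intensity"]]]]))
  inty[!is.finite(inty) | inty <= 0 & intensity_scale == "raw"] <- NA_real_
  log2inty <- if (intensity_scale == "raw") log2(inty) else inty
  log2inty[!is.finite(log2inty)] <- NA_real_

  tab <- tibble::tibble(
    protein = as.character(get_col("protein")),
    site = as.character(get_col("site")),
    peptide = as.character(get_col("peptide")),
    charge = as.integer(raw[[map[["charge"]]]]),
    run = as.character(get_col("run")),
    condition = as.character(get_col("condition")),
    mixture = as.character(get_col("mixture")),
    channel = as.character(get_col("channel")),
    replicate = as.character(get_col("replicate")),
    log2inty = log2inty
  )
  tab$feature <- paste(tab$peptide, tab$charge, sep = "_")
  tab$is_mod <- !is.na(tab$site) | grepl(mod_marker, tab$peptide)
  tab$origin <- origin
  tab <- tab[, ft_cols]
  validate_feature_table(tab)
  tab
}

#' Write a canonical feature table
#'
#' Writes the canonical layout back to disk in the `generic_long` dialect,
#' with intensities on the log2 scale (read back with
#' `intensity_scale = "log2"` for a lossless round trip).
#'
#' @param table a canonical feature table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  out <- tibble::tibble(
    ProteinName = table$protein,
    Site = table$site,
    PeptideSequence = table$peptide,
    PrecursorCharge = table$charge,
    Run = table$run,
    Condition = table$condition,
    Mixture = table$mixture,
    Channel = table$channel,
    BioReplicate = table$replicate,
    Intensity = table$log2inty
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a canonical feature table
#'
#' Checks the structural invariants of the canonical layout: all columns
#' present, intensities finite where observed, no duplicated
#' (feature, run, channel) combination within a target, and no site label on
#' unmodified records.
#'
#' @param table a candidate feature table.
#' @return `table`, invisibly, or an error describing the violation.
#' @export
validate_feature_table <- function(table) {
  missing_cols <- setdiff(ft_cols, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("not a canonical feature table; missing: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ptm_schema_error")
  }
  obs <- table$log2inty[!is.na(table$log2inty)]
  if (any(!is.finite(obs))) {
    abort("non-finite log2 intensities present", class = "ptm_schema_error")
  }
  key <- paste(table$protein, table$feature, table$run,
               ifelse(is.na(table$channel), "", table$channel))
  if (anyDuplicated(key) > 0) {
    dup <- table[duplicated(key), , drop = FALSE]
    abort(
      paste0("duplicated (feature, run, channel) rows, e.g. feature '",
             dup$feature[1], "' in run '", dup$run[1], "'"),
      class = "ptm_integrity_error"
    )
  }
  if (any(!table$is_mod & !is.na(table$site))) {
    abort("unmodified records must not carry a site label",
          class = "ptm_schema_error")
  }
  invisible(table)
}

#' Remove unmodified features from enriched runs
#'
#' Enrichment (e.g. phospho- or KGG-enrichment) is imperfect, so enriched
#' runs also contain unmodified background peptides. These carry no
#' information about the modification and are removed before summarization.
#'
#' @param table a canonical feature table with `origin = "enriched"`.
#' @return the table with all `is_mod = FALSE` records dropped.
#' @export
clean_enriched <- function(table) {
  validate_feature_table(table)
  dplyr::filter(table, .data$is_mod)
}

# Accession from a FASTA header: UniProt-style "sp|P12345|NAME ..." yields
# P12345; otherwise the first whitespace-delimited token.
fasta_accession <- function(header) {
  first <- sub("\\s.*$", "", header)
  parts <- strsplit(first, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2 && parts[1] %in% c("sp", "tr")) parts[2] else parts[1]
}

#' Localize modification sites from peptide sequences and a FASTA database
#'
#' When the upstream tool reports only the modified peptide sequence (with an
#' in-sequence marker after the modified residue, e.g. `"ABS*CK"`), the site
#' is localized by matching the stripped peptide against the full protein
#' sequence. A modification of the 70th residue, a serine, is labelled
#' `"S70"`; peptides carrying several markers get a `"+"`-joined composite
#' label. Positions are 1-based within the full protein sequence.
#'
#' @param table a canonical feature table.
#' @param fasta path to a protein FASTA file containing every referenced
#'   accession.
#' @param mod_residues optional character vector of amino-acid letters that
#'   can carry the modification (e.g. `c("S","T","Y")`); marked residues
#'   outside this set raise an error.
#' @param mod_marker regular expression for the in-sequence marker
#'   (default `"\\*"`).
#' @param keep_first if `TRUE`, a peptide matching several positions in its
#'   protein is assigned the first occurrence instead of raising an
#'   ambiguity error.
#' @return the table with `site` filled in for every modified record;
#'   unmodified records are untouched. Idempotent.
#' @export
locate_sites <- function(table, fasta, mod_residues = NULL,
                         mod_marker = "\\*", keep_first = FALSE) {
  validate_feature_table(table)
  seqs <- Biostrings::readAAStringSet(fasta)
  acc <- vapply(names(seqs), fasta_accession, character(1))
  seq_chr <- setNames(as.character(seqs), acc)

  todo <- dplyr::distinct(
    dplyr::filter(table, .data$is_mod),
    .data$protein, .data$peptide
  )
  if (nrow(todo) == 0) return(table)

  site_for <- function(protein, peptide) {
    if (!protein %in% names(seq_chr)) {
      abort(paste0("accession not found in FASTA: ", protein),
            class = "ptm_lookup_error")
    }
    chars <- strsplit(peptide, "")[[1]]
    is_marker <- grepl(mod_marker, chars)
    if (!any(is_marker)) return(NA_character_)
    stripped <- paste(chars[!is_marker], collapse = "")
    # residue index (within stripped peptide) preceding each marker
    pep_pos <- cumsum(!is_marker)[is_marker]
    if (any(pep_pos == 0)) {
      abort(paste0("marker precedes any residue in peptide: ", peptide),
            class = "ptm_localization_error")
    }
    hits <- gregexpr(stripped, seq_chr[[protein]], fixed = TRUE)[[1]]
    if (hits[1] == -1) {
      abort(paste0("peptide not found in protein ", protein, ": ", stripped),
            class = "ptm_localization_error")
    }
    if (length(hits) > 1 && !keep_first) {
      abort(
        paste0("peptide maps to ", length(hits), " positions in ", protein,
               ": ", stripped, " (use keep_first = TRUE to take the first)"),
        class = "ptm_ambiguity_error"
      )
    }
    start <- hits[1]
    residues <- chars[!is_marker][pep_pos]
    if (!is.null(mod_residues) && !all(residues %in% mod_residues)) {
      abort(paste0("marked residue not in mod_residues for peptide: ",
                   peptide), class = "ptm_localization_error")
    }
    paste0(residues, start - 1L + pep_pos, collapse = "+")
  }

  todo$site_new <- purrr::map2_chr(todo$protein, todo$peptide, site_for)
  out <- dplyr::left_join(table, todo, by = c("protein", "peptide"))
  out$site <- ifelse(out$is_mod & !is.na(out$site_new), out$site_new, out$site)
  out$site_new <- NULL
  validate_feature_table(out)
  out
}
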