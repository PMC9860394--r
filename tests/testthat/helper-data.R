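# Small in-code fixtures shared across test files.

# A canonical feature-table tibble from parallel vectors, filling defaults.
make_ft <- function(protein, peptide, run, condition, log2inty,
                    site = NA_character_, charge = 2L,
                    replicate = condition, mixture = NA_character_,
                    channel = NA_character_, is_mod = !is.na(site),
                    origin = "enriched") {
  tibble::tibble(
    protein = protein, site = site, peptide = peptide, charge = charge,
    feature = paste(peptide, charge, sep = "_"), run = run,
    condition = condition, mixture = mixture, channel = channel,
    replicate = replicate, log2inty = log2inty, is_mod = is_mod,
    origin = origin
  )
}

# Run summaries for a single target, one value per run.
make_summaries <- function(values, conditions, target_type = "site",
                           protein = "P1", site = "S70",
                           mixture = NA_character_) {
  n <- length(values)
  tibble::tibble(
    protein = protein,
    site = if (target_type == "site") site else NA_character_,
    target_type = target_type,
    run = sprintf("R%02d", seq_len(n)),
    channel = NA_character_,
    condition = conditions,
    mixture = rep_len(mixture, n),
    replicate = sprintf("%s_%d", conditions, seq_len(n)),
    log2inty = values,
    n_features = 1L,
    method = "median_polish"
  )
}

# Write a generic_long CSV (raw-scale intensities) and return its path.
write_generic_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

# One-protein FASTA with serine at position 70 (peptide MSTK at 69..72).
demo_fasta <- function(path = tempfile(fileext = ".fasta")) {
  seq70 <- paste0(strrep("G", 68), "MSTK", "ASDTR", strrep("L", 10))
  writeLines(c(">sp|P00001|DEMO_HUMAN demo", seq70,
               ">P00002", paste0("AAKAAK", strrep("W", 20))), path)
  path
}
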