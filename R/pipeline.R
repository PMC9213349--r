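#' Run the authentication pipeline end to end
#'
#' Filters evidence, labels records original/contaminant by the
#' contaminant accession list, estimates the modification-level profile
#' per sample and group with bootstrap CIs, classifies proteins by the
#' marker-peptide rules (including the conservative contaminant
#' reclassification), and summarizes peptide taxonomy as LCA tree views.
#' All tables are written as TSV under `out_dir` together with a JSON
#' manifest recording the configuration hash and seed, so a rerun with the
#' same inputs and seed reproduces the outputs exactly.
#'
#' @param records Evidence tibble (see [read_evidence()] or
#'   [simulate_evidence()]).
#' @param contaminants Contaminant accession vector.
#' @param panel Reference panel for classification (see
#'   [classify_proteins()]).
#' @param target_clade Species labels of the endogenous clade.
#' @param tree Optional [taxonomy_tree()] for LCA profiling.
#' @param peptide_taxa Optional peptide -> taxa map (see
#'   [assign_peptides()]).
#' @param exclude_groups Optional reference-group roots for the LCA
#'   exclusion rule.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the bootstrap.
#' @param min_score Score filter (default 40).
#' @param max_missed_cleavages Missed-cleavage filter (default 3).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param mod_panel Modification panel (default [default_mod_panel()] plus
#'   a pooled `NQ` deamidation row used by the conservative rule).
#' @param human_label Human species label.
#' @return List with `profile`, `calls`, `assignments`, `clade_summary`,
#'   `manifest` (also written to disk), invisibly.
#' @export
run_authentication <- function(records, contaminants, panel, target_clade,
                               tree = NULL, peptide_taxa = NULL,
                               exclude_groups = NULL,
                               out_dir, seed, min_score = 40,
                               max_missed_cleavages = 3, n_boot = 1000,
                               mod_panel = NULL,
                               human_label = "Homo sapiens") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(mod_panel)) {
    mod_panel <- dplyr::bind_rows(
      default_mod_panel(),
      tibble::tibble(residue = "NQ", mod_name = "deamidation")
    )
  }
  n_in <- nrow(records)
  filtered <- filter_records(records, min_score = min_score,
                             max_missed_cleavages = max_missed_cleavages,
                             quiet = TRUE)
  filtered <- assign_groups(filtered, contaminants)
  message("authentication: ", nrow(filtered), "/", n_in,
          " records pass filters (score >= ", min_score, ", intensity, <= ",
          max_missed_cleavages, " missed cleavages)")

  profile <- group_profile(filtered, panel = mod_panel,
                           n_boot = n_boot, seed = seed)
  attribution <- tibble::tibble(
    accession = as.character(unlist(filtered$proteins)),
    peptide = rep(filtered$sequence, lengths(filtered$proteins))
  )
  calls <- classify_proteins(attribution, panel, contaminants, target_clade,
                             human_label)
  calls <- apply_conservative_flag(calls, filtered, profile)

  artifacts <- character(0)
  write_tsv_artifact <- function(tab, file) {
    path <- file.path(out_dir, file)
    flat <- tab
    for (col in names(flat)) {
      if (is.list(flat[[col]])) {
        flat[[col]] <- vapply(flat[[col]], function(x) {
          paste(unlist(x), collapse = ";")
        }, character(1))
      }
    }
    readr::write_tsv(flat, path, progress = FALSE)
    artifacts <<- c(artifacts, file)
    path
  }
  write_tsv_artifact(profile, "mod_levels.tsv")
  write_tsv_artifact(calls, "protein_calls.tsv")

  assignments <- NULL
  clade_summary <- NULL
  if (!is.null(tree) && !is.null(peptide_taxa)) {
    original <- filtered[filtered$group == "original", ]
    assignments <- assign_peptides(tree, peptide_taxa,
                                   unique(original$sequence),
                                   exclude_groups = exclude_groups)
    clade_summary <- treeview(tree, assignments)
    write_tsv_artifact(assignments, "peptide_assignments.tsv")
    write_tsv_artifact(clade_summary, "clade_summary.tsv")
  }
  counts <- tibble::tibble(
    stage = c("input", "filtered", "original", "contaminant"),
    n = c(n_in, nrow(filtered), sum(filtered$group == "original"),
          sum(filtered$group == "contaminant"))
  )
  write_tsv_artifact(counts, "stage_counts.tsv")

  manifest <- list(
    pipeline = "authentication",
    seed = seed,
    parameters = list(min_score = min_score,
                      max_missed_cleavages = max_missed_cleavages,
                      n_boot = n_boot, human_label = human_label,
                      target_clade = target_clade),
    config_hash = rlang::hash(list(min_score, max_missed_cleavages, n_boot,
                                   target_clade, human_label, seed)),
    artifacts = artifacts,
    n_records_in = n_in,
    n_records_filtered = nrow(filtered)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(profile = profile, calls = calls, assignments = assignments,
                 clade_summary = clade_summary, manifest = manifest))
}

#' Run the collagen characterization pipeline
#'
#' Maps observed peptides onto a reference alpha chain with
#' substitution/indel calling, computes coverage, validates the
#' Gly-Xaa-Yaa repeat over the reference, and (when a multi-species panel
#' is supplied) tabulates diagnostic sites. Writes alignment, edit,
#' coverage and diagnostic-site TSVs plus a manifest under `out_dir`.
#'
#' @param peptides Character vector of observed peptides (shorter than 6
#'   residues are skipped with a warning).
#' @param reference One-row reference tibble (see [read_fasta()]).
#' @param panel_refs Optional multi-species reference panel for
#'   [diagnostic_sites()].
#' @param out_dir Output directory.
#' @param max_edits Maximum edits per placement (default 2).
#' @return List with `alignments`, `edits`, `coverage`, `triplets`,
#'   `diagnostics`, `manifest`, invisibly.
#' @export
run_collagen <- function(peptides, reference, panel_refs = NULL, out_dir,
                         max_edits = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- as_reference(reference)
  alignments <- map_peptides(peptides, reference, max_edits = max_edits)
  cov <- coverage(alignments, reference)
  edits <- if (nrow(alignments)) {
    tidyr::unnest(alignments[, c("peptide", "edits")], "edits")
  } else {
    tibble::tibble(peptide = character(), type = character(),
                   ref_position = integer(), ref_residue = character(),
                   obs_residue = character(), note = character())
  }
  trip <- validate_triplets(reference$residues, frame = NULL,
                            offset = reference$numbering_offset)
  diagnostics <- NULL
  if (!is.null(panel_refs)) {
    diagnostics <- diagnostic_sites(panel_refs, alignment_calls(alignments))
  }
  artifacts <- character(0)
  save_tsv <- function(tab, file) {
    flat <- tab
    for (col in names(flat)) {
      if (is.list(flat[[col]])) flat[[col]] <- NULL
    }
    readr::write_tsv(flat, file.path(out_dir, file), progress = FALSE)
    artifacts <<- c(artifacts, file)
  }
  save_tsv(alignments, "alignments.tsv")
  save_tsv(edits, "edits.tsv")
  save_tsv(tibble::tibble(accession = cov$accession,
                          chain_length = cov$chain_length,
                          n_fragments = cov$n_fragments,
                          n_covered = length(cov$covered_positions),
                          pct_covered = cov$pct_covered),
           "coverage.tsv")
  save_tsv(trip$violations, "triplet_violations.tsv")
  if (!is.null(diagnostics)) save_tsv(diagnostics, "diagnostic_sites.tsv")

  summary_lines <- c(
    sprintf("reference %s: %d residues", cov$accession, cov$chain_length),
    sprintf("%d of %d peptides placed (max %d edits)",
            nrow(alignments), length(peptides), max_edits),
    sprintf("coverage: %.1f%% (%d positions)", cov$pct_covered,
            length(cov$covered_positions)),
    sprintf("edit calls: %d", nrow(edits)),
    sprintf("Gly-Xaa-Yaa frame %d: %d violation(s) across %d triplets",
            trip$frame, nrow(trip$violations), trip$n_triplets)
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  artifacts <- c(artifacts, "summary.txt")
  manifest <- list(
    pipeline = "collagen",
    parameters = list(max_edits = max_edits,
                      reference = reference$accession),
    config_hash = rlang::hash(list(max_edits, reference$accession,
                                   reference$residues)),
    artifacts = artifacts,
    n_peptides_in = length(peptides),
    n_aligned = nrow(alignments)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(alignments = alignments, edits = edits, coverage = cov,
                 triplets = trip, diagnostics = diagnostics,
                 manifest = manifest))
}
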