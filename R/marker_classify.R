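#' Classify a protein by marker-peptide rules
#'
#' Applies the marker-peptide classification used to authenticate ancient
#' proteins: a protein is `contaminant` when its accession is on the
#' contaminant list; `not_identified` with fewer than two matched peptides;
#' `endogenous_specific` when at least one of its peptides (a marker
#' peptide) occurs only in species of the target clade; otherwise
#' `shared_including_human` when any peptide's species set includes the
#' human label, else `shared_non_human`. Peptides absent from the reference
#' panel are counted as unresolvable and ignored for the class decision.
#'
#' @param accession Protein accession.
#' @param peptides Character vector of peptides attributed to the protein.
#' @param panel Reference panel: named list `peptide -> character vector of
#'   species labels`, or a data frame with columns `peptide` and `species`
#'   (list column). Peptide keys are I/L-normalized.
#' @param contaminants Character vector of contaminant accessions.
#' @param target_clade Character vector of species labels making up the
#'   endogenous target clade.
#' @param human_label Species label treated as human (default
#'   `"Homo sapiens"`).
#' @return One-row tibble: `accession`, `n_peptides`, `class_label`,
#'   `marker_peptides` (list), `n_unresolved`.
#' @export
classify_protein <- function(accession, peptides, panel, contaminants,
                             target_clade, human_label = "Homo sapiens") {
  panel <- as_panel(panel)
  call <- tibble::tibble(
    accession = accession, n_peptides = length(peptides),
    class_label = NA_character_,
    marker_peptides = list(character(0)), n_unresolved = 0L
  )
  if (accession %in% contaminants) {
    call$class_label <- "contaminant"
    return(call)
  }
  if (length(peptides) < 2) {
    call$class_label <- "not_identified"
    return(call)
  }
  keys <- normalize_il(peptides)
  species_sets <- panel[keys]
  unresolved <- vapply(species_sets, is.null, logical(1))
  call$n_unresolved <- sum(unresolved)
  if (any(unresolved)) {
    warning("protein ", accession, ": ", sum(unresolved),
            " peptide(s) not in reference panel, ignored", call. = FALSE)
  }
  species_sets <- species_sets[!unresolved]
  resolved_peptides <- peptides[!unresolved]
  if (length(species_sets) == 0) {
    call$class_label <- "shared_non_human"  # no evidence either way
    return(call)
  }
  is_marker <- vapply(species_sets, function(sp) {
    length(sp) > 0 && all(sp %in% target_clade)
  }, logical(1))
  if (any(is_marker)) {
    call$class_label <- "endogenous_specific"
    call$marker_peptides <- list(resolved_peptides[is_marker])
    return(call)
  }
  has_human <- vapply(species_sets, function(sp) human_label %in% sp, logical(1))
  call$class_label <- if (any(has_human)) "shared_including_human" else "shared_non_human"
  call
}

as_panel <- function(panel) {
  if (is.data.frame(panel)) {
    panel <- stats::setNames(panel$species, normalize_il(panel$peptide))
  } else {
    names(panel) <- normalize_il(names(panel))
  }
  panel
}

#' Classify every protein in an attribution table
#'
#' @param attribution Data frame with columns `accession` and `peptide`
#'   (one row per attributed peptide), or columns `accession` and
#'   `peptides` (list column).
#' @inheritParams classify_protein
#' @return Tibble of protein calls, one row per accession, sorted by
#'   accession.
#' @export
classify_proteins <- function(attribution, panel, contaminants, target_clade,
                              human_label = "Homo sapiens") {
  if ("peptides" %in% names(attribution)) {
    accs <- attribution$accession
    peps <- attribution$peptides
  } else {
    split_peps <- split(attribution$peptide, attribution$accession)
    accs <- names(split_peps)
    peps <- unname(split_peps)
  }
  if (length(accs) == 0) {
    return(tibble::tibble(accession = character(), n_peptides = integer(),
                          class_label = character(), marker_peptides = list(),
                          n_unresolved = integer()))
  }
  panel <- as_panel(panel)
  calls <- lapply(seq_along(accs), function(i) {
    classify_protein(accs[i], unique(peps[[i]]), panel, contaminants,
                     target_clade, human_label)
  })
  out <- dplyr::bind_rows(calls)
  out[order(out$accession), , drop = FALSE]
}

#' Conservative contaminant reclassification by modification profile
#'
#' The precautionary rule for proteins (typically keratins) whose peptides
#' are shared with human: when such a protein's own peptide deamidation
#' level looks like the contaminant population rather than the endogenous
#' one, it is conservatively reclassified as a contaminant. The qualitative
#' "similar profile" judgment is formalized as: the protein's deamidation
#' point estimate falls inside the contaminant group's bootstrap CI and
#' outside the original group's CI. Proteins without N/Q evidence are left
#' unchanged and flagged indeterminate.
#'
#' @param call One-row protein call (see [classify_protein()]).
#' @param protein_deamidation_pct The protein's own peptide deamidation
#'   point estimate (percent; `NA` when the protein has no N/Q sites).
#' @param contaminant_ci,original_ci Length-2 numeric vectors
#'   `c(low, high)` in percent: the group-level bootstrap CIs.
#' @return The call, possibly with `class_label` set to `contaminant`, and
#'   an added logical column `indeterminate`.
#' @export
conservative_contaminant_flag <- function(call, protein_deamidation_pct,
                                          contaminant_ci, original_ci) {
  call$indeterminate <- FALSE
  if (call$class_label != "shared_including_human") return(call)
  if (is.na(protein_deamidation_pct)) {
    call$indeterminate <- TRUE
    return(call)
  }
  inside <- function(x, ci) x >= ci[1] & x <= ci[2]
  if (inside(protein_deamidation_pct, contaminant_ci) &&
      !inside(protein_deamidation_pct, original_ci)) {
    call$class_label <- "contaminant"
  }
  call
}

#' Apply the conservative contaminant rule across a call table
#'
#' Computes each shared-including-human protein's own pooled N/Q
#' deamidation level from its evidence records and applies
#' [conservative_contaminant_flag()] against the group-level CIs taken
#' from a modification profile.
#'
#' @param calls Protein call table (see [classify_proteins()]).
#' @param records Filtered, group-labeled evidence tibble.
#' @param profile Output of [group_profile()] containing pooled `NQ`
#'   deamidation rows for groups `original` and `contaminant` (any sample;
#'   when several samples are present the widest CI envelope is used).
#' @return Call table with the rule applied and an `indeterminate` column.
#' @export
apply_conservative_flag <- function(calls, records, profile) {
  nq <- profile[profile$mod_name == "deamidation" & profile$residue == "NQ", ]
  ci_for <- function(grp) {
    rows <- nq[nq$group == grp, ]
    if (nrow(rows) == 0) return(c(NA_real_, NA_real_))
    c(min(rows$ci_low_pct), max(rows$ci_high_pct))
  }
  cont_ci <- ci_for("contaminant")
  orig_ci <- ci_for("original")
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, , drop = FALSE]
    if (call$class_label == "shared_including_human" &&
        !anyNA(c(cont_ci, orig_ci))) {
      sub <- records[vapply(records$proteins,
                            function(p) call$accession %in% p, logical(1)), ]
      pct <- if (nrow(sub)) modification_fraction(sub, c("N", "Q"), "deamidation")
             else NA_real_
      call <- conservative_contaminant_flag(call, pct, cont_ci, orig_ci)
    } else {
      call$indeterminate <- FALSE
    }
    out[[i]] <- call
  }
  dplyr::bind_rows(out)
}
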