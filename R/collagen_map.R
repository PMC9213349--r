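#' In-silico tryptic digestion
#'
#' Cleaves after K or R (by default not when the next residue is proline)
#' and enumerates all products with up to `max_missed` uncut internal
#' sites. Coordinates are 1-based inclusive positions in the input
#' sequence; zero-missed-cleavage products concatenate back to the input.
#'
#' @param seq Protein sequence.
#' @param max_missed Maximum missed cleavages per product (default 3).
#' @param min_len Minimum product length to report (default 1).
#' @param proline_rule Suppress cleavage before proline (default TRUE).
#' @return Tibble with columns `peptide`, `start`, `end`, `missed`.
#' @export
tryptic_digest <- function(seq, max_missed = 3, min_len = 1,
                           proline_rule = TRUE) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (proline_rule && length(cut_after)) {
    cut_after <- cut_after[res[cut_after + 1L] != "P"]
  }
  bounds <- c(0L, cut_after, n)  # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  starts <- integer(0)
  ends <- integer(0)
  missed <- integer(0)
  for (mc in 0:max_missed) {
    i <- seq_len(nfrag - mc)
    if (!length(i)) break
    starts <- c(starts, bounds[i] + 1L)
    ends <- c(ends, bounds[i + mc + 1L])
    missed <- c(missed, rep(mc, length(i)))
  }
  keep <- which(ends - starts + 1L >= min_len)
  if (length(keep) == 0L) {
    return(tibble::tibble(peptide = character(), start = integer(),
                          end = integer(), missed = integer()))
  }
  out <- tibble::tibble(
    peptide = substring(seq, starts[keep], ends[keep]),
    start = starts[keep], end = ends[keep], missed = missed[keep]
  )
  out[order(out$start, out$end), , drop = FALSE]
}

as_reference <- function(reference) {
  if (is.data.frame(reference)) {
    stopifnot(nrow(reference) == 1)
    reference <- as.list(reference)
  }
  if (is.null(reference$numbering_offset)) reference$numbering_offset <- 1L
  if (is.null(reference$accession)) reference$accession <- "reference"
  reference
}

# Fit alignment of the whole peptide into a local window of the reference.
# Match +1, mismatch -1, gap -2; reference prefix/suffix free.
fit_align <- function(pep, ref) {
  m <- length(pep)
  n <- length(ref)
  GAP <- -2
  D <- matrix(-Inf, n + 1L, m + 1L)
  D[, 1L] <- 0            # free reference prefix
  D[1L, ] <- GAP * (0:m)  # peptide overhanging before the reference
  for (j in seq_len(m)) {
    s <- ifelse(ref == pep[j], 1, -1)
    best_prev <- pmax(D[1:n, j] + s,           # diagonal
                      D[2:(n + 1L), j] + GAP)  # insertion (peptide residue unaligned)
    # vertical (reference deletion) chains resolve via a cumulative-max
    # transform: D[i] = max(best_prev[i], D[i-1] + GAP) for all i at once
    e <- cummax(c(D[1L, j + 1L], best_prev - GAP * (1:n)))
    D[2:(n + 1L), j + 1L] <- e[-1L] + GAP * (1:n)
  }
  D
}

traceback_one <- function(D, pep, ref, i_end) {
  GAP <- -2
  i <- i_end
  j <- length(pep)
  ops <- list()  # reversed order
  while (j > 0L) {
    cur <- D[i + 1L, j + 1L]
    s <- if (i > 0L && ref[i] == pep[j]) 1 else -1
    if (i > 0L && isTRUE(all.equal(cur, D[i, j] + s))) {
      ops[[length(ops) + 1L]] <- list(op = if (s > 0) "match" else "substitution",
                                      ref_i = i, pep_j = j)
      i <- i - 1L
      j <- j - 1L
    } else if (i > 0L && isTRUE(all.equal(cur, D[i, j + 1L] + GAP))) {
      ops[[length(ops) + 1L]] <- list(op = "deletion", ref_i = i, pep_j = NA)
      i <- i - 1L
    } else {
      ops[[length(ops) + 1L]] <- list(op = "insertion", ref_i = i, pep_j = j)
      j <- j - 1L
    }
  }
  ops <- rev(ops)
  list(ops = ops, ref_start = i + 1L, ref_end = i_end)
}

#' Map an observed peptide onto a reference chain
#'
#' Substitution/indel-tolerant placement of a de novo or database peptide
#' on a reference alpha chain: the whole peptide is aligned against the
#' best-scoring local window of the reference (match +1, mismatch -1, gap
#' -2), and the placement is reported with its edits in mature-chain
#' coordinates. Placements needing more than `max_edits` edits
#' (substitutions + indels) are rejected. Ties are broken toward fewest
#' indels, then the leftmost placement; remaining ties set the `ambiguous`
#' flag. A substituted site where the observed residue could equally be a
#' deamidated form of the reference residue (D for N, E for Q) carries a
#' note, since deamidation cannot be excluded at such positions.
#'
#' @param peptide Observed peptide (length >= 6).
#' @param reference One-row tibble from [read_fasta()] (or a list with
#'   `accession`, `residues`, `numbering_offset`).
#' @param max_edits Maximum substitutions + indels (default 2).
#' @return One-row tibble (`peptide`, `accession`, `ref_start`, `ref_end`,
#'   `n_edits`, `score`, `ambiguous`, `edits` list column with `type`,
#'   `ref_position`, `ref_residue`, `obs_residue`, `note`), or `NULL` when
#'   no placement within `max_edits` exists.
#' @export
map_peptide <- function(peptide, reference, max_edits = 2) {
  reference <- as_reference(reference)
  if (nchar(peptide) < 6) {
    warning("peptide shorter than 6 residues skipped: ", peptide, call. = FALSE)
    return(NULL)
  }
  pep <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  ref <- strsplit(reference$residues, "", fixed = TRUE)[[1]]
  D <- fit_align(pep, ref)
  final <- D[, length(pep) + 1L]
  best <- max(final)
  ends <- which(final == best) - 1L  # reference end indices (0..n)
  cands <- lapply(ends, function(e) traceback_one(D, pep, ref, e))
  n_indels <- vapply(cands, function(c) {
    sum(vapply(c$ops, function(o) o$op %in% c("deletion", "insertion"), logical(1)))
  }, numeric(1))
  starts <- vapply(cands, function(c) c$ref_start, integer(1))
  ord <- order(n_indels, starts)
  pick <- cands[[ord[1]]]
  ambiguous <- length(ord) > 1 && n_indels[ord[2]] == n_indels[ord[1]]
  edits <- edits_from_ops(pick$ops, pep, ref, reference$numbering_offset)
  n_edits <- nrow(edits)
  if (n_edits > max_edits) return(NULL)
  tibble::tibble(
    peptide = peptide,
    accession = reference$accession,
    ref_start = pick$ref_start + reference$numbering_offset - 1L,
    ref_end = pick$ref_end + reference$numbering_offset - 1L,
    n_edits = n_edits,
    score = best,
    ambiguous = ambiguous,
    edits = list(edits)
  )
}

edits_from_ops <- function(ops, pep, ref, offset) {
  rows <- list()
  for (o in ops) {
    if (o$op == "match") next
    if (o$op == "substitution") {
      rr <- ref[o$ref_i]
      ob <- pep[o$pep_j]
      note <- if ((rr == "N" && ob == "D") || (rr == "Q" && ob == "E")) {
        "could be deamidated reference residue"
      } else NA_character_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        type = "substitution", ref_position = o$ref_i + offset - 1L,
        ref_residue = rr, obs_residue = ob, note = note)
    } else if (o$op == "deletion") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        type = "deletion", ref_position = o$ref_i + offset - 1L,
        ref_residue = ref[o$ref_i], obs_residue = NA_character_,
        note = NA_character_)
    } else {  # insertion: observed residue without a reference position
      rows[[length(rows) + 1L]] <- tibble::tibble(
        type = "insertion", ref_position = o$ref_i + offset - 1L,
        ref_residue = NA_character_, obs_residue = pep[o$pep_j],
        note = "inserted after this reference position")
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(type = character(), ref_position = integer(),
                          ref_residue = character(), obs_residue = character(),
                          note = character()))
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$ref_position), , drop = FALSE]
}

#' Map many peptides onto one reference
#'
#' @param peptides Character vector of peptides.
#' @param reference,max_edits See [map_peptide()].
#' @return Tibble of alignments (peptides without a qualifying placement,
#'   or shorter than 6 residues, are omitted).
#' @export
map_peptides <- function(peptides, reference, max_edits = 2) {
  hits <- lapply(peptides, function(p) map_peptide(p, reference, max_edits))
  dplyr::bind_rows(hits[!vapply(hits, is.null, logical(1))])
}

#' Reference coverage of an alignment set
#'
#' A reference position counts as covered when some alignment places an
#' observed residue on it: matches always, substituted positions when
#' `count_substitutions` (the default), deleted reference positions never.
#'
#' @param alignments Tibble from [map_peptides()], all against the same
#'   reference.
#' @param reference The reference used for mapping.
#' @param count_substitutions Count substituted positions as characterized
#'   (default TRUE).
#' @return List with `accession`, `covered_positions` (sorted integer
#'   vector, mature coordinates), `pct_covered`, `n_fragments`,
#'   `chain_length`.
#' @export
coverage <- function(alignments, reference, count_substitutions = TRUE) {
  reference <- as_reference(reference)
  len <- nchar(reference$residues)
  covered <- integer(0)
  for (i in seq_len(nrow(alignments))) {
    pos <- alignments$ref_start[i]:alignments$ref_end[i]
    ed <- alignments$edits[[i]]
    drop <- ed$ref_position[ed$type == "deletion"]
    if (!count_substitutions) {
      drop <- c(drop, ed$ref_position[ed$type == "substitution"])
    }
    covered <- c(covered, setdiff(pos, drop))
  }
  covered <- sort(unique(covered))
  list(
    accession = reference$accession,
    covered_positions = covered,
    pct_covered = 100 * length(covered) / len,
    n_fragments = nrow(alignments),
    chain_length = len
  )
}

#' Validate the Gly-Xaa-Yaa collagen repeat
#'
#' The collagenous domain requires glycine at every third position; a
#' non-glycine at a triplet start destabilizes the triple helix and flags
#' either a genuine interruption or a reference-sequence error. With an
#' explicit `frame` (0-2) the check starts at `frame + 1`; otherwise the
#' frame minimizing violations is selected and reported. Only complete
#' triplets are checked.
#'
#' @param region Amino-acid string (length >= 3).
#' @param frame Optional frame 0-2.
#' @param offset 1-based mature-chain coordinate of the region's first
#'   residue (default 1), used for reported positions.
#' @return List with `frame`, `n_triplets`, and `violations` (tibble:
#'   `triplet_index`, `ref_position`, `residue`).
#' @export
validate_triplets <- function(region, frame = NULL, offset = 1) {
  res <- strsplit(region, "", fixed = TRUE)[[1]]
  n <- length(res)
  stopifnot(n >= 3)
  viol_for <- function(f) {
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    bad <- starts[res[starts] != "G"]
    tibble::tibble(
      triplet_index = match(bad, starts),
      ref_position = bad + offset - 1L,
      residue = res[bad]
    )
  }
  frames <- if (is.null(frame)) 0:2 else frame
  viols <- lapply(frames, viol_for)
  pick <- which.min(vapply(viols, nrow, integer(1)))
  list(
    frame = frames[pick],
    n_triplets = length(seq.int(frames[pick] + 1L, n - 2L, by = 3L)),
    violations = viols[[pick]]
  )
}

#' Consensus observed residue calls from an alignment set
#'
#' For every covered reference position, the residue the alignments
#' observed there (the reference residue at matches, the substituting
#' residue at substitutions). Conflicting calls are resolved by majority,
#' ties toward the reference residue.
#'
#' @param alignments Tibble from [map_peptides()].
#' @return Tibble with columns `position`, `residue`.
#' @export
alignment_calls <- function(alignments) {
  calls <- list()
  for (i in seq_len(nrow(alignments))) {
    pos <- alignments$ref_start[i]:alignments$ref_end[i]
    ed <- alignments$edits[[i]]
    pep <- strsplit(alignments$peptide[i], "", fixed = TRUE)[[1]]
    deleted <- ed$ref_position[ed$type == "deletion"]
    ins_pos <- ed$ref_position[ed$type == "insertion"]
    # leading insertions carry ref_position ref_start - 1; at reference
    # position p the peptide residues consumed so far are the non-deleted
    # reference positions before p plus the insertions before p
    kept <- setdiff(pos, deleted)
    pep_index <- vapply(kept, function(p) {
      sum(kept < p) + sum(ins_pos < p) + 1L
    }, integer(1))
    calls[[i]] <- tibble::tibble(position = kept, residue = pep[pep_index])
  }
  all <- dplyr::bind_rows(calls)
  if (nrow(all) == 0) return(tibble::tibble(position = integer(), residue = character()))
  counts <- dplyr::count(all, .data$position, .data$residue)
  counts <- counts[order(counts$position, -counts$n, counts$residue), ]
  counts <- counts[!duplicated(counts$position), c("position", "residue")]
  tibble::as_tibble(counts)
}

#' Diagnostic sites against a multi-species reference panel
#'
#' Given observed residue calls in mature-chain coordinates and two or
#' more panel references sharing that numbering, reports positions where
#' the observed residue differs from every panel member (candidate
#' sample-diagnostic mutations) and positions where the panel members
#' disagree among themselves (species-separating sites).
#'
#' @param panel Tibble from [read_fasta()] with >= 2 rows, all numbered in
#'   the same mature-chain coordinates.
#' @param observed_calls Tibble with columns `position`, `residue` (e.g.
#'   from [alignment_calls()]), or `NULL` for panel-separating sites only.
#' @return Tibble: `position`, `observed`, one column per panel accession,
#'   `observed_unique` (logical), `panel_separating` (logical); rows where
#'   neither holds are dropped.
#' @export
diagnostic_sites <- function(panel, observed_calls = NULL) {
  stopifnot(nrow(panel) >= 2)
  residue_at <- function(row, pos) {
    idx <- pos - panel$numbering_offset[row] + 1L
    out <- rep(NA_character_, length(pos))
    ok <- idx >= 1L & idx <= nchar(panel$residues[row])
    out[ok] <- substring(panel$residues[row], idx[ok], idx[ok])
    out
  }
  max_pos <- max(panel$numbering_offset + nchar(panel$residues) - 1L)
  min_pos <- min(panel$numbering_offset)
  positions <- min_pos:max_pos
  mat <- vapply(seq_len(nrow(panel)), function(r) residue_at(r, positions),
                character(length(positions)))
  colnames(mat) <- panel$accession
  separating <- apply(mat, 1, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) > 1
  })
  observed <- rep(NA_character_, length(positions))
  if (!is.null(observed_calls) && nrow(observed_calls)) {
    idx <- match(observed_calls$position, positions)
    observed[idx[!is.na(idx)]] <- observed_calls$residue[!is.na(idx)]
  }
  unique_obs <- !is.na(observed) &
    apply(mat != observed, 1, function(x) all(x, na.rm = TRUE)) &
    apply(!is.na(mat), 1, any)
  keep <- separating | unique_obs
  out <- tibble::tibble(position = positions[keep], observed = observed[keep])
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat[keep, , drop = FALSE]))
  out$observed_unique <- unique_obs[keep]
  out$panel_separating <- separating[keep]
  out
}
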