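#' Evidence-table dialect
#'
#' Column mapping for the tab-separated peptide evidence dialect the package
#' reads: a documented subset of MaxQuant's `evidence.txt`. The mapping can
#' be edited to absorb column-name drift between search-engine versions.
#'
#' Modification positions are carried in the `Modified sequence` column as
#' short parenthesized codes after the modified residue, e.g.
#' `_GN(de)DGATK_` for a deamidated Asn at position 2; `(ac)` before the
#' first residue marks an N-terminal modification (position 0). Long engine
#' spellings such as `N(Deamidation (NQ))` are also accepted: parentheses
#' are matched, not split. See [mod_name_aliases()] for the recognized
#' spellings.
#'
#' @param ... Named overrides of individual column names.
#' @return Named list mapping internal field names to file column names.
#' @export
evidence_dialect <- function(...) {
  d <- list(
    sequence = "Sequence",
    modified_sequence = "Modified sequence",
    modifications = "Modifications",
    charge = "Charge",
    mz = "m/z",
    intensity = "Intensity",
    score = "Score",
    proteins = "Proteins",
    raw_file = "Raw file"
  )
  over <- list(...)
  d[names(over)] <- over
  d
}

# Parse a modified-sequence string like "_GN(de)DGAM(ox)K_" into
# (clean sequence, mods tibble). Parentheses are balanced by hand so nested
# engine spellings like "N(Deamidation (NQ))" survive.
parse_modified_sequence <- function(mod_seq) {
  s <- gsub("^_|_$", "", mod_seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  seq_chars <- character(0)
  pos <- integer(0)
  name <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) stop("unbalanced parentheses in modified sequence '",
                            mod_seq, "'", call. = FALSE)
      label <- paste(chars[(i + 1L):(j - 2L)], collapse = "")
      pos <- c(pos, length(seq_chars))  # 0 when before the first residue
      name <- c(name, label)
      i <- j
    } else {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  list(
    sequence = paste(seq_chars, collapse = ""),
    mods = tibble::tibble(position = pos, name = normalize_mod_names(name))
  )
}

# Inverse of parse_modified_sequence, using short codes where known.
build_modified_sequence <- function(sequence, mods) {
  mods <- mods_as_tibble(mods)
  if (nrow(mods) == 0) return(paste0("_", sequence, "_"))
  al <- mod_name_aliases()
  short_for <- function(nm) {
    # prefer the short alias (first alias that maps to nm and has no space)
    cand <- names(al)[al == nm & !grepl(" ", names(al))]
    if (length(cand)) cand[1] else nm
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- character(length(chars) + 1L)  # slot 1 = N-terminus
  for (i in seq_len(nrow(mods))) {
    slot <- mods$position[i] + 1L
    out[slot] <- paste0(out[slot], "(", short_for(mods$name[i]), ")")
  }
  body <- paste0(out[1], paste0(chars, out[-1], collapse = ""))
  paste0("_", body, "_")
}

new_evidence <- function(sequence, mods, charge, mz, intensity, score,
                         proteins, sample_id, group = "unassigned") {
  tibble::tibble(
    sequence = sequence, mods = mods, charge = as.integer(charge),
    mz = as.numeric(mz), intensity = as.numeric(intensity),
    score = as.numeric(score), proteins = proteins,
    sample_id = sample_id, group = group
  )
}

#' Read a peptide evidence table
#'
#' Reads a TSV evidence table in the dialect of [evidence_dialect()] and
#' returns one record per row. Modification annotations are parsed from the
#' modified-sequence string; unknown modification names are preserved
#' verbatim. Rows violating the record invariants (empty sequence, charge
#' below 1, modification position beyond the peptide) raise an error naming
#' the offending row.
#'
#' @param path Path to the TSV file.
#' @param dialect Column mapping, see [evidence_dialect()].
#' @return Tibble of evidence records with columns `sequence`, `mods`
#'   (list of tibbles `position`/`name`), `charge`, `mz`, `intensity`,
#'   `score`, `proteins` (list of accession vectors), `sample_id`, `group`.
#' @export
read_evidence <- function(path, dialect = evidence_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c(dialect$sequence, dialect$score)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("evidence table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  get_col <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, n)
  }
  sequence <- toupper(get_col("sequence"))
  mod_seq <- get_col("modified_sequence")
  charge <- suppressWarnings(as.integer(get_col("charge", "1")))
  mz <- suppressWarnings(as.numeric(get_col("mz")))
  intensity <- suppressWarnings(as.numeric(get_col("intensity")))
  score <- suppressWarnings(as.numeric(get_col("score")))
  prot_col <- get_col("proteins")
  prot_col[is.na(prot_col)] <- ""
  proteins <- strsplit(prot_col, ";", fixed = TRUE)
  sample_id <- get_col("raw_file", "sample1")

  mods <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(sequence[i]) || !nzchar(sequence[i])) {
      stop("row ", i, ": empty peptide sequence", call. = FALSE)
    }
    if (is.na(charge[i]) || charge[i] < 1L) {
      stop("row ", i, ": charge must be a positive integer", call. = FALSE)
    }
    if (!is.na(mod_seq[i]) && nzchar(mod_seq[i])) {
      parsed <- parse_modified_sequence(mod_seq[i])
      if (parsed$sequence != sequence[i]) {
        stop("row ", i, ": modified sequence does not match Sequence column",
             call. = FALSE)
      }
      if (nrow(parsed$mods) && any(parsed$mods$position > nchar(sequence[i]))) {
        stop("row ", i, ": modification position beyond peptide length",
             call. = FALSE)
      }
      mods[[i]] <- parsed$mods
    } else {
      mods[[i]] <- tibble::tibble(position = integer(), name = character())
    }
  }
  new_evidence(sequence, mods, charge, mz, intensity, score,
               proteins, sample_id)
}

#' Write evidence records back to the TSV dialect
#'
#' Inverse of [read_evidence()]: a read-write-read round trip preserves
#' every field of every record.
#'
#' @param records Evidence tibble as returned by [read_evidence()].
#' @param path Output path.
#' @param dialect Column mapping.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(records, path, dialect = evidence_dialect()) {
  out <- tibble::tibble(
    a = records$sequence,
    b = vapply(seq_len(nrow(records)),
               function(i) build_modified_sequence(records$sequence[i],
                                                   records$mods[[i]]),
               character(1)),
    c = vapply(records$mods, function(m) {
      if (nrow(m) == 0) "Unmodified" else paste(sort(unique(m$name)), collapse = ";")
    }, character(1)),
    d = records$charge,
    e = records$mz,
    f = records$intensity,
    g = records$score,
    h = vapply(records$proteins, paste, character(1), collapse = ";"),
    i = records$sample_id
  )
  names(out) <- c(dialect$sequence, dialect$modified_sequence,
                  dialect$modifications, dialect$charge, dialect$mz,
                  dialect$intensity, dialect$score, dialect$proteins,
                  dialect$raw_file)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Count internal missed cleavage sites of a tryptic peptide
#'
#' Internal K/R positions (the C-terminal residue excluded); with the
#' proline rule on, K/R immediately followed by P does not count as a
#' cleavage site.
#'
#' @param sequence Peptide sequence(s).
#' @param proline_rule Suppress cleavage before proline (default TRUE).
#' @return Integer vector of missed-cleavage counts.
#' @export
count_missed_cleavages <- function(sequence, proline_rule = TRUE) {
  vapply(sequence, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(res)
    if (n < 2) return(0L)
    internal <- seq_len(n - 1L)
    site <- res[internal] %in% c("K", "R")
    if (proline_rule) site <- site & res[internal + 1L] != "P"
    sum(site)
  }, integer(1), USE.NAMES = FALSE)
}

#' Filter evidence records by score, intensity and missed cleavages
#'
#' Keeps rows with search score at or above `min_score` (default 40, the
#' usual threshold for modified and unmodified peptides), with an MS1
#' intensity present and positive when `require_intensity` is set, and with
#' at most `max_missed_cleavages` uncut internal K/R sites. The operation
#' preserves row order and is idempotent; counts of dropped rows are
#' reported via `message()`.
#'
#' @param records Evidence tibble.
#' @param min_score Minimum search-engine score (default 40).
#' @param require_intensity Drop rows with missing or non-positive
#'   intensity (default TRUE).
#' @param max_missed_cleavages Maximum internal K/R count (default 3).
#' @param proline_rule Passed to [count_missed_cleavages()].
#' @param quiet Suppress the dropped-row message.
#' @return Filtered evidence tibble.
#' @export
filter_records <- function(records, min_score = 40, require_intensity = TRUE,
                           max_missed_cleavages = 3, proline_rule = TRUE,
                           quiet = FALSE) {
  keep <- !is.na(records$score) & records$score >= min_score
  if (require_intensity) {
    keep <- keep & !is.na(records$intensity) & records$intensity > 0
  }
  mc <- count_missed_cleavages(records$sequence, proline_rule = proline_rule)
  keep <- keep & mc <= max_missed_cleavages
  if (!quiet && any(!keep)) {
    message(sum(!keep), " of ", nrow(records), " evidence rows dropped by filters")
  }
  records[keep, , drop = FALSE]
}

#' Label records as original or contaminant by accession
#'
#' A record is labeled `contaminant` when any of its protein accessions is
#' in the contaminant list, `original` otherwise.
#'
#' @param records Evidence tibble.
#' @param contaminants Character vector of contaminant accessions.
#' @return Records with the `group` column filled in.
#' @export
assign_groups <- function(records, contaminants) {
  is_cont <- vapply(records$proteins,
                    function(p) any(p %in% contaminants), logical(1))
  records$group <- ifelse(is_cont, "contaminant", "original")
  records
}

#' Read protein reference sequences from FASTA
#'
#' Sequences are uppercased; `*` and gap characters are rejected. The
#' header may carry an `offset=<n>` token giving the 1-based mature-chain
#' coordinate of the first residue (default 1), so that precursor-form
#' entries can be numbered in mature-chain coordinates downstream.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `accession`, `description`, `residues`,
#'   `numbering_offset`.
#' @export
read_fasta <- function(path) {
  aset <- Biostrings::readAAStringSet(path)
  headers <- names(aset)
  accession <- sub("\\s.*$", "", headers)
  if (anyDuplicated(accession)) {
    stop("duplicate accession in FASTA: ",
         accession[duplicated(accession)][1], call. = FALSE)
  }
  residues <- toupper(as.character(aset))
  bad <- grepl("[*-]", residues)
  if (any(bad)) {
    stop("sequence '", accession[which(bad)[1]],
         "' contains '*' or gap characters", call. = FALSE)
  }
  offset <- rep(1L, length(aset))
  m <- regmatches(headers, regexpr("offset=\\d+", headers))
  has <- grepl("offset=\\d+", headers)
  offset[has] <- as.integer(sub("offset=", "", m))
  tibble::tibble(
    accession = unname(accession),
    description = sub("^\\S+\\s*", "", headers),
    residues = unname(residues),
    numbering_offset = offset
  )
}

#' Read a contaminant accession list
#'
#' One accession per line; blank lines and `#` comments ignored; duplicates
#' removed.
#'
#' @param path Plain-text file path.
#' @return Character vector of accessions.
#' @export
read_contaminant_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}
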