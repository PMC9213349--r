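#' Monoisotopic amino-acid residue masses
#'
#' Residue (not free amino acid) monoisotopic masses in Dalton for the
#' 20 standard amino acids. A peptide's neutral mass is the sum of its
#' residue masses plus one water.
#'
#' @return Named numeric vector of residue masses (Da), one per letter.
#' @export
amino_acid_masses <- function() {
  c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
    D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
    H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
  )
}

#' @rdname mass_constants
#' @export
mass_water <- function() 18.010565

#' Physical mass constants
#'
#' `mass_water()` is the monoisotopic mass of H2O added once per peptide;
#' `mass_proton()` the proton mass used in m/z arithmetic.
#'
#' @return A single Dalton value.
#' @name mass_constants
#' @export
mass_proton <- function() 1.007276

#' Modification mass-delta table
#'
#' The canonical table of chemical modifications handled by the package:
#' each row names a modification, the residue letters it applies to
#' (comma-separated; `Nterm` marks modifications restricted to the peptide
#' N-terminus) and its monoisotopic mass delta. The table ships as a
#' plain-text TSV resource under `extdata/` and can be replaced by any file
#' with the same columns, e.g. to add engine-specific modifications.
#'
#' Tryptophan-to-oxolactone and tyrosine-to-dopaquinone are represented with
#' a delta of +13.97926 Da (one oxygen gained, two hydrogens lost); this is
#' a documented convention, as no authoritative numeric value is attached to
#' these products in the search-engine output we mirror.
#'
#' @param path Optional path to an alternative TSV (columns `name`,
#'   `targets`, `delta_mass`, `nterm_only`).
#' @return Tibble with columns `name`, `targets` (list of residue letters),
#'   `delta_mass` (Da), `nterm_only` (logical).
#' @export
modification_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "modifications.tsv", package = "paleopept")
  }
  cached <- .paleopept_cache[[path]]
  if (!is.null(cached)) return(cached)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("name", "targets", "delta_mass", "nterm_only") %in% names(tab)))
  tab$targets <- strsplit(tab$targets, ",", fixed = TRUE)
  tab <- tibble::as_tibble(tab)
  .paleopept_cache[[path]] <- tab
  tab
}

.paleopept_cache <- new.env(parent = emptyenv())

#' Spelling aliases for modification names
#'
#' Maps search-engine spellings and the short in-sequence codes used in
#' modified-sequence strings (e.g. `"(de)"`, `"Deamidation (NQ)"`) to the
#' canonical names of [modification_table()]. Unmapped spellings are
#' preserved verbatim by the readers and ignored, with a warning, by the
#' level estimators.
#'
#' @return Named character vector: alias -> canonical name.
#' @export
mod_name_aliases <- function() {
  c(
    "de" = "deamidation", "Deamidation (NQ)" = "deamidation",
    "Deamidation (N)" = "deamidation", "Deamidation (Q)" = "deamidation",
    "ox" = "oxidation", "Oxidation (M)" = "oxidation",
    "Oxidation (P)" = "oxidation", "Oxidation (MP)" = "oxidation",
    "Oxidation (W)" = "oxidation", "Oxidation (Y)" = "oxidation",
    "2ox" = "dioxidation", "Dioxidation (WYM)" = "dioxidation",
    "3ox" = "trioxidation", "Trioxidation (C)" = "trioxidation",
    "cam" = "carbamidomethyl", "Carbamidomethyl (C)" = "carbamidomethyl",
    "ac" = "acetyl", "Acetyl (K)" = "acetyl",
    "gl" = "pyro_glu_q", "Gln->pyro-Glu" = "pyro_glu_q",
    "gu" = "pyro_glu_e", "Glu->pyro-Glu" = "pyro_glu_e",
    "kyn" = "kynurenine", "Trp->Kynurenine" = "kynurenine",
    "iod" = "iodination", "Iodination (Y)" = "iodination",
    "2iod" = "diiodination", "Diiodination (Y)" = "diiodination",
    "oxo" = "oxolactone", "Trp->Oxolactone" = "oxolactone",
    "dq" = "dopaquinone", "Tyr->Dopaquinone" = "dopaquinone"
  )
}

#' Canonicalize modification names
#'
#' @param names Character vector of modification spellings.
#' @return Character vector with known aliases replaced by canonical names;
#'   unknown spellings pass through unchanged.
#' @export
normalize_mod_names <- function(names) {
  al <- mod_name_aliases()
  hit <- names %in% names(al)
  names[hit] <- al[names[hit]]
  names
}

mods_as_tibble <- function(mods) {
  if (is.null(mods) || (is.data.frame(mods) && nrow(mods) == 0)) {
    return(tibble::tibble(position = integer(), name = character()))
  }
  if (is.data.frame(mods)) {
    stopifnot(all(c("position", "name") %in% names(mods)))
    return(tibble::new_tibble(
      list(position = as.integer(mods$position),
           name = as.character(mods$name)),
      nrow = nrow(mods)
    ))
  }
  # list of (position, name) pairs
  tibble::tibble(
    position = vapply(mods, function(m) as.integer(m[[1]]), integer(1)),
    name = vapply(mods, function(m) as.character(m[[2]]), character(1))
  )
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of a peptide: sum of residue masses, one
#' water, and the mass deltas of any modifications. Each modification must
#' be applicable to the residue at its stated position (position 0 denotes
#' the N-terminus and is checked against the first residue for
#' N-terminus-restricted modifications).
#'
#' @param seq Peptide sequence over the 20-letter amino-acid alphabet.
#' @param mods Modifications as a data frame with columns `position`
#'   (1-based; 0 for N-terminus) and `name`, or a list of
#'   `(position, name)` pairs, or `NULL`.
#' @param mod_table Modification table, see [modification_table()].
#' @return Neutral mass in Da.
#' @export
peptide_mass <- function(seq, mods = NULL, mod_table = modification_table()) {
  stopifnot(is.character(seq), length(seq) == 1, nzchar(seq))
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  aam <- amino_acid_masses()
  bad <- which(!res %in% names(aam))
  if (length(bad)) {
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1], call. = FALSE)
  }
  m <- sum(aam[res]) + mass_water()
  mods <- mods_as_tibble(mods)
  if (nrow(mods) == 0) return(unname(m))
  mods$name <- normalize_mod_names(mods$name)
  for (i in seq_len(nrow(mods))) {
    row <- match(mods$name[i], mod_table$name)
    if (is.na(row)) {
      stop("unknown modification '", mods$name[i], "' at position ",
           mods$position[i], call. = FALSE)
    }
    pos <- mods$position[i]
    if (pos > length(res)) {
      stop("modification position ", pos, " beyond peptide length ",
           length(res), call. = FALSE)
    }
    target_res <- if (pos == 0) res[1] else res[pos]
    if (mod_table$nterm_only[row] && pos > 1) {
      stop("modification '", mods$name[i], "' is N-terminal but placed at position ",
           pos, call. = FALSE)
    }
    targets <- mod_table$targets[[row]]
    if (!("*" %in% targets) && !(target_res %in% targets)) {
      stop("modification '", mods$name[i], "' not applicable to residue '",
           target_res, "' at position ", pos, call. = FALSE)
    }
    m <- m + mod_table$delta_mass[row]
  }
  unname(m)
}

#' Convert m/z and charge to neutral mass
#'
#' `M = z * (m/z) - z * m_proton` for a positively charged precursor.
#'
#' @param mz Observed mass-to-charge ratio (Th).
#' @param charge Positive integer charge state.
#' @return Neutral monoisotopic mass (Da).
#' @export
mz_to_neutral_mass <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  charge * mz - charge * mass_proton()
}

#' Convert neutral mass to m/z at a given charge
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @export
neutral_mass_to_mz <- function(neutral_mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  (neutral_mass + charge * mass_proton()) / charge
}

#' Match a sequence (with modifications) against an observed precursor
#'
#' Compares the theoretical neutral mass of `seq` + `mods` with the neutral
#' mass implied by an observed precursor `(mz, charge)` and reports whether
#' the relative error is within `tol_ppm`.
#'
#' @inheritParams peptide_mass
#' @param mz,charge Observed precursor.
#' @param tol_ppm Tolerance in parts per million (default 15, the usual
#'   high-resolution precursor tolerance).
#' @return List with `match` (logical), `ppm_error` (signed), and
#'   `theoretical`, `observed` neutral masses (Da).
#' @export
match_mass <- function(seq, mods = NULL, mz, charge, tol_ppm = 15,
                       mod_table = modification_table()) {
  theo <- peptide_mass(seq, mods, mod_table)
  obs <- mz_to_neutral_mass(mz, charge)
  ppm <- (obs - theo) / theo * 1e6
  list(match = abs(ppm) <= tol_ppm, ppm_error = ppm,
       theoretical = theo, observed = obs)
}

#' Infer oxidation/deamidation multiplicities consistent with a printed mass
#'
#' Published spectra often report a peptide's molecular mass while encoding
#' hydroxyproline counts only typographically. This helper searches over
#' non-negative combinations of oxidation (+15.99491) and deamidation
#' (+0.98402) counts and returns the smallest combination (fewest total
#' modifications, oxidations first) whose theoretical mass falls within
#' `tol` of `target_mass`. Not every printed mass is reachable this way;
#' in that case a zero-row tibble is returned.
#'
#' @param seq Peptide sequence.
#' @param target_mass Printed neutral mass (Da).
#' @param tol Absolute tolerance (Da), default 0.01.
#' @param max_ox,max_deam Search bounds.
#' @return Tibble with columns `n_oxidation`, `n_deamidation`, `mass`,
#'   `error` for the best match (zero rows if unreachable).
#' @export
infer_mod_counts <- function(seq, target_mass, tol = 0.01,
                             max_ox = 10, max_deam = 5) {
  base <- peptide_mass(seq)
  grid <- expand.grid(n_oxidation = 0:max_ox, n_deamidation = 0:max_deam)
  grid$mass <- base + grid$n_oxidation * 15.99491 + grid$n_deamidation * 0.98402
  grid$error <- grid$mass - target_mass
  hits <- grid[abs(grid$error) <= tol, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble::tibble(n_oxidation = integer(), n_deamidation = integer(),
                          mass = numeric(), error = numeric()))
  }
  hits <- hits[order(hits$n_oxidation + hits$n_deamidation, hits$n_deamidation), ]
  tibble::as_tibble(hits[1, , drop = FALSE])
}
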