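# In-code fixture builders shared across test files.

# minimal evidence tibble built directly (bypasses file IO)
make_records <- function(sequence, mods = NULL, intensity = NULL, score = NULL,
                         charge = NULL, proteins = NULL, sample_id = "s1",
                         group = "unassigned") {
  n <- length(sequence)
  if (is.null(mods)) {
    mods <- replicate(n, tibble::tibble(position = integer(), name = character()),
                      simplify = FALSE)
  }
  if (is.null(intensity)) intensity <- rep(1e6, n)
  if (is.null(score)) score <- rep(100, n)
  if (is.null(charge)) charge <- rep(2L, n)
  if (is.null(proteins)) proteins <- replicate(n, "P1", simplify = FALSE)
  tibble::tibble(
    sequence = sequence, mods = mods, charge = as.integer(charge),
    mz = vapply(seq_len(n), function(i) {
      paleopept::neutral_mass_to_mz(paleopept::peptide_mass(sequence[i], mods[[i]]),
                                    charge[i])
    }, numeric(1)),
    intensity = as.numeric(intensity), score = as.numeric(score),
    proteins = proteins, sample_id = sample_id, group = group
  )
}

mods1 <- function(position, name) {
  tibble::tibble(position = as.integer(position), name = name)
}

# write an evidence TSV in the reader dialect
write_evidence_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  header <- paste("Sequence", "Modified sequence", "Modifications", "Charge",
                  "m/z", "Intensity", "Score", "Proteins", "Raw file",
                  sep = "\t")
  writeLines(c(header, lines), path)
  path
}

ev_line <- function(seq, modseq = paste0("_", seq, "_"), mods = "Unmodified",
                    charge = 2, mz = 500, intensity = 1e6, score = 100,
                    proteins = "P1", raw = "s1") {
  paste(seq, modseq, mods, charge, mz, intensity, score, proteins, raw,
        sep = "\t")
}

# small fixed taxonomy: root -> (Bacteria, Eukaryota -> (Mammalia ->
# (Elephantidae -> loxodonta, mammuthus; Primates -> human), Plants -> arabidopsis))
toy_tree <- function() {
  paleopept::taxonomy_tree(tibble::tibble(
    taxon_id = c("root", "Bacteria", "Ecoli", "Eukaryota", "Mammalia",
                 "Elephantidae", "Loxodonta", "Mammuthus", "Primates", "Human",
                 "Plants", "Arabidopsis"),
    parent_id = c(NA, "root", "Bacteria", "root", "Eukaryota", "Mammalia",
                  "Elephantidae", "Elephantidae", "Mammalia", "Primates",
                  "Eukaryota", "Plants"),
    rank = NA_character_,
    name = c("organism", "Bacteria", "Escherichia coli", "Eukaryota",
             "Mammalia", "Elephantidae", "Loxodonta africana",
             "Mammuthus primigenius", "Primates", "Homo sapiens",
             "Viridiplantae", "Arabidopsis thaliana")
  ))
}

# random recursive tree with n nodes, ids "n1".."nn", root "n1"
random_tree <- function(n) {
  parent <- c(NA_character_, paste0("n", vapply(2:n, function(i) {
    sample.int(i - 1L, 1L)
  }, integer(1))))
  paleopept::taxonomy_tree(tibble::tibble(
    taxon_id = paste0("n", seq_len(n)), parent_id = parent
  ))
}

# brute-force LCA oracle: deepest node on the intersection of root paths
lca_oracle <- function(tree, taxa) {
  paths <- lapply(taxa, function(t) paleopept::ancestor_path(tree, t))
  common <- Reduce(intersect, paths)
  common[which.max(tree$depth[common])]
}

# the four in-paper worked examples: observed peptide, reference trait
# accession, and the expected edit calls
collagen_examples <- function() {
  refs <- paleopept::read_fasta(system.file("extdata",
    "col1a1_reference_traits.fasta", package = "paleopept"))
  peps <- readr::read_tsv(system.file("extdata",
    "mammoth_denovo_peptides.tsv", package = "paleopept"),
    show_col_types = FALSE, progress = FALSE)
  list(refs = refs, peps = peps)
}
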