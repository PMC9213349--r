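test_that("tryptic digestion cleaves after K/R with missed cleavages", {
  d0 <- tryptic_digest("AAAKGGGR", max_missed = 0)
  expect_equal(d0$peptide, c("AAAK", "GGGR"))
  expect_equal(d0$start, c(1L, 5L))
  expect_equal(d0$end, c(4L, 8L))

  d1 <- tryptic_digest("AKRK", max_missed = 1)
  expect_setequal(d1$peptide, c("AK", "R", "K", "AKR", "RK"))
  expect_equal(d1$missed[match(c("AK", "AKR"), d1$peptide)], c(0L, 1L))

  # no cleavage between K and P
  dp <- tryptic_digest("AAKPGR", max_missed = 0)
  expect_equal(dp$peptide, "AAKPGR")
  dp2 <- tryptic_digest("AAKPGR", max_missed = 0, proline_rule = FALSE)
  expect_equal(dp2$peptide, c("AAK", "PGR"))

  expect_equal(nrow(tryptic_digest("AAAKGGGR", max_missed = 0, min_len = 5)), 0)
})

test_that("zero-missed-cleavage products reassemble the input", {
  set.seed(11)
  alphabet <- names(amino_acid_masses())
  for (i in 1:30) {
    s <- paste(sample(alphabet, sample(20:80, 1), replace = TRUE),
               collapse = "")
    d <- tryptic_digest(s, max_missed = 0)
    expect_identical(paste(d$peptide, collapse = ""), s)
    expect_true(all(d$missed == 0))
  }
})

test_that("the four published edit calls are reproduced exactly", {
  ex <- collagen_examples()
  expected <- list(
    G3SSE0_162_192 = tibble::tibble(
      type = c("deletion", "substitution"), ref_position = c(174L, 175L),
      ref_residue = c("V", "S"), obs_residue = c(NA, "G")),
    G3SSE0_723_747 = tibble::tibble(
      type = "substitution", ref_position = 746L,
      ref_residue = "G", obs_residue = "A"),
    G3SSE0_982_1008 = tibble::tibble(
      type = "substitution", ref_position = 989L,
      ref_residue = "A", obs_residue = "T"),
    G3TIC0_303_320 = tibble::tibble(
      type = "substitution", ref_position = 305L,
      ref_residue = "S", obs_residue = "D")
  )
  for (i in seq_len(nrow(ex$peps))) {
    acc <- ex$peps$reference_trait[i]
    ref <- ex$refs[ex$refs$accession == acc, ]
    al <- map_peptide(ex$peps$peptide[i], ref)
    expect_false(is.null(al))
    got <- al$edits[[1]][, c("type", "ref_position", "ref_residue",
                             "obs_residue")]
    expect_equal(as.data.frame(got), as.data.frame(expected[[acc]]),
                 info = acc)
    expect_false(al$ambiguous)
  }
})

test_that("map_peptide with max_edits=0 equals exact substring search", {
  set.seed(23)
  alphabet <- names(amino_acid_masses())
  for (i in 1:40) {
    ref_seq <- paste(sample(alphabet, 100, replace = TRUE), collapse = "")
    ref <- tibble::tibble(accession = "R", description = "",
                          residues = ref_seq, numbering_offset = 1L)
    start <- sample(1:90, 1)
    pep <- substr(ref_seq, start, start + 9)
    al <- map_peptide(pep, ref, max_edits = 0)
    oracle <- regexpr(pep, ref_seq, fixed = TRUE)  # leftmost occurrence
    expect_equal(al$ref_start, as.integer(oracle))
    expect_equal(al$n_edits, 0)
    # a peptide absent from the reference finds no zero-edit placement
    rpep <- paste(sample(alphabet, 10, replace = TRUE), collapse = "")
    hit <- map_peptide(rpep, ref, max_edits = 0)
    expect_identical(is.null(hit),
                     regexpr(rpep, ref_seq, fixed = TRUE) == -1L)
  }
})

test_that("repeated motifs are flagged ambiguous and resolved leftmost", {
  ref <- tibble::tibble(accession = "R", description = "",
                        residues = "AAAGPAGPAGPAKKK", numbering_offset = 1L)
  al <- map_peptide("GPAGPA", ref, max_edits = 0)
  expect_true(al$ambiguous)
  expect_equal(al$ref_start, 4L)  # leftmost of the equal-scoring placements
})

test_that("deamidation-ambiguous substitutions carry a note", {
  ref <- tibble::tibble(accession = "R", description = "",
                        residues = "GAAGNAGPAGKAAA", numbering_offset = 100L)
  al <- map_peptide("GAAGDAGPAGK", ref)
  ed <- al$edits[[1]]
  expect_equal(ed$type, "substitution")
  expect_equal(ed$ref_position, 104L)  # offset-based numbering
  expect_match(ed$note, "deamidated")
})

test_that("coverage unions aligned positions and skips deletions", {
  ref <- tibble::tibble(accession = "R", description = "",
                        residues = strrep("GPA", 100), numbering_offset = 1L)
  al <- map_peptides(substr(ref$residues, 1, 30), ref)
  expect_equal(coverage(al, ref)$pct_covered, 10)
  # fully-overlapping second peptide adds nothing
  al2 <- map_peptides(rep(substr(ref$residues, 1, 30), 2), ref)
  expect_equal(coverage(al2, ref)$pct_covered, 10)
  expect_true(coverage(al2, ref)$n_fragments == 2)

  # deleted reference positions are not covered
  ex <- collagen_examples()
  ref162 <- ex$refs[ex$refs$accession == "G3SSE0_162_192", ]
  al3 <- map_peptides("GNDGATGAAGPPGPTGPAGPPGFPGAVGAK", ref162)
  cov <- coverage(al3, ref162)
  expect_false(174 %in% cov$covered_positions)
  expect_true(175 %in% cov$covered_positions)   # substituted but observed
  expect_equal(length(cov$covered_positions), 30)
  cov_strict <- coverage(al3, ref162, count_substitutions = FALSE)
  expect_false(175 %in% cov_strict$covered_positions)
})

test_that("coverage grows monotonically with the alignment set", {
  ref <- make_collagen_reference(100, seed = 4)
  frags <- tryptic_digest(ref$residues, max_missed = 1, min_len = 6)
  set.seed(5)
  picks <- sample(nrow(frags), 12)
  prev <- 0
  for (k in seq_along(picks)) {
    al <- map_peptides(frags$peptide[picks[seq_len(k)]], ref)
    pct <- coverage(al, ref)$pct_covered
    expect_gte(pct, prev)
    prev <- pct
  }
})

test_that("Gly-Xaa-Yaa validation finds interruptions and picks frames", {
  ok <- validate_triplets("GNDGATGAAGPPGPTGPAGPPGFPGAVGAK", frame = 0)
  expect_equal(nrow(ok$violations), 0)

  bad <- validate_triplets("GNDGATGAAGPPVSPTGPAGPPGFPGAVGAK", frame = 0,
                           offset = 162)
  expect_gt(nrow(bad$violations), 0)
  expect_true((13 + 162 - 1) %in% bad$violations$ref_position)  # the V residue
  expect_true("V" %in% bad$violations$residue)

  synth <- paste(rep("GXX", 3), collapse = "")
  synth <- gsub("X", "A", synth)
  expect_equal(nrow(validate_triplets(synth, frame = 0)$violations), 0)

  # frame selection: shifting the region by one is recognized
  shifted <- paste0("A", strrep("GPA", 5))
  pick <- validate_triplets(shifted)
  expect_equal(pick$frame, 1)
  expect_equal(nrow(pick$violations), 0)
})

test_that("diagnostic sites separate the observation from the panel", {
  panel <- tibble::tibble(
    accession = c("loxodonta", "elephas", "mammut"),
    description = "",
    residues = c("GPAGKAGEDGHPGKPGRPGER",
                 "GPAGKAGEDGHPGKPGRPGER",
                 "GPAGKAGEDGHAGKPGRPGSR"),
    numbering_offset = 740L
  )
  # observed A where every panel member has G (position 746)
  obs <- tibble::tibble(position = c(746L, 751L),
                        residue = c("A", "P"))
  sites <- diagnostic_sites(panel, obs)
  r746 <- sites[sites$position == 746, ]
  expect_equal(nrow(r746), 1)
  expect_true(r746$observed_unique)
  # observation equal to some panel member is not diagnostic, but the
  # panel members' own disagreement is still reported
  r751 <- sites[sites$position == 751, ]
  expect_false(r751$observed_unique)
  expect_true(r751$panel_separating)
  # panel-separating positions are reported even without an observation
  expect_true(759 %in% sites$position[sites$panel_separating])
})

test_that("short peptides are skipped with a warning", {
  ref <- make_collagen_reference(20, seed = 1)
  expect_warning(out <- map_peptide("GPA", ref), "shorter than 6")
  expect_null(out)
})
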