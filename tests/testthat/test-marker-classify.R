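clade <- c("Loxodonta africana", "Mammuthus primigenius", "Elephas maximus")

test_that("classification follows the marker-peptide rules", {
  panel <- list(
    "AAAGLK" = c("Loxodonta africana"),
    "GGGGLK" = c("Loxodonta africana", "Homo sapiens"),
    "TTTGLK" = c("Bos taurus", "Sus scrofa"),
    "MMMGLK" = clade
  )
  # fewer than two peptides -> not identified
  expect_equal(classify_protein("P1", "AAAGLK", panel, character(0),
                                clade)$class_label, "not_identified")
  # one clade-unique marker among two peptides -> endogenous
  call <- classify_protein("P2", c("AAAGLK", "GGGGLK"), panel, character(0), clade)
  expect_equal(call$class_label, "endogenous_specific")
  expect_equal(call$marker_peptides[[1]], "AAAGLK")
  # whole-clade species set still counts as a marker
  expect_equal(classify_protein("P3", c("MMMGLK", "TTTGLK"), panel,
                                character(0), clade)$class_label,
               "endogenous_specific")
  # all peptides shared with human
  expect_equal(classify_protein("P4", c("GGGGLK", "GGGGLK"), panel,
                                character(0), clade)$class_label,
               "shared_including_human")
  # shared but never with human
  expect_equal(classify_protein("P5", c("TTTGLK", "TTTGLK"), panel,
                                character(0), clade)$class_label,
               "shared_non_human")
  # contaminant list wins regardless of peptides
  expect_equal(classify_protein("KRT1", c("AAAGLK", "GGGGLK"), panel,
                                "KRT1", clade)$class_label, "contaminant")
  # unknown peptides are flagged and ignored for the decision
  expect_warning(
    call6 <- classify_protein("P6", c("ZZZZZZ", "TTTGLK", "GGGGLK"),
                              panel, character(0), clade),
    "not in reference panel")
  expect_equal(call6$n_unresolved, 1L)
  expect_equal(call6$class_label, "shared_including_human")
})

test_that("adding a clade-unique peptide never demotes a protein", {
  panel <- list("AAAGLK" = "Loxodonta africana",
                "GGGGLK" = c("Loxodonta africana", "Homo sapiens"),
                "TTTGLK" = c("Bos taurus"))
  rank <- c(not_identified = 0, shared_non_human = 1,
            shared_including_human = 1, endogenous_specific = 2)
  for (base in list(c("GGGGLK", "TTTGLK"), c("TTTGLK", "TTTGLK"),
                    "GGGGLK", c("AAAGLK", "GGGGLK"))) {
    before <- classify_protein("P", base, panel, character(0), clade)$class_label
    after <- classify_protein("P", c(base, "AAAGLK"), panel, character(0),
                              clade)$class_label
    expect_gte(rank[after], rank[before])
  }
})

test_that("conservative rule reclassifies modern-looking shared proteins", {
  shared <- tibble::tibble(accession = "KRT_LIKE", n_peptides = 3L,
                           class_label = "shared_including_human",
                           marker_peptides = list(character(0)),
                           n_unresolved = 0L)
  cont_ci <- c(2, 9)
  orig_ci <- c(35, 63)
  # deamidation like the contaminant population -> contaminant
  expect_equal(conservative_contaminant_flag(shared, 4, cont_ci,
                                             orig_ci)$class_label,
               "contaminant")
  # deamidation like the endogenous population -> unchanged
  expect_equal(conservative_contaminant_flag(shared, 50, cont_ci,
                                             orig_ci)$class_label,
               "shared_including_human")
  # between the CIs (neither profile) -> unchanged
  expect_equal(conservative_contaminant_flag(shared, 20, cont_ci,
                                             orig_ci)$class_label,
               "shared_including_human")
  # no N/Q evidence -> indeterminate, unchanged
  out <- conservative_contaminant_flag(shared, NA_real_, cont_ci, orig_ci)
  expect_true(out$indeterminate)
  expect_equal(out$class_label, "shared_including_human")
  # rule only applies to shared-including-human calls
  endo <- shared
  endo$class_label <- "endogenous_specific"
  expect_equal(conservative_contaminant_flag(endo, 4, cont_ci,
                                             orig_ci)$class_label,
               "endogenous_specific")
})

test_that("apply_conservative_flag uses each protein's own records", {
  # keratin-like case: protein shared with human whose own peptides carry a
  # contaminant-like deamidation level (1 of 20 N sites = 5%, inside the
  # contaminant CI and outside the endogenous one)
  n10 <- paste0("A", strrep("N", 10), "GLK")
  rec <- make_records(
    c(n10, n10, "ANQGLK", "ANQGLK"),
    mods = list(mods1(2, "deamidation"), mods1(integer(0), character(0)),
                mods1(c(2, 3), "deamidation"), mods1(2, "deamidation")),
    proteins = list("KRTX", "KRTX", "COL1", "COL1"),
    group = c("contaminant", "contaminant", "original", "original")
  )
  profile <- tibble::tibble(
    residue = "NQ", mod_name = "deamidation",
    group = c("contaminant", "original"), sample_id = "s1",
    point_pct = c(5, 50), ci_low_pct = c(2, 35), ci_high_pct = c(9, 63),
    n_records = 2L, n_sites = 4L
  )
  calls <- tibble::tibble(accession = c("KRTX", "COL1"), n_peptides = 2L,
                          class_label = c("shared_including_human",
                                          "shared_including_human"),
                          marker_peptides = list(character(0), character(0)),
                          n_unresolved = 0L)
  out <- apply_conservative_flag(calls, rec, profile)
  expect_equal(out$class_label[out$accession == "KRTX"], "contaminant")
  # COL1's own level is 75%: endogenous-like, left unchanged
  expect_equal(out$class_label[out$accession == "COL1"],
               "shared_including_human")
  # endogenous-looking keratin stays shared: 10 of 20 sites = 50%
  rec$mods[[1]] <- mods1(2:11, "deamidation")
  out2 <- apply_conservative_flag(calls, rec, profile)
  expect_equal(out2$class_label[out2$accession == "KRTX"],
               "shared_including_human")
})

test_that("synthetic benchmark recovers generating classes", {
  tax <- make_taxonomy(seed = 5)
  target <- c("Loxodonta africana", "Mammuthus primigenius", "Elephas maximus")
  # build one protein per species from its own generated peptides
  panel <- tax$panel
  prot <- split(panel$peptide, panel$source_species)
  attribution <- tibble::tibble(
    accession = rep(names(prot), lengths(prot)),
    peptide = unlist(prot, use.names = FALSE)
  )
  calls <- classify_proteins(attribution, panel, character(0), target)
  # expected class from the generator's sharing labels, not from the panel
  clade_of <- function(sp) {
    if (sp %in% target) "target" else "other"
  }
  expected <- vapply(names(prot), function(sp) {
    share <- panel$sharing[panel$source_species == sp]
    if (length(share) < 2) return("not_identified")
    if (clade_of(sp) == "target" && any(share == "clade_unique")) {
      return("endogenous_specific")
    }
    if (any(share == "human_shared")) return("shared_including_human")
    "shared_non_human"
  }, character(1))
  got <- calls$class_label[match(names(prot), calls$accession)]
  expect_gte(mean(got == expected), 0.95)
  # every protein receives exactly one label
  expect_true(all(!is.na(calls$class_label)))
  expect_equal(nrow(calls), length(prot))
})
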