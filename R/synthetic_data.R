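#' Configuration for the synthetic evidence generator
#'
#' Defaults emulate the statistical structure of an ancient-tissue shotgun
#' experiment: an endogenous ("ancient") peptide population whose per-site
#' N/Q deamidation probability is drawn once per sample from
#' `[0.35, 0.63]` with elevated oxidation, against a modern contaminant
#' population with 5% deamidation and low oxidation; log-normal MS1
#' intensities; Andromeda-like scores drawn from two shifted normals so the
#' score-40 filter has work to do.
#'
#' @param seed Integer seed (required when the config is used).
#' @param n_ancient,n_contaminant Records per population (default 500 each).
#' @param deamidation_prob_ancient Per-site probability; `NULL` (default)
#'   draws one value per sample uniformly from `deamidation_range_ancient`.
#' @param deamidation_range_ancient Sampling range for the ancient
#'   deamidation probability (default `c(0.35, 0.63)`).
#' @param deamidation_prob_modern Contaminant per-site probability
#'   (default 0.05).
#' @param oxidation_probs_ancient,oxidation_probs_modern Named per-residue
#'   oxidation probabilities.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters
#'   (defaults 16 and 1: typical Orbitrap MS1 magnitudes with the bulk of
#'   identified peptides spanning about two orders of magnitude).
#' @param score_true_mean,score_true_sd,score_noise_mean,score_noise_sd,
#'   noise_fraction Score model: a `noise_fraction` of rows draws the low
#'   ("noise") score distribution, the rest the high one.
#' @param samples Character vector of sample labels (default
#'   `c("trunk", "trunk_tip")`).
#' @param n_triplets Length of the generated collagen-like references, in
#'   Gly-Xaa-Yaa triplets (default 120).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = NULL,
                              n_ancient = 500, n_contaminant = 500,
                              deamidation_prob_ancient = NULL,
                              deamidation_range_ancient = c(0.35, 0.63),
                              deamidation_prob_modern = 0.05,
                              oxidation_probs_ancient =
                                c(M = 0.30, P = 0.25, W = 0.20, Y = 0.12, C = 0.10),
                              oxidation_probs_modern =
                                c(M = 0.05, P = 0.02, W = 0.02, Y = 0.01, C = 0.01),
                              intensity_meanlog = 16, intensity_sdlog = 1,
                              score_true_mean = 90, score_true_sd = 25,
                              score_noise_mean = 25, score_noise_sd = 10,
                              noise_fraction = 0.1,
                              samples = c("trunk", "trunk_tip"),
                              n_triplets = 120) {
  probs <- c(deamidation_prob_modern, oxidation_probs_ancient,
             oxidation_probs_modern, noise_fraction)
  if (!is.null(deamidation_prob_ancient)) probs <- c(probs, deamidation_prob_ancient)
  stopifnot(all(probs >= 0 & probs <= 1), n_ancient >= 0, n_contaminant >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a collagen-like reference sequence
#'
#' `n_triplets` Gly-Xaa-Yaa triplets with Xaa/Yaa drawn from a
#' proline-enriched pool that also contains K/R (so tryptic digestion
#' yields peptides) and the modifiable residues N, Q, M. The result passes
#' [validate_triplets()] with zero violations at frame 0.
#'
#' @param n_triplets Number of triplets (>= 1).
#' @param seed Integer seed.
#' @param p_pro Proline weight in the Xaa/Yaa pool (default 0.3).
#' @param accession Accession for the returned reference.
#' @return One-row tibble in the [read_fasta()] schema.
#' @export
make_collagen_reference <- function(n_triplets, seed, p_pro = 0.3,
                                    accession = "SYN_COL1") {
  stopifnot(n_triplets >= 1)
  pool <- c("P", "A", "S", "E", "D", "K", "R", "V", "L", "N", "Q", "T", "F", "M")
  w <- c(p_pro, rep((1 - p_pro) / (length(pool) - 1), length(pool) - 1))
  xy <- with_seed(seed, sample(pool, 2 * n_triplets, replace = TRUE, prob = w))
  trip <- paste0("G", xy[seq_len(n_triplets) * 2 - 1], xy[seq_len(n_triplets) * 2])
  tibble::tibble(
    accession = accession,
    description = paste("synthetic collagen-like chain,", n_triplets, "triplets"),
    residues = paste(trip, collapse = ""),
    numbering_offset = 1L
  )
}

#' Generate a small multi-kingdom taxonomy with a reference panel
#'
#' Builds a rooted taxonomy (root -> Bacteria + Eukaryota; Eukaryota ->
#' Mammalia (target clade + Primates/human), Viridiplantae, Nematoda, by
#' default), per-species synthetic reference proteins, and a peptide ->
#' species panel with controlled sharing: each tryptic peptide is either
#' clade-unique (all carriers inside one clade), shared across clades
#' without human, or shared including human.
#'
#' @param clades Named list of species vectors; the human label is added
#'   under its own clade automatically.
#' @param sharing Probabilities for the three sharing categories, summing
#'   to 1: `clade_unique`, `shared_non_human`, `human_shared`.
#' @param seed Integer seed.
#' @param n_triplets Reference length per species (see
#'   [make_collagen_reference()]).
#' @param human_label Species label used for human.
#' @return List: `tree` ([taxonomy_tree()]), `panel` (tibble `peptide`,
#'   `species` list column), `references` (tibble, one row per species),
#'   `peptide_taxa` (named list peptide -> leaf taxon ids for LCA use),
#'   `species_taxon` (named vector species -> leaf taxon id).
#' @export
make_taxonomy <- function(clades = list(
                            Proboscidea = c("Loxodonta africana",
                                            "Mammuthus primigenius",
                                            "Elephas maximus"),
                            Viridiplantae = c("Arabidopsis thaliana",
                                              "Amborella trichopoda"),
                            Bacteria = c("Mesoplasma florum",
                                         "Escherichia coli"),
                            Nematoda = c("Caenorhabditis elegans")
                          ),
                          sharing = c(clade_unique = 0.6,
                                      shared_non_human = 0.25,
                                      human_shared = 0.15),
                          seed = 1, n_triplets = 80,
                          human_label = "Homo sapiens") {
  stopifnot(abs(sum(sharing) - 1) < 1e-8)
  nodes <- list(tibble::tibble(taxon_id = "root", parent_id = NA_character_,
                               rank = "no rank", name = "organism"))
  add <- function(id, parent, rank, name) {
    nodes[[length(nodes) + 1L]] <<- tibble::tibble(
      taxon_id = id, parent_id = parent, rank = rank, name = name)
  }
  clade_names <- names(clades)
  euk_clades <- setdiff(clade_names, "Bacteria")
  add("Eukaryota", "root", "superkingdom", "Eukaryota")
  if ("Bacteria" %in% clade_names) add("Bacteria", "root", "superkingdom", "Bacteria")
  species_taxon <- character(0)
  for (cl in clade_names) {
    parent <- if (cl == "Bacteria") "root" else "Eukaryota"
    if (cl != "Bacteria") add(cl, "Eukaryota", "clade", cl)
    anchor <- if (cl == "Bacteria") "Bacteria" else cl
    for (sp in clades[[cl]]) {
      id <- gsub(" ", "_", sp)
      add(id, anchor, "species", sp)
      species_taxon[sp] <- id
    }
  }
  add("Primates", "Eukaryota", "order", "Primates")
  add("Homo_sapiens", "Primates", "species", human_label)
  species_taxon[human_label] <- "Homo_sapiens"
  tree <- taxonomy_tree(dplyr::bind_rows(nodes))

  all_species <- unlist(clades, use.names = FALSE)
  clade_of <- stats::setNames(rep(clade_names, lengths(clades)), all_species)
  refs <- list()
  panel_rows <- list()
  for (k in seq_along(all_species)) {
    sp <- all_species[k]
    ref <- make_collagen_reference(n_triplets, seed = seed + k,
                                   accession = paste0("SYN_", gsub(" ", "_", sp)))
    ref$description <- paste("synthetic reference,", sp)
    refs[[k]] <- ref
    peps <- tryptic_digest(ref$residues, max_missed = 3, min_len = 6)$peptide
    peps <- unique(peps)
    cat_draw <- with_seed(seed + 1000 + k, {
      sample(names(sharing), length(peps), replace = TRUE, prob = sharing)
    })
    other_clade_species <- all_species[clade_of[all_species] != clade_of[sp]]
    extra <- with_seed(seed + 2000 + k, {
      sample(other_clade_species, length(peps), replace = TRUE)
    })
    species_sets <- lapply(seq_along(peps), function(i) {
      switch(cat_draw[i],
        clade_unique = intersect(all_species, names(clade_of)[clade_of == clade_of[sp]]),
        shared_non_human = unique(c(sp, extra[i])),
        human_shared = c(sp, human_label)
      )
    })
    panel_rows[[k]] <- tibble::tibble(peptide = peps, species = species_sets,
                                      source_species = sp,
                                      sharing = cat_draw)
  }
  panel <- dplyr::bind_rows(panel_rows)
  # a peptide generated by several species keeps the union of its sets
  panel$key <- normalize_il(panel$peptide)
  merged <- split(panel$species, panel$key)
  merged <- lapply(merged, function(x) sort(unique(unlist(x))))
  panel <- panel[!duplicated(panel$key), , drop = FALSE]
  panel$species <- merged[panel$key]
  peptide_taxa <- lapply(panel$species, function(sp) unname(species_taxon[sp]))
  names(peptide_taxa) <- panel$key
  list(
    tree = tree,
    panel = panel[, c("peptide", "species", "source_species", "sharing")],
    references = dplyr::bind_rows(refs),
    peptide_taxa = peptide_taxa,
    species_taxon = species_taxon
  )
}

# one Bernoulli draw per modifiable site; caller controls the RNG state
draw_mods_once <- function(res, deam_prob, ox_probs) {
  pos <- integer(0)
  name <- character(0)
  nq <- which(res %in% c("N", "Q"))
  if (length(nq)) {
    hit <- nq[stats::runif(length(nq)) < deam_prob]
    pos <- c(pos, hit)
    name <- c(name, rep("deamidation", length(hit)))
  }
  ox_at <- which(res %in% names(ox_probs))
  if (length(ox_at)) {
    hit <- ox_at[stats::runif(length(ox_at)) < unname(ox_probs[res[ox_at]])]
    pos <- c(pos, hit)
    name <- c(name, rep("oxidation", length(hit)))
  }
  ord <- order(pos)
  tibble::new_tibble(list(position = as.integer(pos[ord]), name = name[ord]),
                     nrow = length(ord))
}

#' Simulate a labeled evidence table
#'
#' Draws tryptic peptides from synthetic references (endogenous records
#' from the target clade's references, contaminant records from a
#' human-keratin-like contaminant reference), modifies each N/Q site with
#' its group's deamidation probability and each oxidizable residue with the
#' group's oxidation probability, attaches log-normal intensities,
#' two-component scores, charges 2-4 and the theoretical m/z, and returns
#' the evidence together with full ground truth. Deterministic for a fixed
#' config + seed.
#'
#' @param config A [simulation_config()] with a non-`NULL` seed.
#' @param taxonomy Optional output of [make_taxonomy()]; generated from the
#'   config seed when absent.
#' @return List with `records` (evidence tibble ready for
#'   [filter_records()] / [write_evidence()]), `truth` (tibble: row `id`,
#'   `group`, `sample_id`, `source_species`, `deamidation_prob`,
#'   `n_nq_sites`, `n_deamidated`), `contaminants` (accession list),
#'   `taxonomy` (the panel/tree used), `deamidation_prob_by_sample`
#'   (named vector, ancient draw per sample).
#' @export
simulate_evidence <- function(config, taxonomy = NULL) {
  stopifnot(inherits(config, "simulation_config"), !is.null(config$seed))
  seed <- config$seed
  if (is.null(taxonomy)) taxonomy <- make_taxonomy(seed = seed)
  cont_ref <- make_collagen_reference(config$n_triplets, seed = seed + 77,
                                      accession = "CON_KRT_SYN")
  cont_ref$description <- "synthetic contaminant (keratin-like), modern"
  contaminants <- cont_ref$accession

  deam_by_sample <- stats::setNames(numeric(length(config$samples)), config$samples)
  digest_pool <- function(refs) {
    dplyr::bind_rows(lapply(seq_len(nrow(refs)), function(r) {
      d <- tryptic_digest(refs$residues[r], max_missed = 3, min_len = 7)
      d$accession <- refs$accession[r]
      d
    }))
  }
  pools <- list(original = digest_pool(taxonomy$references),
                contaminant = digest_pool(cont_ref))
  truth_rows <- list()
  rec_rows <- list()
  id0 <- 0L
  for (si in seq_along(config$samples)) {
    smp <- config$samples[si]
    p_anc <- if (is.null(config$deamidation_prob_ancient)) {
      with_seed(seed + 5000 + si,
                stats::runif(1, config$deamidation_range_ancient[1],
                             config$deamidation_range_ancient[2]))
    } else config$deamidation_prob_ancient
    deam_by_sample[smp] <- p_anc
    specs <- list(
      list(group = "original", n = config$n_ancient, deam = p_anc,
           ox = config$oxidation_probs_ancient),
      list(group = "contaminant", n = config$n_contaminant,
           deam = config$deamidation_prob_modern,
           ox = config$oxidation_probs_modern)
    )
    for (sp in specs) {
      if (sp$n == 0) next
      pool <- pools[[sp$group]]
      # peptides without N/Q cannot inform deamidation; keep a mixed pool
      block <- with_seed(seed + 101 * si + ifelse(sp$group == "original", 0, 13), {
        draw <- sample.int(nrow(pool), sp$n, replace = TRUE)
        sub <- pool[draw, , drop = FALSE]
        res_list <- strsplit(sub$peptide, "", fixed = TRUE)
        mods <- lapply(res_list, draw_mods_once, deam_prob = sp$deam,
                       ox_probs = sp$ox)
        list(sub = sub, mods = mods,
             nq = vapply(res_list, function(r) sum(r %in% c("N", "Q")),
                         integer(1)))
      })
      for (i in seq_len(sp$n)) {
        id0 <- id0 + 1L
        mods <- block$mods[[i]]
        rec_rows[[id0]] <- list(sequence = block$sub$peptide[i], mods = mods,
                                accession = block$sub$accession[i],
                                sample = smp, group = sp$group)
        truth_rows[[id0]] <- list(
          id = id0, group = sp$group, sample_id = smp,
          source_species = block$sub$accession[i], deamidation_prob = sp$deam,
          n_nq_sites = block$nq[i],
          n_deamidated = sum(mods$name == "deamidation")
        )
      }
    }
  }
  n <- id0
  numbers <- with_seed(seed + 9999, {
    list(
      intensity = stats::rlnorm(n, config$intensity_meanlog, config$intensity_sdlog),
      is_noise = stats::runif(n) < config$noise_fraction,
      score_true = stats::rnorm(n, config$score_true_mean, config$score_true_sd),
      score_noise = stats::rnorm(n, config$score_noise_mean, config$score_noise_sd),
      charge = sample(2:4, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
    )
  })
  score <- ifelse(numbers$is_noise, numbers$score_noise, numbers$score_true)
  score <- pmax(score, 0)
  sequence <- vapply(rec_rows, `[[`, character(1), "sequence")
  mods <- lapply(rec_rows, `[[`, "mods")
  mz <- vapply(seq_len(n), function(i) {
    neutral_mass_to_mz(peptide_mass(sequence[i], mods[[i]]), numbers$charge[i])
  }, numeric(1))
  records <- new_evidence(
    sequence = sequence, mods = mods, charge = numbers$charge, mz = mz,
    intensity = numbers$intensity, score = score,
    proteins = lapply(rec_rows, function(r) r$accession),
    sample_id = vapply(rec_rows, `[[`, character(1), "sample"),
    group = vapply(rec_rows, `[[`, character(1), "group")
  )
  truth <- tibble::tibble(
    id = vapply(truth_rows, `[[`, integer(1), "id"),
    group = vapply(truth_rows, `[[`, character(1), "group"),
    sample_id = vapply(truth_rows, `[[`, character(1), "sample_id"),
    source_species = vapply(truth_rows, `[[`, character(1), "source_species"),
    deamidation_prob = vapply(truth_rows, `[[`, numeric(1), "deamidation_prob"),
    n_nq_sites = vapply(truth_rows, `[[`, integer(1), "n_nq_sites"),
    n_deamidated = vapply(truth_rows, function(x) as.integer(x$n_deamidated),
                          integer(1))
  )
  list(
    records = records,
    truth = truth,
    contaminants = contaminants,
    taxonomy = taxonomy,
    deamidation_prob_by_sample = deam_by_sample
  )
}
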