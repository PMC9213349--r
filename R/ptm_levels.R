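#' Default modification panel for level estimation
#'
#' Deamidation of Asn and Gln (reported separately, as is standard for
#' ancient-protein authentication) plus oxidation of the photo/oxidation-
#' sensitive residues Trp, Tyr, Cys, Met and Pro.
#'
#' @return Tibble with columns `residue`, `mod_name`.
#' @export
default_mod_panel <- function() {
  tibble::tibble(
    residue = c("N", "Q", "W", "Y", "C", "M", "P"),
    mod_name = c("deamidation", "deamidation", rep("oxidation", 5))
  )
}

# per-record modified-site count k and site count n for a residue set
site_counts <- function(records, residue, mod_name) {
  pattern <- paste0("[", paste(residue, collapse = ""), "]")
  n_sites <- vapply(records$sequence, function(s) {
    lengths(regmatches(s, gregexpr(pattern, s)))
  }, integer(1), USE.NAMES = FALSE)
  k_sites <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    m <- records$mods[[i]]
    if (nrow(m) == 0) next
    hit <- m$name == mod_name & m$position >= 1
    if (!any(hit)) next
    res_at <- substring(records$sequence[i], m$position[hit], m$position[hit])
    k_sites[i] <- sum(res_at %in% residue)
  }
  unknown <- unique(unlist(lapply(records$mods, function(m) m$name)))
  unknown <- setdiff(unknown, c(modification_table()$name))
  if (length(unknown)) {
    warning("ignoring unrecognized modification name(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  list(k = k_sites, n = n_sites)
}

#' Intensity-weighted modification fraction
#'
#' The level of a chemical modification at a residue type, pooled over
#' records with MS1 intensity weighting:
#' \deqn{100 \cdot \frac{\sum_i I_i k_i}{\sum_i I_i n_i}}
#' where, for record \eqn{i}, \eqn{k_i} is the number of residue positions
#' carrying the modification, \eqn{n_i} the number of such residues in the
#' peptide, and \eqn{I_i} the intensity. Records without the residue
#' (\eqn{n_i = 0}) or without intensity are excluded. When no record
#' carries the residue the estimate is undefined and `NA` is returned
#' (distinct from 0%).
#'
#' @param records Filtered evidence tibble (see [filter_records()]).
#' @param residue Residue letter, or several letters to pool (e.g.
#'   `c("N", "Q")` for a combined deamidation level).
#' @param mod_name Canonical modification name.
#' @param weighting `"intensity"` (the default, shown in the formula) or
#'   `"unweighted"`, which sets every \eqn{I_i = 1} and so pools sites with
#'   equal weight per record.
#' @return Percentage in `[0, 100]`, or `NA_real_` if undefined.
#' @export
modification_fraction <- function(records, residue, mod_name,
                                  weighting = c("intensity", "unweighted")) {
  weighting <- match.arg(weighting)
  sc <- site_counts(records, residue, mod_name)
  use <- sc$n > 0 & !is.na(records$intensity) & records$intensity > 0
  if (!any(use)) return(NA_real_)
  I <- if (weighting == "intensity") records$intensity[use] else
    rep(1, sum(use))
  100 * sum(I * sc$k[use]) / sum(I * sc$n[use])
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Bootstrap confidence interval for a modification level
#'
#' Resamples whole records with replacement `n_boot` times (default 1000),
#' recomputes the intensity-weighted fraction on each replicate, and
#' returns a percentile interval. Deterministic for a fixed seed.
#'
#' @inheritParams modification_fraction
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (required: estimates must be reproducible).
#' @param level Confidence level (default 0.95).
#' @param group,sample_id Optional labels copied into the output row.
#' @return One-row tibble: `residue`, `mod_name`, `group`, `sample_id`,
#'   `point_pct`, `ci_low_pct`, `ci_high_pct`, `n_records`, `n_sites`.
#' @export
bootstrap_ci <- function(records, residue, mod_name, n_boot = 1000, seed,
                         level = 0.95, group = NA_character_,
                         sample_id = NA_character_,
                         weighting = c("intensity", "unweighted")) {
  weighting <- match.arg(weighting)
  stopifnot(!missing(seed))
  sc <- site_counts(records, residue, mod_name)
  use <- sc$n > 0 & !is.na(records$intensity) & records$intensity > 0
  if (weighting == "unweighted") {
    records <- records[, , drop = FALSE]
    records$intensity[use] <- 1
  }
  out <- tibble::tibble(
    residue = paste(residue, collapse = ""), mod_name = mod_name,
    group = group, sample_id = sample_id,
    point_pct = NA_real_, ci_low_pct = NA_real_, ci_high_pct = NA_real_,
    n_records = sum(use), n_sites = sum(sc$n[use])
  )
  if (!any(use)) return(out)
  a <- records$intensity[use] * sc$k[use]  # weighted modified sites
  b <- records$intensity[use] * sc$n[use]  # weighted total sites
  m <- length(a)
  out$point_pct <- 100 * sum(a) / sum(b)
  reps <- with_seed(seed, {
    idx <- sample.int(m, m * n_boot, replace = TRUE)
    dim(idx) <- c(m, n_boot)
    100 * colSums(matrix(a[idx], m)) / colSums(matrix(b[idx], m))
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  out$ci_low_pct <- qs[1]
  out$ci_high_pct <- qs[2]
  out
}

#' Modification-level profile per sample and peptide group
#'
#' Runs [bootstrap_ci()] for every cell of (sample, group, panel row).
#' Samples are never pooled; original and contaminant peptides are
#' estimated separately. Cells without records are omitted. Per-cell seeds
#' are derived deterministically from `seed`.
#'
#' @param records Filtered evidence tibble with `group` labels assigned
#'   (see [assign_groups()]).
#' @param panel Modification panel, see [default_mod_panel()]. Rows with a
#'   multi-letter `residue` entry (e.g. `"NQ"`) pool those residues.
#' @param n_boot,level,seed As in [bootstrap_ci()].
#' @return Tibble of estimates, sorted by sample, group, residue, mod.
#' @export
group_profile <- function(records, panel = default_mod_panel(),
                          n_boot = 1000, seed, level = 0.95) {
  stopifnot(!missing(seed))
  cells <- expand.grid(
    sample_id = sort(unique(records$sample_id)),
    group = sort(unique(records$group)),
    row = seq_len(nrow(panel)),
    stringsAsFactors = FALSE
  )
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- records[records$sample_id == cells$sample_id[i] &
                     records$group == cells$group[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    residues <- strsplit(panel$residue[cells$row[i]], "", fixed = TRUE)[[1]]
    est <- bootstrap_ci(sub, residues, panel$mod_name[cells$row[i]],
                        n_boot = n_boot, seed = seed + i, level = level,
                        group = cells$group[i],
                        sample_id = cells$sample_id[i])
    if (est$n_records > 0) out[[i]] <- est
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(
      residue = character(), mod_name = character(), group = character(),
      sample_id = character(), point_pct = numeric(), ci_low_pct = numeric(),
      ci_high_pct = numeric(), n_records = integer(), n_sites = integer()
    ))
  }
  dplyr::arrange(res, .data$sample_id, .data$group, .data$residue,
                 .data$mod_name)
}

#' Bar plot of modification levels with bootstrap error bars
#'
#' @param profile Output of [group_profile()].
#' @return A ggplot object: one bar per (residue, group) with the bootstrap
#'   interval as error bars, faceted by sample and modification.
#' @export
plot_mod_levels <- function(profile) {
  ggplot2::ggplot(
    profile,
    ggplot2::aes(x = .data$residue, y = .data$point_pct, fill = .data$group)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low_pct, ymax = .data$ci_high_pct),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::facet_grid(mod_name ~ sample_id) +
    ggplot2::labs(x = "residue", y = "modification level (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
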