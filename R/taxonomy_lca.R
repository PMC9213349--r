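#' Construct a rooted taxonomy tree
#'
#' Validates and indexes a node table: exactly one root (whose parent is
#' itself or `NA`), every parent present, no cycles. Ranks are free-form
#' and may be missing; the tree need not be fully ranked.
#'
#' @param nodes Data frame with columns `taxon_id`, `parent_id`, and
#'   optionally `rank`, `name`.
#' @return An object of class `taxonomy_tree`: list with the validated
#'   `nodes` tibble, `root` id, a named `parent` lookup and a named
#'   `depth` vector (root depth 0).
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("taxon_id", "parent_id") %in% names(nodes)))
  nodes$taxon_id <- as.character(nodes$taxon_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (!"rank" %in% names(nodes)) nodes$rank <- NA_character_
  if (!"name" %in% names(nodes)) nodes$name <- nodes$taxon_id
  if (anyDuplicated(nodes$taxon_id)) {
    stop("duplicate taxon_id in node table", call. = FALSE)
  }
  is_root <- is.na(nodes$parent_id) | nodes$parent_id == nodes$taxon_id
  if (sum(is_root) != 1) {
    stop("taxonomy must have exactly one root, found ", sum(is_root),
         call. = FALSE)
  }
  root <- nodes$taxon_id[is_root]
  missing_parent <- setdiff(nodes$parent_id[!is_root], nodes$taxon_id)
  if (length(missing_parent)) {
    stop("parent_id not present in tree: ", missing_parent[1], call. = FALSE)
  }
  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  parent[root] <- NA_character_
  # depths via repeated parent hops; a cycle never reaches the root
  depth <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$taxon_id)
  depth[root] <- 0
  pending <- setdiff(nodes$taxon_id, root)
  while (length(pending)) {
    ready <- pending[!is.na(depth[parent[pending]])]
    if (!length(ready)) {
      stop("taxonomy contains a cycle (nodes unreachable from root): ",
           paste(utils::head(pending, 3), collapse = ", "), call. = FALSE)
    }
    depth[ready] <- depth[parent[ready]] + 1
    pending <- setdiff(pending, ready)
  }
  structure(list(nodes = nodes, root = root, parent = parent, depth = depth),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes, root =", x$root,
      ", max depth =", max(x$depth), "\n")
  invisible(x)
}

#' Read a taxonomy from NCBI-dump-like TSV files
#'
#' A minimal two-file dialect: `nodes_path` is a TSV with header columns
#' `taxon_id`, `parent_id`, `rank`; `names_path` (optional) a TSV with
#' `taxon_id`, `name`.
#'
#' @param nodes_path,names_path File paths.
#' @return A [taxonomy_tree()].
#' @export
read_taxonomy <- function(nodes_path, names_path = NULL) {
  nodes <- readr::read_tsv(nodes_path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(names_path)) {
    nm <- readr::read_tsv(names_path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    nodes$name <- nm$name[match(nodes$taxon_id, nm$taxon_id)]
  }
  taxonomy_tree(nodes)
}

#' Path from a taxon to the root
#'
#' @param tree A [taxonomy_tree()].
#' @param taxon_id Taxon identifier.
#' @return Character vector of taxon ids from `taxon_id` up to the root.
#' @export
ancestor_path <- function(tree, taxon_id) {
  taxon_id <- as.character(taxon_id)
  if (!taxon_id %in% names(tree$parent)) {
    stop("unknown taxon_id: ", taxon_id, call. = FALSE)
  }
  path <- taxon_id
  while (!is.na(tree$parent[path[length(path)]])) {
    path <- c(path, unname(tree$parent[path[length(path)]]))
  }
  path
}

lca_pair <- function(tree, a, b) {
  # equalize depths, then walk both up
  while (tree$depth[a] > tree$depth[b]) a <- unname(tree$parent[a])
  while (tree$depth[b] > tree$depth[a]) b <- unname(tree$parent[b])
  while (a != b) {
    a <- unname(tree$parent[a])
    b <- unname(tree$parent[b])
  }
  a
}

#' Lowest common ancestor of a taxon set
#'
#' The deepest node ancestral to (or equal to) every input taxon. A
#' singleton set returns its element; a set spanning the whole tree
#' returns the root (ubiquitous peptides end up at the root "organism"
#' node). Computed by pairwise depth-equalized walking; commutative and
#' associative over set union.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxa Non-empty vector of taxon ids, all present in the tree.
#' @return The LCA taxon id.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0) stop("taxa must be non-empty", call. = FALSE)
  unknown <- setdiff(taxa, names(tree$parent))
  if (length(unknown)) stop("unknown taxon_id: ", unknown[1], call. = FALSE)
  Reduce(function(a, b) lca_pair(tree, a, b), taxa)
}

#' Normalize peptide sequences for taxon matching
#'
#' Isoleucine and leucine are isobaric and indistinguishable by standard
#' shotgun MS; peptide keys are normalized by replacing I with L before any
#' lookup, the usual metaproteomics convention.
#'
#' @param peptides Character vector.
#' @return Normalized character vector.
#' @export
normalize_il <- function(peptides) {
  gsub("I", "L", toupper(peptides), fixed = TRUE)
}

subtree_members <- function(tree, root_id) {
  root_id <- as.character(root_id)
  kids <- split(tree$nodes$taxon_id, tree$nodes$parent_id)
  acc <- character(0)
  frontier <- root_id
  while (length(frontier)) {
    acc <- c(acc, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
    frontier <- setdiff(frontier, acc)
  }
  acc
}

#' Assign peptides to their lowest common ancestor
#'
#' Each peptide's taxon set is reduced to its LCA. Peptides whose taxa span
#' two or more of the configured disjoint reference groups (e.g. the
#' endogenous-clade / plant / bacteria+nematode split of separate database
#' searches) are excluded as invalid identifications; peptides absent from
#' the map are reported as unassigned.
#'
#' @param tree A [taxonomy_tree()].
#' @param map Peptide-to-taxa mapping: a named list `peptide -> character
#'   vector of taxon ids` (peptide keys are I/L-normalized on construction)
#'   or a data frame with columns `peptide` and `taxa` (list column).
#' @param peptides Character vector of observed peptides.
#' @param exclude_groups Optional named list of subtree-root taxon ids
#'   defining the disjoint reference groups for the exclusion rule.
#' @return Tibble with columns `peptide`, `taxon_id` (NA unless assigned),
#'   `status` (`assigned`, `excluded`, `unassigned`), `reason`.
#' @export
assign_peptides <- function(tree, map, peptides, exclude_groups = NULL) {
  if (is.data.frame(map)) {
    map <- stats::setNames(map$taxa, normalize_il(map$peptide))
  } else {
    names(map) <- normalize_il(names(map))
  }
  group_sets <- lapply(exclude_groups, function(r) subtree_members(tree, r))
  key <- normalize_il(peptides)
  out <- tibble::tibble(peptide = peptides, taxon_id = NA_character_,
                        status = "unassigned", reason = "not in map")
  for (i in seq_along(key)) {
    taxa <- map[[key[i]]]
    if (is.null(taxa) || length(taxa) == 0) next
    if (length(group_sets)) {
      in_group <- vapply(group_sets, function(g) any(taxa %in% g), logical(1))
      if (sum(in_group) >= 2) {
        out$status[i] <- "excluded"
        out$reason[i] <- paste("spans reference groups:",
                               paste(names(group_sets)[in_group], collapse = "+"))
        next
      }
    }
    out$taxon_id[i] <- lca(tree, taxa)
    out$status[i] <- "assigned"
    out$reason[i] <- NA_character_
  }
  out
}

#' Per-clade peptide counts with parent-relative percentages
#'
#' Summarizes LCA assignments as a tree view: for every node, the number of
#' peptides assigned to the node itself (`n_direct`), to its whole subtree
#' (`n_subtree`), and the subtree count as a percentage of the parent's
#' subtree count (`pct_of_parent`; the parent's count is the 100%
#' reference, so sibling percentages need not reach 100 when some peptides
#' stop at the parent). Rows are emitted in deterministic depth-first
#' order, children sorted by taxon id; nodes with empty subtrees are
#' dropped.
#'
#' @param tree A [taxonomy_tree()].
#' @param assignments Output of [assign_peptides()] (only rows with status
#'   `assigned` are counted).
#' @return Tibble: `taxon_id`, `name`, `rank`, `depth`, `n_direct`,
#'   `n_subtree`, `pct_of_parent`.
#' @export
treeview <- function(tree, assignments) {
  counted <- assignments$taxon_id[assignments$status == "assigned"]
  direct <- table(counted)
  n_direct <- stats::setNames(rep(0L, nrow(tree$nodes)), tree$nodes$taxon_id)
  n_direct[names(direct)] <- as.integer(direct)
  # accumulate subtree counts bottom-up (deepest first)
  n_subtree <- n_direct
  ord <- names(sort(tree$depth, decreasing = TRUE))
  for (id in ord) {
    p <- tree$parent[id]
    if (!is.na(p)) n_subtree[p] <- n_subtree[p] + n_subtree[id]
  }
  kids <- split(tree$nodes$taxon_id, tree$nodes$parent_id)
  dfs <- character(0)
  stack <- tree$root
  while (length(stack)) {
    id <- stack[1]
    stack <- stack[-1]
    dfs <- c(dfs, id)
    ch <- sort(setdiff(kids[[id]], id))
    stack <- c(ch, stack)
  }
  pct <- vapply(dfs, function(id) {
    p <- tree$parent[id]
    if (is.na(p)) return(100)
    if (n_subtree[p] == 0) return(NA_real_)
    100 * n_subtree[id] / n_subtree[p]
  }, numeric(1))
  out <- tibble::tibble(
    taxon_id = dfs,
    name = tree$nodes$name[match(dfs, tree$nodes$taxon_id)],
    rank = tree$nodes$rank[match(dfs, tree$nodes$taxon_id)],
    depth = unname(tree$depth[dfs]),
    n_direct = unname(n_direct[dfs]),
    n_subtree = unname(n_subtree[dfs]),
    pct_of_parent = unname(pct)
  )
  out[out$n_subtree > 0, , drop = FALSE]
}

#' Export a taxonomy (optionally with counts) as a Newick string
#'
#' Leaf and internal node labels are the node names; when a treeview is
#' supplied, subtree counts are appended to the labels. The output parses
#' with standard Newick readers.
#'
#' @param tree A [taxonomy_tree()].
#' @param view Optional output of [treeview()]; restricts the export to
#'   counted nodes and annotates labels with counts.
#' @return A single Newick string (with trailing `;`).
#' @export
taxonomy_to_newick <- function(tree, view = NULL) {
  keep <- tree$nodes$taxon_id
  counts <- NULL
  if (!is.null(view)) {
    keep <- view$taxon_id
    counts <- stats::setNames(view$n_subtree, view$taxon_id)
  }
  kids <- split(tree$nodes$taxon_id, tree$nodes$parent_id)
  label <- function(id) {
    nm <- tree$nodes$name[match(id, tree$nodes$taxon_id)]
    nm <- gsub("[ ,():;]", "_", nm)
    if (!is.null(counts)) nm <- paste0(nm, "_", counts[id])
    nm
  }
  rec <- function(id) {
    ch <- sort(intersect(setdiff(kids[[id]], id), keep))
    if (length(ch) == 0) return(label(id))
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
           label(id))
  }
  paste0(rec(tree$root), ";")
}
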