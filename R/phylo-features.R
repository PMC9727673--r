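#' Branch-occurrence feature layers
#'
#' Turns a phylogeny plus a presence matrix into one spatial feature per
#' branch: a branch is present in a cell if any of its descendant tips
#' occurs there, and its weight is its branch length — the raw material of
#' phylogeny-weighted prioritization. The edge above the root is excluded
#' (it carries no length). Branch ids are stable content hashes of the
#' sorted descendant tip set, so they are comparable across runs and
#' topologically identical trees.
#'
#' @param tree A rooted [ape::phylo] with branch lengths; every tip must
#'   appear in `presences` (tips with no presence row raise an error).
#' @param presences Long tibble with columns `species`, `cell_id`.
#' @return A long tibble `branch_id`, `weight`, `cell_id` (one row per
#'   branch-cell occurrence), with attribute `branches`: a tibble
#'   `branch_id`, `node`, `weight`, `n_tips`, `n_cells`.
#' @export
branch_occurrences <- function(tree, presences) {
  missing_tips <- setdiff(tree$tip.label, unique(presences$species))
  if (length(missing_tips) > 0) {
    abort(sprintf("tips with no presence rows: %s",
                  paste(head(missing_tips, 10), collapse = ", ")))
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  cells_by_sp <- split(presences$cell_id, presences$species)

  node_cells <- vector("list", n_node)
  node_tips <- vector("list", n_node)
  for (i in seq_len(n_tip)) {
    node_cells[[i]] <- sort(unique(cells_by_sp[[tree$tip.label[i]]]))
    node_tips[[i]] <- tree$tip.label[i]
  }
  for (e in ape::postorder(tree)) { # children before parents
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    node_cells[[par]] <- union(node_cells[[par]] %||% integer(), node_cells[[chd]])
    node_tips[[par]] <- c(node_tips[[par]] %||% character(), node_tips[[chd]])
  }

  nodes <- tree$edge[, 2] # every edge's child node; root excluded by design
  ids <- vapply(nodes, function(nd) rlang::hash(sort(node_tips[[nd]])), "")
  branches <- tibble(
    branch_id = ids,
    node = nodes,
    weight = tree$edge.length,
    n_tips = vapply(nodes, function(nd) length(node_tips[[nd]]), 0L),
    n_cells = vapply(nodes, function(nd) length(node_cells[[nd]]), 0L)
  )
  long <- tibble(
    branch_id = rep(ids, times = branches$n_cells),
    weight = rep(tree$edge.length, times = branches$n_cells),
    cell_id = unlist(lapply(nodes, function(nd) sort(node_cells[[nd]])))
  )
  attr(long, "branches") <- branches
  long
}

#' Faith's phylogenetic diversity per grid cell
#'
#' Local PD of a cell is the summed branch length of the subtree connecting
#' the cell's species to the root (the path to the root is included, so a
#' single-species cell has nonzero PD). Computed by summing, per cell, the
#' lengths of all branches whose descendant tips reach that cell — exactly
#' equivalent to the induced-subtree definition. Cells with no species get
#' PD 0.
#'
#' @inheritParams branch_occurrences
#' @param cells Optional vector of all cell ids (e.g. `grid$cell_id`) so
#'   empty cells appear with `pd = 0`.
#' @return A tibble `cell_id`, `pd`.
#' @export
faith_pd_per_cell <- function(tree, presences, cells = NULL) {
  occ <- branch_occurrences(tree, presences)
  pd <- occ |>
    group_by(.data$cell_id) |>
    summarise(pd = sum(.data$weight), .groups = "drop")
  if (!is.null(cells)) {
    pd <- tibble(cell_id = cells) |>
      left_join(pd, by = "cell_id") |>
      mutate(pd = tidyr::replace_na(.data$pd, 0))
  }
  pd
}

#' Vulnerability of species or branches to habitat change
#'
#' CSH is the relative change in a unit's total suitable habitat between a
#' current and a future scenario: `(future - current) / current`. Units are
#' classified as `lost` (no future habitat), `contracted` (negative CSH),
#' `stable` (0 <= CSH <= `expand_threshold`) or `greatly_expanded`
#' (CSH above the threshold, default 0.8 i.e. an 80% gain). Units with no
#' current habitat get `NA` CSH and are flagged `undefined`.
#'
#' @param current,future Long tibbles (`unit`-like first column, `cell_id`)
#'   of occupied cells per unit; the first column name must match.
#' @param expand_threshold CSH above which a unit counts as greatly expanded.
#' @return A tibble `unit`, `current_cells`, `future_cells`, `csh`, `class`.
#' @export
compute_csh <- function(current, future, expand_threshold = 0.8) {
  key <- names(current)[1]
  if (names(future)[1] != key) abort("unit columns differ between scenarios")
  cur <- current |> group_by(unit = .data[[key]]) |>
    summarise(current_cells = n_distinct(.data$cell_id), .groups = "drop")
  fut <- future |> group_by(unit = .data[[key]]) |>
    summarise(future_cells = n_distinct(.data$cell_id), .groups = "drop")
  full_join(cur, fut, by = "unit") |>
    mutate(
      current_cells = tidyr::replace_na(.data$current_cells, 0L),
      future_cells = tidyr::replace_na(.data$future_cells, 0L),
      csh = ifelse(.data$current_cells > 0,
                   (.data$future_cells - .data$current_cells) / .data$current_cells,
                   NA_real_),
      class = case_when(
        .data$current_cells == 0 ~ "undefined",
        .data$future_cells == 0 ~ "lost",
        .data$csh < 0 ~ "contracted",
        .data$csh > expand_threshold ~ "greatly_expanded",
        TRUE ~ "stable"
      )
    )
}

#' Quantile classes of local phylogenetic diversity
#'
#' Divides cells into `n_classes` near-equal-size classes by their PD rank
#' (class 1 = lowest PD). Tied values share the minimum rank and therefore
#' fall in the lower class; a monotone relabeling of the input leaves the
#' classes unchanged.
#'
#' @param pd Numeric vector of per-cell PD values.
#' @param n_classes Number of classes (default 5).
#' @return An integer vector of class labels in `1:n_classes`.
#' @export
pd_quantile_classes <- function(pd, n_classes = 5) {
  if (length(unique(pd)) == 1) {
    warn("all PD values identical; assigning a single class")
    return(rep(1L, length(pd)))
  }
  r <- rank(pd, ties.method = "min")
  as.integer(ceiling(r * n_classes / length(pd)))
}
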