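#' Assemble a feature set for prioritization
#'
#' Bundles a feature-by-cell occurrence table with feature weights, per-cell
#' cost and an optional lock-in mask into the input object of
#' [run_prioritization()].
#'
#' @param occurrences Long tibble with a feature id column (first column or
#'   `feature`) and `cell_id`; optionally a `weight` column (constant per
#'   feature).
#' @param cells Vector of all cell ids in the landscape (occupied or not).
#' @param weights Optional named numeric vector of feature weights
#'   (default: the `weight` column, else 1).
#' @param cost Per-cell cost, recycled (default 1).
#' @param mask Cell ids locked in (e.g. currently protected cells); locked
#'   cells are removed only after every free cell, which pins them to the
#'   top of the ranking.
#' @param grid Optional grid tibble kept for plotting.
#' @return A `feature_set` object.
#' @export
feature_set <- function(occurrences, cells, weights = NULL, cost = 1,
                        mask = integer(), grid = NULL) {
  key <- if ("feature" %in% names(occurrences)) "feature" else names(occurrences)[1]
  feats <- unique(occurrences[[key]])
  if (length(feats) == 0) abort("no features")
  bad <- setdiff(unique(occurrences$cell_id), cells)
  if (length(bad) > 0) abort("occurrences reference unknown cells")
  occ <- matrix(0, nrow = length(feats), ncol = length(cells),
                dimnames = list(NULL, NULL))
  occ[cbind(match(occurrences[[key]], feats),
            match(occurrences$cell_id, cells))] <- 1
  if (any(rowSums(occ) == 0)) abort("every feature must occupy >= 1 cell")
  if (is.null(weights)) {
    if ("weight" %in% names(occurrences)) {
      weights <- occurrences |>
        distinct(.data[[key]], .data$weight) |>
        (\(d) setNames(d$weight, d[[key]]))()
      weights <- unname(weights[as.character(feats)])
    } else {
      weights <- rep(1, length(feats))
    }
  }
  if (any(weights <= 0)) abort("weights must be positive")
  cost <- rep_len(cost, length(cells))
  if (any(cost <= 0)) abort("costs must be positive")
  structure(
    list(features = feats, cells = cells, occ = occ,
         weights = as.numeric(weights), cost = as.numeric(cost),
         mask = intersect(mask, cells), grid = grid),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features x %d cells (%d locked in)\n",
              length(x$features), length(x$cells), length(x$mask)))
  invisible(x)
}

#' Build a feature set from branch occurrences
#'
#' One feature per phylogenetic branch, weighted by branch length — the
#' phylogeny-weighted prioritization input.
#'
#' @param branch_occ Long tibble from [branch_occurrences()].
#' @inheritParams feature_set
#' @return A `feature_set`.
#' @export
build_branch_featureset <- function(branch_occ, cells, cost = 1,
                                    mask = integer(), grid = NULL) {
  feature_set(branch_occ |> rename(feature = "branch_id"), cells,
              cost = cost, mask = mask, grid = grid)
}

#' Build a species feature set (richness-based prioritization)
#'
#' One unit-weight feature per species, the traditional species-richness
#' counterpart used to benchmark the phylogeny-weighted ranking.
#'
#' @param presences Long tibble `species`, `cell_id`.
#' @inheritParams feature_set
#' @return A `feature_set`.
#' @export
build_species_featureset <- function(presences, cells, cost = 1,
                                     mask = integer(), grid = NULL) {
  feature_set(presences |> rename(feature = "species") |>
                mutate(weight = 1),
              cells, cost = cost, mask = mask, grid = grid)
}

#' Marginal loss of a cell under the current landscape state
#'
#' With `q_ji` the fraction of feature j's remaining occurrences that sit in
#' cell i, the core-area rule (CAZ) scores a cell by the weighted maximum
#' `max_j w_j q_ji / c_i` (what is the most irreplaceable thing here?) and
#' the additive benefit function (ABF) by the weighted sum
#' `sum_j w_j q_ji / c_i`.
#'
#' @param features A `feature_set`.
#' @param cell Cell id to score.
#' @param rule `"caz"` or `"abf"`.
#' @param remaining Cell ids still in the landscape (default: all).
#' @return The marginal-loss value (scalar).
#' @export
marginal_loss <- function(features, cell, rule = c("caz", "abf"),
                          remaining = NULL) {
  rule <- match.arg(rule)
  remaining <- remaining %||% features$cells
  if (!(cell %in% remaining)) abort("cell already removed")
  rem_idx <- match(remaining, features$cells)
  i <- match(cell, features$cells)
  totals <- rowSums(features$occ[, rem_idx, drop = FALSE])
  q <- ifelse(totals > 0, features$occ[, i] / totals, 0)
  v <- features$weights * q
  if (rule == "caz") max(v) / features$cost[i] else sum(v) / features$cost[i]
}

#' Rank all cells by iterative marginal-loss removal
#'
#' The Zonation-style greedy: at each step the remaining cell with the
#' smallest marginal loss (CAZ or ABF) is removed and feature totals are
#' updated, until the landscape is empty. Ties are broken by a seeded
#' random key. Locked-in (masked) cells are removed only after every free
#' cell, so existing protected areas end at the top of the ranking and
#' expansion is chosen among free cells.
#'
#' Each cell's `priority` is the fraction of the landscape already removed
#' when it goes, i.e. `removal_order / n_cells`: higher means the cell
#' survived longer and is more important. The top fraction `f` of the
#' landscape is the set with `priority > 1 - f` (see [top_fraction()]).
#'
#' @param features A `feature_set`.
#' @param rule `"caz"` (weighted max, the default and the rule favoured for
#'   tree-of-life conservation because long branches dominate) or `"abf"`
#'   (weighted sum).
#' @param seed Integer seed for tie-breaking.
#' @return A `priority_rank` object; see [tidy.priority_rank()],
#'   [glance.priority_rank()], [performance_curves()], [top_fraction()].
#' @export
run_prioritization <- function(features, rule = c("caz", "abf"), seed = 1) {
  rule <- match.arg(rule)
  stopifnot(inherits(features, "feature_set"))
  n <- length(features$cells)
  tiebreak <- with_seed(seed, runif(n))
  stratum <- as.integer(features$cells %in% features$mask)
  ord <- greedy_removal_cpp(features$occ, features$weights, features$cost,
                            stratum, if (rule == "caz") 0L else 1L, tiebreak)
  rank <- tibble(
    cell_id = features$cells[ord],
    removal_order = seq_len(n),
    priority = seq_len(n) / n
  )
  structure(list(rank = rank, rule = rule, seed = seed, features = features),
            class = "priority_rank")
}

#' @export
print.priority_rank <- function(x, ...) {
  cat(sprintf("<priority_rank> rule=%s, %d cells, %d features\n",
              x$rule, nrow(x$rank), length(x$features$features)))
  invisible(x)
}

#' @describeIn run_prioritization Per-cell ranking as a tibble
#'   (`cell_id`, `removal_order`, `priority`).
#' @param x A `priority_rank` object.
#' @param ... Unused.
#' @method tidy priority_rank
#' @export
tidy.priority_rank <- function(x, ...) x$rank |> arrange(.data$cell_id)

#' @describeIn run_prioritization One-row summary of the run.
#' @method glance priority_rank
#' @export
glance.priority_rank <- function(x, ...) {
  tibble(n_cells = nrow(x$rank),
         n_features = length(x$features$features),
         n_locked = length(x$features$mask),
         rule = x$rule, seed = x$seed)
}

#' Feature retention curves along the removal sequence
#'
#' For each feature, the fraction of its original occurrences remaining
#' when a fraction `f` of cells has been removed. Retention starts at 1,
#' is non-increasing, and hits 0 exactly when the feature's last occupied
#' cell is removed.
#'
#' @param x A `priority_rank` object.
#' @return A long tibble `feature`, `f`, `retention` (one row per feature
#'   per removal step).
#' @export
performance_curves <- function(x) {
  stopifnot(inherits(x, "priority_rank"))
  fs <- x$features
  ord_idx <- match(x$rank$cell_id, fs$cells)
  occ_ord <- fs$occ[, ord_idx, drop = FALSE]
  lost <- t(apply(occ_ord, 1, cumsum))
  totals <- rowSums(fs$occ)
  ret <- 1 - sweep(lost, 1, totals, "/")
  n <- length(fs$cells)
  tibble(
    feature = rep(fs$features, each = n),
    f = rep(seq_len(n) / n, times = length(fs$features)),
    retention = as.vector(t(ret))
  )
}

#' Top-priority fraction of the landscape
#'
#' The `ceiling(f * n)` cells removed last — the cells a conservation plan
#' targeting a fraction `f` of the land would select.
#'
#' @param x A `priority_rank` object (or its [tidy()] tibble).
#' @param f Fraction in (0, 1].
#' @return A vector of cell ids.
#' @export
top_fraction <- function(x, f) {
  if (f <= 0 || f > 1) abort("f must be in (0,1]")
  rank <- if (inherits(x, "priority_rank")) x$rank else x
  k <- ceiling(f * nrow(rank))
  rank |> arrange(desc(.data$removal_order)) |> head(k) |> pull("cell_id")
}

#' Partition current vs future priority areas
#'
#' Splits the union of two priority-cell sets into cells selected under
#' both scenarios (`overlapped`), only currently (`disappeared`) and only
#' in the future (`newly_formed`).
#'
#' @param current_top,future_top Cell-id vectors (e.g. from
#'   [top_fraction()]).
#' @return A tibble `cell_id`, `status`.
#' @export
scenario_overlap <- function(current_top, future_top) {
  all_cells <- union(current_top, future_top)
  tibble(
    cell_id = all_cells,
    status = case_when(
      all_cells %in% current_top & all_cells %in% future_top ~ "overlapped",
      all_cells %in% current_top ~ "disappeared",
      TRUE ~ "newly_formed"
    )
  )
}

#' Pearson correlation between two rank maps
#'
#' The standard agreement check between priority maps from different rules
#' or different resolved phylogenies.
#'
#' @param a,b `priority_rank` objects (or tidy rank tibbles) on the same
#'   grid.
#' @return Pearson's r of the per-cell priorities.
#' @export
compare_rank_maps <- function(a, b) {
  ta <- if (inherits(a, "priority_rank")) a$rank else a
  tb <- if (inherits(b, "priority_rank")) b$rank else b
  j <- inner_join(ta, tb, by = "cell_id", suffix = c("_a", "_b"))
  if (nrow(j) != nrow(ta) || nrow(j) != nrow(tb)) abort("grids differ")
  if (sd(j$priority_a) == 0 || sd(j$priority_b) == 0) {
    abort("zero variance in priorities")
  }
  cor(j$priority_a, j$priority_b)
}
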