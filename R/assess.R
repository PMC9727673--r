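#' Flag protected cells
#'
#' A cell counts as protected when reserve polygons cover strictly more
#' than `cutoff` of its area (default 30%, the post-2020 framework figure).
#'
#' @param pa A tibble with `cell_id` and `pa_fraction` in `[0, 1]`.
#' @param cutoff Area-fraction cutoff; the comparison is strict (`>`).
#' @return The input with a logical `protected` column.
#' @export
protected_cells <- function(pa, cutoff = 0.3) {
  if (any(pa$pa_fraction < 0 | pa$pa_fraction > 1)) {
    abort("pa_fraction must be in [0,1]")
  }
  pa |> mutate(protected = .data$pa_fraction > cutoff)
}

#' Range-scaled representation target
#'
#' The fraction of a unit's range that ought to be protected, scaled with
#' range size in the Rodrigues et al. manner: 100% for ranges below
#' `lower` km2, a `floor` (10%) above `upper` km2, log-linear in between:
#' `1 - (1 - floor) * (log A - log lower) / (log upper - log lower)`.
#'
#' @param range_area Range area(s) in km2 (> 0).
#' @param lower,upper Interpolation endpoints in km2.
#' @param floor Minimum target fraction for the widest ranges.
#' @return Target fraction(s) in `[floor, 1]`.
#' @export
conservation_target <- function(range_area, lower = 1000, upper = 250000,
                                floor = 0.1) {
  if (any(range_area <= 0)) abort("range_area must be positive")
  t <- 1 - (1 - floor) * (log(range_area) - log(lower)) /
    (log(upper) - log(lower))
  pmin(1, pmax(floor, t))
}

#' Gap classification of species or branches
#'
#' Compares each unit's protected range against its representation target.
#' `achieved` is protected-cells-in-range divided by `target * range-cells`.
#' Classes: `unprotected` (no protected cell at all), `gap` (achieved up to
#' 20% of target), `partial_gap` (20-90%] and `covered` (> 90%).
#'
#' @param units A tibble with columns `unit`, `range_cells` (count),
#'   `protected_in_range` (count) and `target` (fraction in (0, 1]).
#' @return The input with `achieved` and `class` columns.
#' @export
gap_classify <- function(units) {
  stopifnot(all(c("unit", "range_cells", "protected_in_range", "target")
                %in% names(units)))
  if (any(units$target <= 0 | units$target > 1)) abort("targets must be in (0,1]")
  units |>
    mutate(
      achieved = .data$protected_in_range / (.data$target * .data$range_cells),
      class = case_when(
        .data$protected_in_range == 0 ~ "unprotected",
        .data$achieved <= 0.2 ~ "gap",
        .data$achieved <= 0.9 ~ "partial_gap",
        TRUE ~ "covered"
      )
    )
}

#' Gap analysis from occurrence layers
#'
#' Convenience wrapper: counts each unit's range and protected cells,
#' derives its representation target from range area (cells x cell area)
#' and classifies it with [gap_classify()].
#'
#' @param occurrences Long tibble with a unit column (first column) and
#'   `cell_id`.
#' @param protected Cell ids of protected cells.
#' @param cell_area Cell area in km2 (default 400 = 20 x 20 km).
#' @param ... Passed to [conservation_target()].
#' @return A classified tibble, one row per unit.
#' @export
gap_analysis <- function(occurrences, protected, cell_area = 400, ...) {
  key <- names(occurrences)[1]
  occurrences |>
    group_by(unit = .data[[key]]) |>
    summarise(
      range_cells = n_distinct(.data$cell_id),
      protected_in_range = n_distinct(.data$cell_id[.data$cell_id %in% protected]),
      .groups = "drop"
    ) |>
    mutate(target = conservation_target(.data$range_cells * cell_area, ...)) |>
    gap_classify()
}

#' Mean geographical coverage of branches by a protected set
#'
#' The mean over branches of the fraction of each branch's occupied cells
#' that are protected — the headline statistic of tree-of-life protection
#' accounting. Monotone non-decreasing under any enlargement of the
#' protected set.
#'
#' @param branch_occ Long tibble from [branch_occurrences()] (or any
#'   unit/cell_id long table).
#' @param protected Cell ids of protected cells.
#' @param weights Optional named vector of per-branch weights (e.g. branch
#'   lengths) keyed by unit id; when given, the mean is weighted.
#' @return A single number in `[0, 1]`.
#' @seealso [branch_coverage()] for the per-branch table.
#' @export
mean_branch_coverage <- function(branch_occ, protected, weights = NULL) {
  cov <- branch_coverage(branch_occ, protected)
  if (is.null(weights)) {
    mean(cov$coverage)
  } else {
    w <- weights[as.character(cov$unit)]
    sum(w * cov$coverage) / sum(w)
  }
}

#' @describeIn mean_branch_coverage Per-branch coverage table
#'   (`unit`, `range_cells`, `covered_cells`, `coverage`).
#' @export
branch_coverage <- function(branch_occ, protected) {
  key <- names(branch_occ)[1]
  branch_occ |>
    group_by(unit = .data[[key]]) |>
    summarise(
      range_cells = n_distinct(.data$cell_id),
      covered_cells = n_distinct(.data$cell_id[.data$cell_id %in% protected]),
      .groups = "drop"
    ) |>
    mutate(coverage = .data$covered_cells / .data$range_cells)
}

#' Protection per phylogenetic-diversity class
#'
#' For each local-PD class, the fraction of its cells that is protected.
#'
#' @param pd_classes Integer class label per cell (see
#'   [pd_quantile_classes()]).
#' @param protected Logical protected flag per cell (same order).
#' @return A tibble `pd_class`, `n_cells`, `n_protected`, `prop_protected`.
#' @export
pd_class_protection <- function(pd_classes, protected) {
  if (length(pd_classes) != length(protected)) abort("length mismatch")
  tibble(pd_class = pd_classes, protected = as.logical(protected)) |>
    group_by(.data$pd_class) |>
    summarise(n_cells = n(), n_protected = sum(.data$protected),
              .groups = "drop") |>
    mutate(prop_protected = .data$n_protected / .data$n_cells)
}

#' Human-pressure classes
#'
#' The standard three-way banding of the human modification index:
#' low (< 0.1), moderate ([0.1, 0.4)) and high (>= 0.4).
#'
#' @param hmi Numeric vector in `[0, 1]`.
#' @return A factor with levels `low`, `moderate`, `high`.
#' @export
hmi_classify <- function(hmi) {
  if (any(hmi < 0 | hmi > 1)) abort("hmi must be in [0,1]")
  cut(hmi, breaks = c(-Inf, 0.1, 0.4, Inf), right = FALSE,
      labels = c("low", "moderate", "high"))
}

#' Human pressure by protection group
#'
#' Descriptive summaries (mean, sd, n, class shares) of HMI in groups of
#' cells — typically existing protected areas, selected expansion areas and
#' the remaining unprotected land.
#'
#' @param hmi Numeric HMI per cell.
#' @param groups Character/factor group label per cell (a partition).
#' @return A tibble, one row per group: `group`, `n`, `mean_hmi`, `sd_hmi`,
#'   `share_low`, `share_moderate`, `share_high`.
#' @export
group_hmi_summary <- function(hmi, groups) {
  if (length(hmi) != length(groups)) abort("length mismatch")
  tibble(hmi = hmi, group = as.character(groups)) |>
    mutate(class = hmi_classify(.data$hmi)) |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      mean_hmi = mean(.data$hmi),
      sd_hmi = ifelse(n() > 1, sd(.data$hmi), 0),
      share_low = mean(.data$class == "low"),
      share_moderate = mean(.data$class == "moderate"),
      share_high = mean(.data$class == "high"),
      .groups = "drop"
    )
}

#' Flag cells with novel (non-analogous) climate
#'
#' Area-of-applicability style screening: variables are standardized by the
#' reference mean/sd; each projected cell's dissimilarity is its nearest-
#' neighbour Euclidean distance to the reference cells, scaled by the mean
#' pairwise reference distance; a cell is novel when its dissimilarity
#' exceeds the `quantile` of the reference cells' own leave-one-out
#' dissimilarities. On exchangeable reference/projection data about
#' `1 - quantile` of cells are flagged; a projection identical to the
#' reference flags none.
#'
#' @param reference,projection Climate tibbles with the same variables.
#' @param quantile Calibration quantile (default 0.95).
#' @return A tibble `cell_id`, `dissimilarity`, `novel`, with attribute
#'   `threshold`.
#' @export
aoa_novel_climate <- function(reference, projection, quantile = 0.95) {
  vars <- climate_vars(reference)
  if (!setequal(vars, climate_vars(projection))) abort("variables differ")
  if (nrow(reference) < 2) abort("need at least 2 reference cells")
  mu <- colMeans(as.matrix(reference[vars]))
  sg <- apply(as.matrix(reference[vars]), 2, sd)
  sg[sg == 0] <- 1
  zr <- sweep(sweep(as.matrix(reference[vars]), 2, mu), 2, sg, "/")
  zp <- sweep(sweep(as.matrix(projection[vars]), 2, mu), 2, sg, "/")

  dref <- as.matrix(dist(zr))
  dbar <- mean(dref[upper.tri(dref)])
  diag(dref) <- Inf
  loo <- apply(dref, 1, min) / dbar
  thr <- stats::quantile(loo, quantile, names = FALSE)

  cross <- cross_dist_mat(zp, zr)
  di <- apply(cross, 1, min) / dbar
  out <- tibble(cell_id = projection$cell_id, dissimilarity = di,
                novel = di > thr)
  attr(out, "threshold") <- thr
  out
}

# Euclidean cross-distance between row sets of two matrices.
cross_dist_mat <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Protected-area expansion report
#'
#' Given a masked prioritization (existing reserves locked in), selects the
#' highest-priority free cells amounting to each additional land fraction,
#' and reports mean branch coverage and PD-class protection before and
#' after expansion. The canonical fractions +15% and +35% take a reserve
#' system of about 15% of the land to the 30% and 50% area targets.
#'
#' @param rank A `priority_rank` from a run whose mask equals
#'   `protected`.
#' @param protected Cell ids of currently protected cells.
#' @param branch_occ Long branch-occurrence tibble.
#' @param pd_classes Optional integer PD class per cell (in `rank` cell
#'   order after sorting by `cell_id`).
#' @param add_fractions Additional land fractions to evaluate.
#' @return A list with `summary` (one row per fraction: cells added, mean
#'   branch coverage before/after) and `expansion` (tibble `add_fraction`,
#'   `cell_id`), plus `pd_protection` per fraction when `pd_classes` is
#'   given.
#' @export
expansion_report <- function(rank, protected, branch_occ,
                             pd_classes = NULL,
                             add_fractions = c(0.15, 0.35)) {
  stopifnot(inherits(rank, "priority_rank"))
  if (!setequal(rank$features$mask, protected)) {
    abort("rank must come from a run masked by `protected`")
  }
  n <- nrow(rank$rank)
  free_rank <- rank$rank |>
    filter(!(.data$cell_id %in% protected)) |>
    arrange(desc(.data$removal_order))
  before <- mean_branch_coverage(branch_occ, protected)
  cells_sorted <- sort(rank$features$cells)

  rows <- list(); exp_rows <- list(); pd_prot <- list()
  for (f in add_fractions) {
    k <- ceiling(f * n)
    if (k > nrow(free_rank)) abort("add fraction exceeds the free-cell share")
    add <- free_rank$cell_id[seq_len(k)]
    new_prot <- union(protected, add)
    rows[[length(rows) + 1]] <- tibble(
      add_fraction = f, n_added = k,
      coverage_before = before,
      coverage_after = mean_branch_coverage(branch_occ, new_prot)
    )
    exp_rows[[length(exp_rows) + 1]] <- tibble(add_fraction = f, cell_id = add)
    if (!is.null(pd_classes)) {
      pd_prot[[as.character(f)]] <- pd_class_protection(
        pd_classes, cells_sorted %in% new_prot)
    }
  }
  out <- list(summary = bind_rows(rows), expansion = bind_rows(exp_rows))
  if (!is.null(pd_classes)) {
    out$pd_protection_before <- pd_class_protection(
      pd_classes, cells_sorted %in% protected)
    out$pd_protection_after <- pd_prot
  }
  out
}
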