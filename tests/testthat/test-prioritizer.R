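simple_fs <- function(occ_long, cells, ...) feature_set(occ_long, cells, ...)

test_that("marginal loss follows the CAZ/ABF formulas", {
  # one feature in 4 cells, w = 2, cost 1 -> q = 0.25, CAZ loss 0.5
  fs <- feature_set(data.frame(feature = "f1", cell_id = 0:3), 0:3,
                    weights = 2)
  expect_equal(marginal_loss(fs, 0, "caz"), 0.5)
  # two features with w*q of 0.3 and 0.5 in a cell: CAZ max, ABF sum
  occ <- dplyr::bind_rows(
    data.frame(feature = "a", cell_id = 0:9),   # q = 0.1, w = 3 -> 0.3
    data.frame(feature = "b", cell_id = 0:1)    # q = 0.5, w = 1 -> 0.5
  )
  fs2 <- feature_set(occ, 0:9, weights = c(3, 1))
  expect_equal(marginal_loss(fs2, 0, "caz"), 0.5)
  expect_equal(marginal_loss(fs2, 0, "abf"), 0.8)
  # a feature's last remaining cell: q = 1, loss >= w/c
  expect_gte(marginal_loss(fs2, 1, "caz", remaining = c(1, 5, 6)), 1)
  expect_error(marginal_loss(fs2, 3, remaining = c(1, 2)), "removed")
})

test_that("an irreplaceable cell is removed last", {
  # feature A only in cell 0, feature B everywhere, equal weights:
  # exhaustive reasoning says cell 0 must survive to the end
  occ <- dplyr::bind_rows(
    data.frame(feature = "A", cell_id = 0L),
    data.frame(feature = "B", cell_id = 0:2)
  )
  for (rule in c("caz", "abf")) {
    for (s in 1:5) {
      r <- run_prioritization(feature_set(occ, 0:2), rule, seed = s)
      expect_equal(r$rank$cell_id[3], 0L)
    }
  }
})

test_that("removal order matches the exhaustive greedy oracle", {
  for (s in 1:50) {
    inst <- random_instance(s, with_mask = s %% 2 == 0)
    keys <- tiebreak_keys(s, ncol(inst$occ))
    for (rule in c("caz", "abf")) {
      got <- run_on_instance(inst, rule, seed = s)$rank$cell_id + 1L
      want <- oracle_greedy(inst$occ, inst$w, inst$cost, inst$stratum,
                            rule, keys)
      expect_identical(as.integer(got), as.integer(want))
    }
  }
})

test_that("identical cells are removed in a seeded uniform order", {
  occ <- data.frame(feature = "f", cell_id = 0:7)
  fs <- feature_set(occ, 0:7)
  r1 <- run_prioritization(fs, "caz", seed = 9)
  r2 <- run_prioritization(fs, "caz", seed = 9)
  expect_identical(r1$rank, r2$rank)
  r3 <- run_prioritization(fs, "caz", seed = 10)
  expect_false(identical(r1$rank$cell_id, r3$rank$cell_id))
  # matches the rank order of the tie-break keys themselves
  expect_identical(r1$rank$cell_id[1:7], (0:7)[order(tiebreak_keys(9, 8))][1:7])
})

test_that("scaling all weights leaves the removal order unchanged", {
  inst <- random_instance(99)
  keys_fs <- function(k) {
    cells <- seq_len(ncol(inst$occ)) - 1L
    occ_long <- do.call(rbind, lapply(seq_len(nrow(inst$occ)), function(j) {
      data.frame(feature = paste0("f", j), cell_id = cells[inst$occ[j, ] == 1])
    }))
    feature_set(occ_long, cells, weights = inst$w * k, cost = inst$cost)
  }
  for (rule in c("caz", "abf")) {
    base <- run_prioritization(keys_fs(1), rule, seed = 3)$rank$cell_id
    expect_identical(run_prioritization(keys_fs(7.3), rule, seed = 3)$rank$cell_id,
                     base)
  }
})

test_that("locked-in cells outrank every free cell", {
  withr::with_seed(31, {
    occ <- dplyr::bind_rows(lapply(1:6, function(j) {
      data.frame(feature = paste0("f", j), cell_id = sample(0:19, 8))
    }))
  })
  mask <- c(2L, 5L, 11L)
  fs <- feature_set(occ, 0:19, mask = mask)
  r <- run_prioritization(fs, "caz", seed = 1)
  pa_min <- min(r$rank$priority[r$rank$cell_id %in% mask])
  free_max <- max(r$rank$priority[!r$rank$cell_id %in% mask])
  expect_gt(pa_min, free_max)
})

test_that("CAZ keeps a narrow-range, heavily weighted feature in the top set", {
  withr::with_seed(17, {
    occ <- dplyr::bind_rows(
      data.frame(feature = "long_branch", cell_id = 7L),
      data.frame(feature = "common", cell_id = 0:19)
    )
  })
  fs <- feature_set(occ, 0:19, weights = c(10, 1))
  for (s in 1:5) {
    r <- run_prioritization(fs, "caz", seed = s)
    expect_true(7L %in% top_fraction(r, 1 / 20))
  }
})

test_that("performance curves retain everything at start and nothing at the end", {
  inst <- random_instance(123, max_cells = 6, max_feats = 4)
  r <- run_on_instance(inst, "abf", seed = 2)
  curves <- performance_curves(r)
  for (f in unique(curves$feature)) {
    ret <- curves$retention[curves$feature == f]
    expect_true(all(diff(ret) <= 1e-12)) # non-increasing
    expect_equal(ret[length(ret)], 0)
  }
  # retention hits 0 exactly when the feature's last occupied cell goes
  feats <- r$features$features
  for (j in seq_along(feats)) {
    cells_j <- r$features$cells[r$features$occ[j, ] == 1]
    last_removed <- max(r$rank$removal_order[r$rank$cell_id %in% cells_j])
    ret <- curves$retention[curves$feature == feats[j]]
    expect_equal(min(which(ret == 0)), last_removed)
  }
})

test_that("tidy, glance and top_fraction expose the ranking faithfully", {
  inst <- random_instance(5)
  r <- run_on_instance(inst, "caz", seed = 4)
  td <- tidy(r)
  expect_equal(nrow(td), ncol(inst$occ))
  expect_setequal(td$cell_id, r$rank$cell_id)
  expect_true(all(sort(r$rank$removal_order) == seq_len(nrow(td))))
  gl <- glance(r)
  expect_equal(gl$n_cells, ncol(inst$occ))
  expect_equal(gl$rule, "caz")

  rk <- run_prioritization(
    feature_set(data.frame(feature = "f", cell_id = 0:9), 0:9), "caz", 1)
  expect_length(top_fraction(rk, 0.3), 3) # ceiling rule
  expect_setequal(top_fraction(rk, 1), 0:9)
  expect_true(all(top_fraction(rk, 0.3) %in% top_fraction(rk, 0.5)))
  expect_error(top_fraction(rk, 0), "f must be")
})

test_that("scenario overlap partitions the union of priority sets", {
  out <- scenario_overlap(c(1, 2, 3), c(2, 3, 4))
  expect_setequal(out$cell_id[out$status == "overlapped"], c(2, 3))
  expect_setequal(out$cell_id[out$status == "disappeared"], 1)
  expect_setequal(out$cell_id[out$status == "newly_formed"], 4)
  same <- scenario_overlap(1:3, 1:3)
  expect_true(all(same$status == "overlapped"))
  disj <- scenario_overlap(1:3, 4:6)
  expect_equal(sum(disj$status == "disappeared"), 3)
  expect_equal(sum(disj$status == "newly_formed"), 3)
  expect_equal(nrow(disj), 6)
})

test_that("rank-map correlation behaves at its extremes and near zero", {
  rank_tbl <- function(ord) {
    tibble::tibble(cell_id = ord, removal_order = seq_along(ord),
                   priority = seq_along(ord) / length(ord))
  }
  a <- rank_tbl(0:9)
  expect_equal(compare_rank_maps(a, a), 1)
  expect_equal(compare_rank_maps(a, rank_tbl(9:0)), -1)
  rs <- withr::with_seed(77, {
    replicate(100, {
      compare_rank_maps(rank_tbl(sample(0:399)), rank_tbl(sample(0:399)))
    })
  })
  expect_lt(mean(abs(rs)), 0.1)
})

test_that("feature sets validate their inputs", {
  expect_error(feature_set(data.frame(feature = "f", cell_id = 5L), 0:3),
               "unknown cells")
  expect_error(feature_set(data.frame(feature = "f", cell_id = 0L), 0:3,
                           weights = -1), "positive")
  expect_error(feature_set(data.frame(feature = "f", cell_id = 0L), 0:3,
                           cost = 0), "positive")
})
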