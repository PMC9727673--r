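make_presences <- function(...) {
  sets <- list(...)
  dplyr::bind_rows(lapply(names(sets), function(sp) {
    tibble::tibble(species = sp, cell_id = as.integer(sets[[sp]]))
  }))
}

test_that("branch occurrences are unions over descendant tips", {
  tr <- tiny_tree()
  pr <- make_presences(A = c(1, 2), B = 2, C = 5)
  occ <- branch_occurrences(tr, pr)
  br <- attr(occ, "branches")
  expect_equal(nrow(br), 4) # 3 tip edges + 1 internal edge; root excluded
  # tip branches occupy exactly their species' cells
  sets <- split(occ$cell_id, occ$branch_id)
  ab_id <- br$branch_id[br$n_tips == 2]
  expect_setequal(sets[[ab_id]], c(1, 2)) # ancestor of A,B: union rule
  expect_error(branch_occurrences(tr, make_presences(A = 1, B = 2)), "C")
})

test_that("branch cell sets match brute-force descendant enumeration", {
  for (s in 1:25) {
    tr <- simulate_tree(sample(3:12, 1), 1, 0, seed = 700 + s)
    pr <- withr::with_seed(800 + s, {
      dplyr::bind_rows(lapply(tr$tip.label, function(sp) {
        tibble::tibble(species = sp, cell_id = sample(0:19, sample(1:8, 1)))
      }))
    })
    occ <- branch_occurrences(tr, pr)
    br <- attr(occ, "branches")
    sets <- split(occ$cell_id, occ$branch_id)
    by_sp <- split(pr$cell_id, pr$species)
    for (e in seq_len(nrow(tr$edge))) {
      tips <- oracle_descendant_tips(tr, e)
      expected <- sort(unique(unlist(by_sp[tips])))
      id <- br$branch_id[br$node == tr$edge[e, 2]]
      expect_equal(sort(unique(sets[[id]])), expected)
    }
    # ancestor branches contain their descendants' cells (monotonicity)
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]
      pe <- which(tr$edge[, 2] == parent)
      if (length(pe) == 1) {
        id_c <- br$branch_id[br$node == tr$edge[e, 2]]
        id_p <- br$branch_id[br$node == parent]
        expect_true(all(sets[[id_c]] %in% sets[[id_p]]))
      }
    }
  }
})

make_presences2 <- function(spp, cell) {
  dplyr::bind_rows(lapply(spp, function(s) {
    tibble::tibble(species = s, cell_id = cell)
  }))
}

test_that("Faith's PD matches the worked three-tip cases", {
  tr <- tiny_tree()
  pd_of <- function(spp) {
    pr <- dplyr::bind_rows(lapply(spp, function(s) {
      tibble::tibble(species = s, cell_id = 0L)
    }))
    # other species parked in cell 99 so all tips have rows
    rest <- setdiff(c("A", "B", "C"), spp)
    pr <- dplyr::bind_rows(pr, make_presences2(rest, 99L))
    faith_pd_per_cell(tr, pr)$pd[faith_pd_per_cell(tr, pr)$cell_id == 0]
  }
  expect_equal(pd_of("A"), 2)       # tip branch 1 + stem 1
  expect_equal(pd_of(c("A", "B")), 3)
  expect_equal(pd_of(c("A", "B", "C")), 5) # the whole tree
})

test_that("branch-layer PD equals path-sum and induced-subtree oracles", {
  skip_if_not_installed("picante")
  for (s in 1:20) {
    n <- sample(4:12, 1)
    tr <- simulate_tree(n, 1, 0, seed = 900 + s)
    pr <- withr::with_seed(1000 + s, {
      dplyr::bind_rows(lapply(tr$tip.label, function(sp) {
        tibble::tibble(species = sp, cell_id = sample(0:9, sample(1:5, 1)))
      }))
    })
    pd <- faith_pd_per_cell(tr, pr, cells = 0:9)
    by_cell <- split(pr$species, pr$cell_id)
    comm <- matrix(0, nrow = 10, ncol = n,
                   dimnames = list(as.character(0:9), tr$tip.label))
    for (cl in names(by_cell)) comm[cl, unique(by_cell[[cl]])] <- 1
    picante_pd <- picante::pd(comm, tr, include.root = TRUE)$PD
    for (i in 1:10) {
      spp <- unique(by_cell[[as.character(i - 1)]])
      expect_equal(pd$pd[pd$cell_id == i - 1], oracle_pd(tr, spp))
      if (length(spp) > 0) {
        expect_equal(pd$pd[pd$cell_id == i - 1], picante_pd[i])
      }
    }
  }
})

test_that("PD is bounded by total tree length and monotone in species removal", {
  tr <- simulate_tree(15, 1, 0, seed = 21)
  total <- sum(tr$edge.length)
  pr <- withr::with_seed(22, {
    dplyr::bind_rows(lapply(tr$tip.label, function(sp) {
      tibble::tibble(species = sp, cell_id = sample(0:5, 3))
    }))
  })
  pd <- faith_pd_per_cell(tr, pr, cells = 0:5)
  expect_true(all(pd$pd <= total + 1e-9))
  # dropping one species from a cell never increases that cell's PD
  target <- pr$species[pr$cell_id == 0][1]
  pr2 <- pr[!(pr$species == target & pr$cell_id == 0), ]
  pd2 <- faith_pd_per_cell(tr, pr2, cells = 0:5)
  expect_lte(pd2$pd[pd2$cell_id == 0], pd$pd[pd$cell_id == 0])
})

test_that("habitat-change classes follow the CSH definition", {
  cur <- tibble::tibble(species = rep(c("a", "b", "c", "d"), c(10, 10, 10, 10)),
                        cell_id = c(0:9, 0:9, 0:9, 0:9))
  fut <- tibble::tibble(
    species = rep(c("a", "c", "d"), c(5, 19, 12)),
    cell_id = c(0:4, 0:18, 0:11)
  )
  out <- compute_csh(cur, fut)
  expect_equal(out$csh[out$unit == "a"], -0.5)
  expect_equal(out$class[out$unit == "a"], "contracted")
  expect_equal(out$class[out$unit == "b"], "lost")
  expect_equal(out$csh[out$unit == "c"], 0.9)
  expect_equal(out$class[out$unit == "c"], "greatly_expanded")
  expect_equal(out$class[out$unit == "d"], "stable") # csh 0.2
})

test_that("PD quantile classes are rank-based with ties pushed down", {
  x <- c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6)
  cls <- pd_quantile_classes(x, 5)
  expect_equal(as.vector(table(cls)), rep(2L, 5))
  # monotone relabeling leaves classes unchanged
  expect_equal(pd_quantile_classes(x^3, 5), cls)
  # heavy ties: compare to a sorted-rank oracle
  y <- c(1, 2, 2, 2, 2, 2, 3, 4, 5, 6)
  cls_y <- pd_quantile_classes(y, 5)
  r <- rank(y, ties.method = "min")
  expect_equal(cls_y, as.integer(ceiling(r * 5 / length(y))))
  expect_length(unique(cls_y[y == 2]), 1)
  expect_setequal(sort(unique(cls_y)), unique(sort(cls_y))) # partition complete
  expect_warning(one <- pd_quantile_classes(rep(3, 4)), "identical")
  expect_equal(one, rep(1L, 4))
})

test_that("grafting expands genera reproducibly while staying ultrametric", {
  bb <- ape::read.tree(text = "((GenA:2,GenB:2):1,GenC:3);")
  mem <- tibble::tibble(
    species = c("a1", "a2", "a3", "b1", "c1", "c2"),
    genus = c("GenA", "GenA", "GenA", "GenB", "GenC", "GenC")
  )
  tr <- graft_and_resolve(bb, mem, seed = 5)
  expect_setequal(tr$tip.label, mem$species)
  expect_equal(tr$Nnode, length(mem$species) - 1) # fully binary
  expect_true(all(tr$edge.length > 0))
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_equal(max(depths), 3) # backbone depth preserved
  expect_identical(ape::write.tree(graft_and_resolve(bb, mem, seed = 5)),
                   ape::write.tree(tr))
  expect_false(identical(ape::write.tree(graft_and_resolve(bb, mem, seed = 6)),
                         ape::write.tree(tr)))
})

test_that("species with unknown genera are excluded with a warning", {
  bb <- ape::read.tree(text = "(GenA:1,GenB:1);")
  mem <- tibble::tibble(species = c("a1", "b1", "x1"),
                        genus = c("GenA", "GenB", "GenX"))
  expect_warning(tr <- graft_and_resolve(bb, mem, seed = 1), "GenX|x1")
  expect_setequal(tr$tip.label, c("a1", "b1"))
  expect_equal(attr(tr, "unplaced"), "x1")
})
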