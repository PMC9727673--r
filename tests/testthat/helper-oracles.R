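# Independent oracle implementations used to verify the package's fast
# paths. These deliberately share no code with the implementations they
# check: the greedy oracle recomputes every loss from the raw matrix with
# base-R reductions, and the PD oracle walks root-to-tip paths.

# Exhaustive greedy cell removal. occ: features x cells 0/1 matrix.
# Returns the removal sequence of column indices (first removed first).
oracle_greedy <- function(occ, w, cost, stratum = rep(0L, ncol(occ)),
                          rule = "caz", tiebreak = seq_len(ncol(occ))) {
  remaining <- rep(TRUE, ncol(occ))
  out <- integer(0)
  for (s in 0:1) {
    while (any(remaining & stratum == s)) {
      totals <- rowSums(occ[, remaining, drop = FALSE])
      cand <- which(remaining & stratum == s)
      losses <- vapply(cand, function(i) {
        q <- ifelse(totals > 0, occ[, i] / totals, 0)
        if (rule == "caz") max(w * q) / cost[i] else sum(w * q) / cost[i]
      }, 0.0)
      best <- cand[losses == min(losses)]
      pick <- best[which.min(tiebreak[best])]
      remaining[pick] <- FALSE
      out <- c(out, pick)
    }
  }
  out
}

# Faith's PD of a species set by summing edges on root-to-tip paths.
oracle_pd <- function(tree, species) {
  if (length(species) == 0) return(0)
  root <- length(tree$tip.label) + 1L
  edges <- integer(0)
  for (sp in species) {
    node <- which(tree$tip.label == sp)
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[unique(edges)])
}

# All descendant tip labels of the node subtended by edge e (brute force
# breadth-first walk over the edge table).
oracle_descendant_tips <- function(tree, e) {
  frontier <- tree$edge[e, 2]
  tips <- character(0)
  while (length(frontier) > 0) {
    node <- frontier[1]
    frontier <- frontier[-1]
    if (node <= length(tree$tip.label)) {
      tips <- c(tips, tree$tip.label[node])
    } else {
      frontier <- c(frontier, tree$edge[tree$edge[, 1] == node, 2])
    }
  }
  sort(tips)
}

# Lag-1 (rook neighbour) Moran's I on a row-major field.
moran_i <- function(values, nx, ny) {
  m <- matrix(values, nrow = ny, ncol = nx, byrow = TRUE)
  z <- m - mean(m)
  num <- 0; wsum <- 0
  for (dr in list(c(0, 1), c(1, 0))) {
    a <- z[seq_len(ny - dr[1]), seq_len(nx - dr[2])]
    b <- z[seq_len(ny - dr[1]) + dr[1], seq_len(nx - dr[2]) + dr[2]]
    num <- num + 2 * sum(a * b)
    wsum <- wsum + 2 * length(a)
  }
  (length(z) / wsum) * num / sum(z^2)
}

# Random small prioritization instance for oracle comparisons.
random_instance <- function(seed, max_cells = 6, max_feats = 4,
                            with_mask = FALSE) {
  withr::with_seed(seed, {
    nc <- sample(2:max_cells, 1)
    nf <- sample(1:max_feats, 1)
    occ <- matrix(0, nf, nc)
    for (j in seq_len(nf)) {
      occ[j, sample(nc, sample(nc, 1))] <- 1
    }
    list(
      occ = occ,
      w = runif(nf, 0.1, 3),
      cost = runif(nc, 0.5, 2),
      stratum = if (with_mask) sample(0:1, nc, replace = TRUE) else rep(0L, nc)
    )
  })
}

# Tie-break keys exactly as run_prioritization() derives them from its seed,
# so the oracle resolves ties identically without sharing any code.
tiebreak_keys <- function(seed, n) withr::with_seed(seed, runif(n))

# Run the package prioritizer on a raw instance via the feature_set API.
run_on_instance <- function(inst, rule, seed = 1) {
  cells <- seq_len(ncol(inst$occ)) - 1L
  occ_long <- do.call(rbind, lapply(seq_len(nrow(inst$occ)), function(j) {
    data.frame(feature = paste0("f", j), cell_id = cells[inst$occ[j, ] == 1])
  }))
  fs <- feature_set(occ_long, cells,
                    weights = inst$w, cost = inst$cost,
                    mask = cells[inst$stratum == 1])
  run_prioritization(fs, rule, seed = seed)
}

# Point-to-segment distance, written from the classic projection formula.
point_seg_oracle <- function(px, py, ax, ay, bx, by) {
  mapply(function(x, y) {
    t <- ((x - ax) * (bx - ax) + (y - ay) * (by - ay)) /
      ((bx - ax)^2 + (by - ay)^2)
    t <- max(0, min(1, t))
    sqrt((x - (ax + t * (bx - ax)))^2 + (y - (ay + t * (by - ay)))^2)
  }, px, py)
}

# Tiny fixed tree used across phylo tests: ((A:1,B:1):1,C:2);
tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
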