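#' Simulate spatially autocorrelated climate surfaces
#'
#' Generates `n_vars` standardized climate variables over the grid by Gaussian
#' smoothing of white noise. `corr_len` controls the spatial correlation
#' length in cells: the smoothing kernel has standard deviation
#' `corr_len - 1`, so `corr_len = 1` is exactly uncorrelated white noise and
#' larger values give smoother fields (monotonically larger lag-1 Moran's I).
#' Each variable is re-standardized to zero mean and unit variance after
#' smoothing.
#'
#' @param grid A grid tibble from [make_grid()].
#' @param n_vars Number of climate variables (default 6, mirroring the usual
#'   bioclim set of seasonality / extreme-quarter variables).
#' @param corr_len Correlation length in cells (>= 1).
#' @param seed Integer seed; the same seed yields a bitwise-identical stack.
#' @param scenario Label attached to the stack (`"current"` by default).
#' @return A tibble with `cell_id` and one column per variable
#'   (`env1`..`envk`), with a `scenario` attribute.
#' @export
simulate_climate <- function(grid, n_vars = 6, corr_len = 3, seed = 1,
                             scenario = "current") {
  if (corr_len < 1) abort("corr_len must be >= 1")
  if (n_vars < 1) abort("n_vars must be >= 1")
  dims <- grid_dims(grid)
  nx <- dims[["nx"]]; ny <- dims[["ny"]]
  sdk <- corr_len - 1
  kx <- smoothing_matrix(nx, sdk)
  ky <- smoothing_matrix(ny, sdk)
  vals <- with_seed(seed, {
    lapply(seq_len(n_vars), function(v) {
      noise <- matrix(rnorm(nx * ny), nrow = ny, ncol = nx)
      f <- ky %*% noise %*% t(kx)
      z <- as.vector(t(f)) # row-major, matching cell_id order
      as.vector(scale(z))
    })
  })
  out <- tibble(cell_id = grid$cell_id)
  for (v in seq_len(n_vars)) out[[paste0("env", v)]] <- vals[[v]]
  attr(out, "scenario") <- scenario
  out
}

# Row-normalized Gaussian smoothing matrix for one axis; sd = 0 is identity.
smoothing_matrix <- function(n, sd) {
  if (sd <= 0) return(diag(n))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-d^2 / (2 * sd^2))
  k / rowSums(k)
}

#' Project a climate stack into the future
#'
#' Future climate is the current stack plus a constant per-variable shift and
#' small independent cell-level noise, giving deterministic, tunable range
#' shifts without any circulation-model machinery.
#'
#' @param climate A climate tibble from [simulate_climate()].
#' @param shift Numeric vector of per-variable shifts (recycled).
#' @param noise_sd Standard deviation of the added iid noise.
#' @param seed Integer seed.
#' @param scenario Label for the projected stack.
#' @return A climate tibble with the same columns and a new scenario label.
#' @export
shift_climate <- function(climate, shift = 0.5, noise_sd = 0.1, seed = 1,
                          scenario = "future") {
  vars <- climate_vars(climate)
  shift <- rep_len(shift, length(vars))
  out <- climate
  noise <- with_seed(seed, matrix(rnorm(nrow(climate) * length(vars),
                                        sd = noise_sd),
                                  ncol = length(vars)))
  for (i in seq_along(vars)) {
    out[[vars[i]]] <- climate[[vars[i]]] + shift[i] + noise[, i]
  }
  attr(out, "scenario") <- scenario
  out
}

climate_vars <- function(climate) setdiff(names(climate), "cell_id")

#' Simulate species ranges from niches evolving on the tree
#'
#' Each climate variable gets a niche optimum per species, evolved along the
#' phylogeny by a Brownian walk (rate `niche_rate` per unit of relative tree
#' depth), so closely related species have similar niches and therefore
#' spatially correlated ranges — the property that gives phylogenetic
#' diversity its spatial structure. Species-specific niche breadths are drawn
#' log-normally, which produces the right-skewed range-size distributions
#' seen in real floras. A species occupies a cell where its Gaussian
#' suitability is at least `threshold`. Species occupying fewer than
#' `min_occ` cells have their tip optima redrawn up to `max_retries` times
#' and are dropped afterwards; the dropped count is recorded in the
#' `dropped` attribute.
#'
#' @param tree A rooted ultrametric phylogeny (`phylo`) whose tips name the
#'   species.
#' @param climate Climate tibble (one row per cell).
#' @param niche_rate Brownian variance accumulated root-to-tip on a
#'   depth-1-rescaled tree; 0 makes all species share the root optimum (and
#'   hence identical ranges).
#' @param breadth Median niche breadth (climate sd units).
#' @param breadth_sdlog Log-sd of the species breadth distribution.
#' @param threshold Suitability cut-off in (0, 1) for presence.
#' @param min_occ Minimum occupied cells for a species to be retained.
#' @param max_retries Redraws of a tip's optima before the species is dropped.
#' @param seed Integer seed.
#' @return A long tibble (`species`, `cell_id`) of presences, with attributes
#'   `optima` (species x variable matrix) and `dropped` (character vector of
#'   dropped species).
#' @export
simulate_ranges <- function(tree, climate, niche_rate = 1, breadth = 0.9,
                            breadth_sdlog = 0.5, threshold = 0.5,
                            min_occ = 20, max_retries = 10, seed = 1) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0,1)")
  vars <- climate_vars(climate)
  env <- as.matrix(climate[vars])
  seeds <- derive_seeds(seed, 3)

  opt <- brownian_tip_optima(tree, niche_rate, length(vars), seeds[1])
  breadths <- with_seed(seeds[2], {
    stats::rlnorm(length(tree$tip.label), log(breadth), breadth_sdlog)
  })
  names(breadths) <- tree$tip.label

  occupied <- function(o, b) {
    d2 <- rowMeans(sweep(env, 2, o, "-")^2)
    which(exp(-d2 / (2 * b^2)) >= threshold)
  }

  pres <- vector("list", length(tree$tip.label))
  dropped <- character()
  with_seed(seeds[3], {
    for (i in seq_along(tree$tip.label)) {
      sp <- tree$tip.label[i]
      cells <- occupied(opt[i, ], breadths[i])
      tries <- 0
      # redraw this tip's optima around its parent value until viable
      while (length(cells) < min_occ && tries < max_retries) {
        opt[i, ] <- opt[i, ] * 0.5 # pull toward the climate centre (0)
        opt[i, ] <- opt[i, ] + rnorm(ncol(opt), sd = 0.2)
        cells <- occupied(opt[i, ], breadths[i])
        tries <- tries + 1
      }
      if (length(cells) < min_occ) {
        dropped <- c(dropped, sp)
      } else {
        pres[[i]] <- tibble(species = sp, cell_id = climate$cell_id[cells])
      }
    }
  })
  out <- bind_rows(pres)
  attr(out, "optima") <- opt
  attr(out, "dropped") <- dropped
  out
}

# Brownian motion of `k` independent traits along the tree, tips only.
# The tree is rescaled to unit depth so `rate` is the root-to-tip variance.
brownian_tip_optima <- function(tree, rate, k, seed) {
  depth <- max(ape::node.depth.edgelength(tree))
  el <- tree$edge.length / depth
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  vals <- matrix(0, nrow = n_node, ncol = k)
  ord <- rev(ape::postorder(tree)) # parent-before-child edge order
  with_seed(seed, {
    for (e in ord) {
      par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
      vals[chd, ] <- vals[par, ] + rnorm(k, sd = sqrt(rate * el[e]))
    }
  })
  out <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a clustered protected-area mask and a human-modification surface
#'
#' The human-modification index (HMI) is a 0-1 pressure score correlated with
#' a designated climate variable (warm/lowland cells carry more pressure).
#' Protected-area placement emulates the historical bias of reserve systems
#' toward low-pressure land: clusters grow from seed cells with selection
#' weight `exp(-8 * pa_bias * hmi)`, so `pa_bias = 1` puts reserves firmly in
#' low-HMI cells and `pa_bias = 0` places them at random. Selected cells get
#' a PA area fraction in (0.35, 1]; a few unselected cells get nuisance
#' fractions below the 0.3 protection cutoff, so the realized share of
#' protected cells matches `pa_fraction` up to rounding.
#'
#' @param grid Grid tibble.
#' @param climate Climate tibble; its `bias_var` column drives HMI.
#' @param pa_fraction Target share of cells protected, in `[0, 1]`.
#' @param pa_bias Strength of the low-pressure placement bias, in `[0, 1]`.
#' @param bias_var Climate variable correlated with HMI.
#' @param seed Integer seed.
#' @return A tibble `cell_id`, `pa_fraction`, `hmi`.
#' @export
simulate_pa_hmi <- function(grid, climate, pa_fraction = 0.15, pa_bias = 1,
                            bias_var = "env1", seed = 1) {
  if (pa_fraction < 0 || pa_fraction > 1) abort("pa_fraction must be in [0,1]")
  if (pa_bias < 0 || pa_bias > 1) abort("pa_bias must be in [0,1]")
  n <- nrow(grid)
  seeds <- derive_seeds(seed, 2)
  hmi <- with_seed(seeds[1], {
    raw <- 0.75 * climate[[bias_var]] + 0.65 * rnorm(n)
    (rank(raw) - 0.5) / n
  })

  pa <- numeric(n)
  n_prot <- round(pa_fraction * n)
  if (n_prot > 0) {
    sel <- with_seed(seeds[2], {
      grow_clusters(grid, n_prot, weight = exp(-8 * pa_bias * hmi))
    })
    with_seed(seeds[2] + 1L, {
      pa[sel] <- runif(length(sel), 0.35, 1)
      # nuisance sub-threshold fractions outside reserves
      loose <- sample(setdiff(seq_len(n), sel), size = min(n - length(sel),
                                                           round(0.05 * n)))
      pa[loose] <- runif(length(loose), 0, 0.29)
    })
  }
  tibble(cell_id = grid$cell_id, pa_fraction = pa, hmi = hmi)
}

# Grow spatial clusters to `n_sel` cells: start seeds, then repeatedly add a
# weighted draw from the rook-neighbour frontier of the selected set.
grow_clusters <- function(grid, n_sel, weight) {
  dims <- grid_dims(grid)
  nx <- dims[["nx"]]; ny <- dims[["ny"]]
  n <- nx * ny
  neighbours <- function(i) {
    i0 <- i - 1L
    r <- i0 %/% nx; c <- i0 %% nx
    nb <- c(if (c > 0) i - 1L, if (c < nx - 1) i + 1L,
            if (r > 0) i - nx, if (r < ny - 1) i + nx)
    nb
  }
  selected <- logical(n)
  n_seeds <- max(1L, round(n_sel / 25))
  seeds <- sample.int(n, n_seeds, prob = weight)
  selected[seeds] <- TRUE
  while (sum(selected) < n_sel) {
    frontier <- unique(unlist(lapply(which(selected), neighbours)))
    frontier <- frontier[!selected[frontier]]
    if (length(frontier) == 0) {
      pool <- which(!selected)
      pick <- pool[sample.int(length(pool), 1, prob = weight[pool])]
    } else if (length(frontier) == 1) {
      pick <- frontier
    } else {
      pick <- frontier[sample.int(length(frontier), 1,
                                  prob = weight[frontier])]
    }
    selected[pick] <- TRUE
  }
  which(selected)
}

#' Simulate a complete synthetic landscape
#'
#' Convenience wrapper chaining all the generators into the bundle of inputs
#' the downstream analysis expects: grid, current and shifted future climate,
#' a birth-death phylogeny, presence ranges from niches evolving on that
#' tree, and protected-area / human-pressure layers. All randomness flows
#' from the single `seed`.
#'
#' @param config A [pipeline_config()] list (or arguments overriding its
#'   defaults via `...`).
#' @param ... Overrides passed to [pipeline_config()] when `config` is NULL.
#' @return A list with elements `grid`, `climate`, `climate_future`, `tree`,
#'   `presences`, `pa_hmi`, `config`.
#' @export
simulate_landscape <- function(config = NULL, ...) {
  cfg <- config %||% pipeline_config(...)
  seeds <- derive_seeds(cfg$seed, 5)
  grid <- make_grid(cfg$nx, cfg$ny, cfg$cell_km)
  climate <- simulate_climate(grid, cfg$n_env_vars, cfg$corr_len, seeds[1])
  climate_future <- shift_climate(climate, cfg$climate_shift,
                                  cfg$shift_noise_sd, seeds[2])
  tree <- simulate_tree(cfg$n_species, cfg$birth, cfg$death, seeds[3])
  presences <- simulate_ranges(tree, climate,
                               niche_rate = cfg$niche_rate,
                               breadth = cfg$niche_breadth,
                               breadth_sdlog = cfg$breadth_sdlog,
                               threshold = cfg$occupancy_threshold,
                               min_occ = cfg$min_occ, seed = seeds[4])
  kept <- unique(presences$species)
  tree_kept <- if (length(kept) < length(tree$tip.label)) {
    ape::keep.tip(tree, kept)
  } else {
    tree
  }
  pa_hmi <- simulate_pa_hmi(grid, climate, cfg$pa_fraction, cfg$pa_bias,
                            seed = seeds[5])
  list(grid = grid, climate = climate, climate_future = climate_future,
       tree = tree_kept, presences = presences, pa_hmi = pa_hmi, config = cfg)
}
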