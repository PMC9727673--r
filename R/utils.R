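# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive `n` independent sub-seeds from one top-level seed (all < 2^31).
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Euclidean distance matrix between two sets of planar points (km).
cross_dist <- function(x1, y1, x2, y2) {
  sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
}

# Validate that `cells` are all known grid cell ids.
check_cells <- function(cells, grid, what = "layer") {
  bad <- setdiff(unique(cells), grid$cell_id)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s references cell ids absent from the grid: %s",
      what, paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
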