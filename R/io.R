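# Canonical on-disk formats. CSV keyed by the grid's cell_id is the one
# exchange format for per-cell layers; trees travel as Newick. Readers
# validate every cell id against the grid so mixed grids fail loudly.

#' Read / write presence tables
#'
#' Long CSV with columns `species`, `cell_id`. Reading validates cell ids
#' against the grid; round-tripping preserves exact cell sets.
#'
#' @param presences Long tibble `species`, `cell_id`.
#' @param path File path.
#' @param grid Grid tibble used for validation.
#' @return `read_presences()` returns the tibble; writers return the path
#'   invisibly.
#' @export
write_presences <- function(presences, path) {
  readr::write_csv(presences |> select("species", "cell_id"), path)
  invisible(path)
}

#' @rdname write_presences
#' @export
read_presences <- function(path, grid) {
  out <- readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(), cell_id = readr::col_integer()))
  check_cells(out$cell_id, grid, "presence table")
  out
}

#' Read / write per-cell layers
#'
#' CSV with a `cell_id` column and one or more value columns (climate
#' stacks, PA fractions, HMI, PD maps, rank maps all share this shape).
#'
#' @param layer Tibble with a `cell_id` column.
#' @inheritParams write_presences
#' @export
write_cell_layer <- function(layer, path) {
  stopifnot("cell_id" %in% names(layer))
  readr::write_csv(layer, path)
  invisible(path)
}

#' @rdname write_cell_layer
#' @export
read_cell_layer <- function(path, grid) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out$cell_id <- as.integer(out$cell_id)
  check_cells(out$cell_id, grid, "cell layer")
  out
}

#' Read / write phylogenies as Newick
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; topology
#' and branch lengths round-trip to printed precision.
#'
#' @param tree An [ape::phylo].
#' @param path File path.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' @rdname write_phylogeny
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort("malformed Newick file")
  tree
}
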