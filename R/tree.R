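#' Simulate a birth-death phylogeny
#'
#' Draws a rooted, binary, ultrametric tree with `n_species` tips under a
#' constant-rate birth-death process. Tip labels are `sp0001`, `sp0002`, ...
#'
#' @param n_species Number of tips (>= 2).
#' @param birth,death Speciation and extinction rates; `birth > death >= 0`.
#' @param seed Integer seed; the same seed yields an identical Newick string.
#' @return An [ape::phylo] object.
#' @export
simulate_tree <- function(n_species, birth = 1, death = 0, seed = 1) {
  if (n_species < 2) abort("n_species must be >= 2")
  if (!(birth > death && death >= 0)) abort("need birth > death >= 0")
  tree <- with_seed(seed, ape::rphylo(n_species, birth, death))
  tree$tip.label <- sprintf("sp%04d", seq_len(n_species))
  tree
}

#' Graft species onto a genus-level backbone and resolve polytomies
#'
#' Expands each genus tip of a dated backbone phylogeny into a clade holding
#' that genus's species. Within-genus topology and node heights are drawn
#' from a birth-death process whose crown depth is placed uniformly inside
#' the genus terminal branch, so the backbone's ultrametricity is preserved
#' and every new branch has positive length. Singleton genera are renamed in
#' place. Species whose genus is not a backbone tip are excluded and listed
#' in the `unplaced` attribute.
#'
#' @param backbone Genus-level ultrametric [ape::phylo]; tip labels are
#'   genus names.
#' @param membership A data frame with columns `species` and `genus`.
#' @param birth,death Rates of the resolving birth-death process.
#' @param crown_range Range (fractions of the genus branch length) in which
#'   the genus crown depth is drawn uniformly.
#' @param seed Integer seed; resolution is fully reproducible.
#' @return A species-level binary [ape::phylo] with attribute `unplaced`.
#' @export
graft_and_resolve <- function(backbone, membership, birth = 1, death = 0,
                              crown_range = c(0.2, 0.8), seed = 1) {
  stopifnot(is.data.frame(membership),
            all(c("species", "genus") %in% names(membership)))
  known <- membership$genus %in% backbone$tip.label
  if (any(!known)) {
    warn(sprintf("excluding %d species with genera missing from the backbone: %s",
                 sum(!known),
                 paste(head(membership$species[!known], 5), collapse = ", ")))
  }
  placed <- membership[known, , drop = FALSE]
  genera <- split(placed$species, placed$genus)
  empty <- setdiff(backbone$tip.label, names(genera))

  tree <- backbone
  sub_seeds <- derive_seeds(seed, length(genera) + 1L)
  i <- 0L
  for (genus in names(genera)) {
    i <- i + 1L
    spp <- genera[[genus]]
    tip <- which(tree$tip.label == genus)
    if (length(spp) == 1) {
      tree$tip.label[tip] <- spp
      next
    }
    stem <- tree$edge.length[tree$edge[, 2] == tip]
    sub <- with_seed(sub_seeds[i], {
      s <- ape::rphylo(length(spp), birth, death)
      d <- runif(1, crown_range[1], crown_range[2]) * stem
      s$edge.length <- s$edge.length * d / max(ape::node.depth.edgelength(s))
      attr(s, "crown") <- d
      s
    })
    sub$tip.label <- spp
    tree <- ape::bind.tree(tree, sub, where = tip, position = attr(sub, "crown"))
    tree <- ape::drop.tip(tree, genus)
  }
  if (length(empty) > 0) tree <- ape::drop.tip(tree, empty)
  attr(tree, "unplaced") <- membership$species[!known]
  tree
}
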