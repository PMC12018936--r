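# Strict and reduced consensus of rooted trees, and compatibility of a tree
# with a molecular scaffold (backbone constraint over the extant taxa).

## non-trivial rooted clades of a tree as canonical "a|b|c" keys
.clade_keys <- function(tree) {
  .check_phylo(tree)
  n_tip <- length(tree$tip.label)
  if (n_tip < 3L || is.null(tree$edge)) return(character(0))
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx)
    paste(sort(tree$tip.label[idx]), collapse = "|"), character(1))
  sizes <- lengths(pp)
  unique(keys[sizes >= 2L & sizes < n_tip])
}

.as_tree_list <- function(trees) {
  if (.is_phylo(trees)) trees <- list(trees)
  if (!length(trees) || !all(vapply(trees, .is_phylo, logical(1))))
    .stopf("`trees` must be one or more \"phylo\" objects")
  trees
}

#' Strict consensus of rooted trees
#'
#' The tree containing exactly the clades present in every input tree.
#'
#' @param trees a `multiPhylo` object or list of rooted `phylo` trees on an
#'   identical taxon set.
#' @return a `phylo` object.
#' @export
strict_consensus <- function(trees) {
  trees <- .as_tree_list(trees)
  tips <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(tips, paste, character(1), collapse = "|"))) > 1L)
    .stopf("trees are not on the same taxon set")
  if (length(trees) == 1L) return(trees[[1]])
  ape::consensus(trees, p = 1, rooted = TRUE)
}

#' Reduced (pruned) strict consensus
#'
#' Deletes the given rogue taxa from every input tree (suppressing the
#' resulting degree-2 nodes) and returns the strict consensus of the pruned
#' trees. Pruning unstable taxa in this way can reveal resolution that they
#' destroy in the plain strict consensus.
#'
#' @inheritParams strict_consensus
#' @param prune character vector of taxa to drop; must leave at least two.
#' @return a `phylo` object.
#' @export
reduced_consensus <- function(trees, prune = character(0)) {
  trees <- .as_tree_list(trees)
  common <- trees[[1]]$tip.label
  if (length(setdiff(common, prune)) < 2L)
    .stopf("pruning would leave fewer than 2 taxa")
  if (length(prune))
    trees <- lapply(trees, ape::drop.tip, tip = prune)
  strict_consensus(trees)
}

#' Does a tree satisfy a backbone (scaffold) constraint?
#'
#' A molecular scaffold fixes the relationships of a constrained taxon
#' subset (in practice the extant species, from molecular topologies) while
#' the remaining "floating" taxa may attach anywhere. A tree satisfies the
#' scaffold when its restriction to the constrained taxa refines or equals
#' the backbone, i.e. contains every backbone clade.
#'
#' @param tree a rooted `phylo` whose tips include the backbone's taxa.
#' @param backbone a rooted `phylo` over the constrained taxa, or `NULL`
#'   (no constraint, always satisfied).
#' @return logical.
#' @export
satisfies_scaffold <- function(tree, backbone) {
  .check_phylo(tree)
  if (is.null(backbone)) return(TRUE)
  .check_phylo(backbone)
  constrained <- backbone$tip.label
  miss <- setdiff(constrained, tree$tip.label)
  if (length(miss))
    .stopf("constrained taxa absent from tree: %s", paste(miss, collapse = ", "))
  want <- .clade_keys(backbone)
  if (!length(want)) return(TRUE)
  restricted <- ape::keep.tip(tree, constrained)
  all(want %in% .clade_keys(restricted))
}

## scaffold restricted to the taxa already present in a partial tree (used
## during stepwise addition); NULL when fewer than 3 constrained taxa remain
.restrict_backbone <- function(backbone, taxa) {
  if (is.null(backbone)) return(NULL)
  keep <- intersect(backbone$tip.label, taxa)
  if (length(keep) < 3L) return(NULL)
  ape::keep.tip(backbone, keep)
}
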