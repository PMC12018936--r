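# Heuristic maximum-parsimony tree search: random-addition starting trees
# honouring the scaffold constraint, then NNI or SPR hill climbing that only
# accepts constraint-satisfying neighbours. Deliberately a simple,
# reproducible desk-scale search, not a re-implementation of the "new
# technology" heuristics used for very large matrices.
#
# Internally trees are rooted nested lists: a leaf is a taxon name, an
# internal node a two-element list. The designated outgroup is held as one
# child of the root throughout, so clades are comparable in rooted terms.

.nl_is_leaf <- function(x) is.character(x)

.nl_tips <- function(x) {
  if (.nl_is_leaf(x)) return(x)
  c(.nl_tips(x[[1]]), .nl_tips(x[[2]]))
}

## canonical newick (children sorted), used for deduplication and tie-breaks
.nl_canon <- function(x) {
  if (.nl_is_leaf(x)) return(x)
  a <- .nl_canon(x[[1]]); b <- .nl_canon(x[[2]])
  if (a <= b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
}

## paths (integer vectors of child indices) to every node, root first
.nl_paths <- function(x, prefix = integer(0)) {
  out <- list(prefix)
  if (!.nl_is_leaf(x))
    out <- c(out, .nl_paths(x[[1]], c(prefix, 1L)),
             .nl_paths(x[[2]], c(prefix, 2L)))
  out
}

.nl_get <- function(x, path) {
  for (i in path) x <- x[[i]]
  x
}

.nl_set <- function(x, path, value) {
  if (!length(path)) return(value)
  x[[path[1]]] <- .nl_set(x[[path[1]]], path[-1], value)
  x
}

## attach `sub` next to the node at `path`
.nl_insert <- function(x, path, sub) {
  node <- .nl_get(x, path)
  .nl_set(x, path, list(node, sub))
}

## remove the subtree at `path` (not the root); its sibling replaces the parent
.nl_remove <- function(x, path) {
  stopifnot(length(path) >= 1L)
  parent_path <- path[-length(path)]
  parent <- .nl_get(x, parent_path)
  sibling <- parent[[3L - path[length(path)]]]
  .nl_set(x, parent_path, sibling)
}

.nl_to_phylo <- function(x) {
  ape::read.tree(text = paste0(.nl_canon(x), ";"))
}

.spr_neighbours <- function(core) {
  if (.nl_is_leaf(core)) return(list())
  out <- list()
  for (p in .nl_paths(core)) {
    if (!length(p)) next                       # cannot prune the root
    sub <- .nl_get(core, p)
    rest <- .nl_remove(core, p)
    for (q in .nl_paths(rest))
      out[[length(out) + 1L]] <- .nl_insert(rest, q, sub)
  }
  out
}

.nni_neighbours <- function(core) {
  out <- list()
  for (p in .nl_paths(core)) {
    if (!length(p)) next
    node <- .nl_get(core, p)
    if (.nl_is_leaf(node)) next
    parent_path <- p[-length(p)]
    parent <- .nl_get(core, parent_path)
    sibling <- parent[[3L - p[length(p)]]]
    for (i in 1:2) {
      swapped <- list(list(node[[3L - i]], sibling), node[[i]])
      out[[length(out) + 1L]] <- .nl_set(core, parent_path, swapped)
    }
  }
  out
}

#' Search configuration
#'
#' @param n_replicates number of random-addition replicates.
#' @param rearrangement `"SPR"` (default) or `"NNI"` hill climbing.
#' @param max_trees maximum number of equally best trees retained.
#' @param seed integer seed (mandatory; the search is deterministic given it).
#' @param outgroup taxon used to root the search trees; defaults to the
#'   matrix's first taxon.
#' @return a list of class `search_config`.
#' @export
search_config <- function(n_replicates = 10L, rearrangement = c("SPR", "NNI"),
                          max_trees = 100L, seed, outgroup = NULL) {
  rearrangement <- match.arg(rearrangement)
  if (missing(seed)) .stopf("`seed` is mandatory")
  stopifnot(n_replicates >= 1L, max_trees >= 1L)
  structure(list(n_replicates = as.integer(n_replicates),
                 rearrangement = rearrangement,
                 max_trees = as.integer(max_trees),
                 seed = as.integer(seed), outgroup = outgroup),
            class = "search_config")
}

#' Heuristic parsimony search under a scaffold constraint
#'
#' Builds random-addition starting trees that honour the backbone
#' constraint, hill-climbs by NNI or SPR accepting only
#' constraint-satisfying neighbours, and pools all distinct best-length
#' trees across replicates. Ties during climbing are broken by canonical
#' (lexicographic) newick order so runs are reproducible given the seed.
#'
#' @param cm a [character_matrix()].
#' @param backbone optional rooted `phylo` scaffold over a taxon subset.
#' @param config a [search_config()].
#' @return a list of `phylo` trees (class `multiPhylo`) with attributes
#'   `"length"` (best length found) and `"n_evaluated"`.
#' @export
heuristic_search <- function(cm, backbone = NULL, config) {
  stopifnot(inherits(cm, "character_matrix"), inherits(config, "search_config"))
  taxa <- cm$taxa
  if (length(taxa) < 3L) .stopf("need at least 3 taxa to search")
  if (!is.null(backbone)) {
    bad <- setdiff(backbone$tip.label, taxa)
    if (length(bad))
      .stopf("backbone taxa absent from matrix: %s", paste(bad, collapse = ", "))
  }
  outgroup <- config$outgroup %||% taxa[1]
  if (!outgroup %in% taxa) .stopf("outgroup %s not in matrix", outgroup)
  others <- setdiff(taxa, outgroup)

  memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(core) {
    key <- .nl_canon(core)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    full <- .nl_to_phylo(list(outgroup, core))
    bb <- .restrict_backbone(backbone, full$tip.label)
    val <- if (!is.null(bb) && !satisfies_scaffold(full, bb)) Inf
           else tree_length(full, cm)
    n_eval <<- n_eval + 1L
    memo[[key]] <- val
    val
  }

  set.seed(config$seed)
  best_len <- Inf
  pool <- list()    # canonical string -> core
  add_to_pool <- function(core, len) {
    if (len > best_len) return()
    if (len < best_len) { best_len <<- len; pool <<- list() }
    pool[[.nl_canon(core)]] <<- core
  }

  for (rep in seq_len(config$n_replicates)) {
    ord <- if (length(others) > 1L) sample(others) else others
    core <- ord[1]
    ok <- TRUE
    for (tx in ord[-1]) {
      cands <- lapply(.nl_paths(core), function(p) .nl_insert(core, p, tx))
      lens <- vapply(cands, score, numeric(1))
      if (!any(is.finite(lens))) {
        ok <- FALSE
        break
      }
      best <- which(lens == min(lens))
      if (length(best) > 1L)
        best <- best[order(vapply(cands[best], .nl_canon, character(1)))[1]]
      core <- cands[[best]]
    }
    if (!ok)
      .stopf("no constraint-satisfying placement found during addition")
    cur <- score(core)
    repeat {
      nbs <- switch(config$rearrangement,
                    SPR = .spr_neighbours(core),
                    NNI = .nni_neighbours(core))
      if (!length(nbs)) {
        add_to_pool(core, cur)
        break
      }
      lens <- vapply(nbs, score, numeric(1))
      if (min(lens) < cur) {
        best <- which(lens == min(lens))
        if (length(best) > 1L)
          best <- best[order(vapply(nbs[best], .nl_canon, character(1)))[1]]
        core <- nbs[[best]]
        cur <- min(lens)
      } else {
        add_to_pool(core, cur)
        for (i in which(lens == cur)) add_to_pool(nbs[[i]], cur)
        break
      }
    }
  }

  keys <- sort(names(pool))
  if (length(keys) > config$max_trees) keys <- keys[seq_len(config$max_trees)]
  trees <- lapply(keys, function(k) .nl_to_phylo(list(outgroup, pool[[k]])))
  class(trees) <- "multiPhylo"
  attr(trees, "length") <- as.integer(best_len)
  attr(trees, "n_evaluated") <- n_eval
  trees
}

#' Enumerate all tree topologies on a taxon set
#'
#' Generates every unrooted binary topology, represented rooted on the
#' given outgroup, by recursive stepwise addition. `(2n-5)!!` trees for `n`
#' taxa; guarded against large `n`. Used as the exhaustive reference for
#' [heuristic_search()] on small problems.
#'
#' @param taxa character vector of taxon names (>= 3).
#' @param outgroup taxon to root on; defaults to the first.
#' @param max_trees guard on the number of topologies generated.
#' @return a `multiPhylo` list of trees.
#' @export
enumerate_topologies <- function(taxa, outgroup = taxa[1], max_trees = 20000L) {
  stopifnot(length(taxa) >= 3L, outgroup %in% taxa)
  others <- setdiff(taxa, outgroup)
  n_expected <- prod(seq(3, by = 2, length.out = max(0L, length(others) - 2L)))
  if (n_expected > max_trees)
    .stopf("%d taxa give %g topologies; raise max_trees deliberately",
           length(taxa), n_expected)
  cores <- list(others[1])
  for (tx in others[-1]) {
    cores <- unlist(lapply(cores, function(core)
      lapply(.nl_paths(core), function(p) .nl_insert(core, p, tx))),
      recursive = FALSE)
  }
  trees <- lapply(cores, function(core) .nl_to_phylo(list(outgroup, core)))
  class(trees) <- "multiPhylo"
  trees
}
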