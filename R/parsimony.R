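# Parsimony scoring on discrete morphological characters. Ordered
# (morphocline) characters are costed as Wagner characters, cost |i - j|
# along the integer cline; unordered characters as Fitch characters, cost 1
# between distinct states. Both are scored with the Sankoff dynamic
# programme, which handles polytomies and ambiguity sets at tips directly.

## state universe per character: observed states for unordered characters,
## the full integer cline min..max for ordered ones (intermediate unobserved
## states are legal ancestral states on a morphocline)
.char_universe <- function(cm, ordered) {
  lapply(seq_len(cm$n_chars), function(j) {
    obs <- sort(unique(unlist(cm$cells[, j])))
    if (length(obs) < 2L) return(obs)
    if (ordered[j]) seq.int(min(obs), max(obs)) else obs
  })
}

.step_matrix <- function(universe, ordered) {
  k <- length(universe)
  if (ordered) abs(outer(universe, universe, "-")) + 0
  else matrix(1, k, k) - diag(k)
}

## tip-state cost vector: 0 on members of the ambiguity set, Inf elsewhere;
## missing cells cost 0 everywhere (they contribute nothing)
.tip_costs <- function(members, universe) {
  if (!length(members)) return(numeric(length(universe)))
  v <- rep(Inf, length(universe))
  v[match(members, universe)] <- 0
  v
}

.check_tips_in_matrix <- function(tree, cm) {
  miss <- setdiff(tree$tip.label, cm$taxa)
  if (length(miss))
    .stopf("tip(s) absent from matrix: %s", paste(miss, collapse = ", "))
}

## min_t (S[t, s] + v[t]) for every column of the k x m cost matrix
.sankoff_transition <- function(S, M) {
  k <- nrow(S)
  out <- matrix(Inf, k, ncol(M))
  for (s in seq_len(k)) {
    acc <- S[1, s] + M[1, ]
    if (k > 1L) for (t in 2:k) acc <- pmin(acc, S[t, s] + M[t, ])
    out[s, ] <- acc
  }
  out
}

#' Parsimony length of a tree
#'
#' Minimum total character-change cost of `tree` for the matrix, summed over
#' characters, computed by the Sankoff downpass. Polytomies are scored as
#' hard polytomies; ambiguity sets at tips cost 0 on their member states;
#' missing cells contribute zero on any tree.
#'
#' @param tree a rooted `phylo` object whose tips are a subset of the
#'   matrix's taxa.
#' @param cm a [character_matrix()].
#' @param ordered optional logical vector overriding the matrix's ordered
#'   flags.
#' @return integer tree length.
#' @seealso [mpr_states()], [enumerate_parsimony()]
#' @export
tree_length <- function(tree, cm, ordered = NULL) {
  .check_phylo(tree)
  stopifnot(inherits(cm, "character_matrix"))
  .check_tips_in_matrix(tree, cm)
  ordered <- ordered %||% cm$ordered
  uni <- .char_universe(cm, ordered)
  keep <- which(lengths(uni) >= 2L)
  if (!length(keep)) return(0L)

  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_all <- n_tip + tr$Nnode
  row_of <- match(tr$tip.label, cm$taxa)
  root <- tr$edge[nrow(tr$edge), 1]

  key <- vapply(keep, function(j)
    paste(ordered[j], paste(uni[[j]], collapse = ","), sep = "|"), character(1))
  total <- 0
  for (grp in split(keep, key)) {
    u <- uni[[grp[1]]]
    k <- length(u)
    m <- length(grp)
    S <- .step_matrix(u, ordered[grp[1]])
    D <- array(0, dim = c(k, m, n_all))
    for (i in seq_len(n_tip))
      D[, , i] <- vapply(grp, function(j)
        .tip_costs(cm$cells[[row_of[i], j]], u), numeric(k))
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      D[, , p] <- D[, , p] +
        .sankoff_transition(S, matrix(D[, , ch], k, m))
    }
    total <- total + sum(apply(matrix(D[, , root], k, m), 2, min))
  }
  as.integer(round(total))
}

#' Most-parsimonious ancestral state sets (MPR) for one character
#'
#' For every node of the tree, the full set of states that the node takes in
#' at least one minimum-cost labeling (no ACCTRAN/DELTRAN resolution).
#' Computed by a Sankoff down-pass plus an up-pass giving the cost of the
#' rest of the tree conditional on each node state.
#'
#' @inheritParams tree_length
#' @param char_index character to reconstruct (1-based column).
#' @return an `ancestral_state_map`: a named list of integer state vectors,
#'   tips named by their labels and internal nodes `"N<ape id>"`, with the
#'   minimum length as attribute `"length"`.
#' @export
mpr_states <- function(tree, cm, char_index = 1L, ordered = NULL) {
  .check_phylo(tree)
  stopifnot(inherits(cm, "character_matrix"))
  .check_tips_in_matrix(tree, cm)
  if (char_index < 1L || char_index > cm$n_chars)
    .stopf("char_index out of range")
  ordered <- ordered %||% cm$ordered
  u <- .char_universe(cm, ordered)[[char_index]]
  if (!length(u))
    .stopf("character %d has no observed states", char_index)

  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_all <- n_tip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  node_names <- c(tr$tip.label, paste0("N", (n_tip + 1):n_all))
  row_of <- match(tr$tip.label, cm$taxa)
  k <- length(u)

  if (k == 1L) {
    res <- rep(list(u), n_all)
    names(res) <- node_names
    ## tips that are missing still "take" the only observed state set;
    ## keep their observed (possibly empty) sets
    for (i in seq_len(n_tip)) {
      obs <- cm$cells[[row_of[i], char_index]]
      res[[i]] <- if (length(obs)) obs else u
    }
    return(structure(res, length = 0L, class = "ancestral_state_map"))
  }

  S <- .step_matrix(u, ordered[char_index])
  D <- matrix(0, k, n_all)        # downpass subtree costs
  for (i in seq_len(n_tip))
    D[, i] <- .tip_costs(cm$cells[[row_of[i], char_index]], u)
  Tm <- matrix(0, k, n_all)       # per-child transition cost into its parent
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    Tm[, ch] <- .sankoff_transition(S, matrix(D[, ch], k, 1))
    D[, p] <- D[, p] + Tm[, ch]
  }
  L <- min(D[, root])

  U <- matrix(Inf, k, n_all)      # cost of the rest of the tree given state
  U[, root] <- 0
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    ctx <- U[, p] + D[, p] - Tm[, ch]    # parent context excluding this child
    U[, ch] <- .sankoff_transition(S, matrix(ctx, k, 1))
  }

  tol <- 1e-9
  res <- lapply(seq_len(n_all), function(v)
    u[D[, v] + U[, v] <= L + tol])
  names(res) <- node_names
  structure(res, length = as.integer(round(L)), class = "ancestral_state_map")
}

#' @export
print.ancestral_state_map <- function(x, ...) {
  cat(sprintf("Ancestral state map over %d nodes (minimum length %d)\n",
              length(x), attr(x, "length")))
  shown <- utils::head(seq_along(x), 10L)
  for (i in shown)
    cat(sprintf("  %s: {%s}\n", names(x)[i], paste(x[[i]], collapse = ",")))
  if (length(x) > 10L) cat(sprintf("  ... and %d more\n", length(x) - 10L))
  invisible(x)
}

#' Exact parsimony by exhaustive labeling enumeration
#'
#' Independent brute-force reference for [tree_length()] and [mpr_states()]:
#' enumerates every assignment of states to internal nodes (and every member
#' of each tip ambiguity set) and minimises the summed step-matrix cost.
#' Only feasible for small trees; intended for validation.
#'
#' @inheritParams tree_length
#' @param max_labelings guard on the enumeration size.
#' @return list with elements `length` (integer) and `mpr` (list, one named
#'   state-set list per character in the same layout as [mpr_states()]).
#' @export
enumerate_parsimony <- function(tree, cm, ordered = NULL,
                                max_labelings = 3e5) {
  .check_phylo(tree)
  .check_tips_in_matrix(tree, cm)
  ordered <- ordered %||% cm$ordered
  uni <- .char_universe(cm, ordered)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_all <- n_tip + tr$Nnode
  node_names <- c(tr$tip.label, paste0("N", (n_tip + 1):n_all))
  row_of <- match(tr$tip.label, cm$taxa)
  internal <- (n_tip + 1):n_all
  parent_of <- integer(n_all)
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]

  total <- 0L
  mpr <- vector("list", cm$n_chars)
  for (j in seq_len(cm$n_chars)) {
    u <- uni[[j]]
    k <- length(u)
    if (k == 0L) {
      mpr[[j]] <- NULL
      next
    }
    if (k^length(internal) > max_labelings)
      .stopf("enumeration too large (%d^%d labelings)", k, length(internal))
    lab <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
    S <- .step_matrix(u, ordered[j])
    cost <- numeric(nrow(lab))
    col_of <- function(node) lab[, match(node, internal)]
    ## internal-internal edges (root has no parent)
    for (nd in internal) {
      p <- parent_of[nd]
      if (p == 0L) next
      cost <- cost + S[cbind(col_of(p), col_of(nd))]
    }
    ## tip edges: tips take their best member given the parent state
    tip_contrib <- vector("list", n_tip)
    for (i in seq_len(n_tip)) {
      members <- cm$cells[[row_of[i], j]]
      p <- parent_of[i]
      if (!length(members)) { tip_contrib[[i]] <- numeric(nrow(lab)); next }
      mi <- match(members, u)
      best <- apply(S[, mi, drop = FALSE], 1, min)   # per parent state
      tip_contrib[[i]] <- best[col_of(p)]
      cost <- cost + tip_contrib[[i]]
    }
    L <- min(cost)
    total <- total + as.integer(round(L))
    sets <- vector("list", n_all)
    tol <- 1e-9
    for (nd in internal)
      sets[[nd]] <- u[sort(unique(col_of(nd)[cost <= L + tol]))]
    for (i in seq_len(n_tip)) {
      members <- cm$cells[[row_of[i], j]]
      if (!length(members)) {
        ## a missing tip can take, at zero cost, any state its parent takes
        ## in some minimum labeling
        sets[[i]] <- sets[[parent_of[i]]]
        next
      }
      p <- parent_of[i]
      keepm <- vapply(members, function(mm) {
        alt <- cost - tip_contrib[[i]] + S[cbind(col_of(p), match(mm, u))]
        min(alt) <= L + tol
      }, logical(1))
      sets[[i]] <- members[keepm]
    }
    names(sets) <- node_names
    mpr[[j]] <- sets
  }
  list(length = total, mpr = mpr)
}
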