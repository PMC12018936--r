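# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code under fixed seeds; nothing is stored.

## random small parsimony instance (tree without branch lengths + matrix
## with missing data and polymorphism)
rand_parsimony_instance <- function(n_taxa = sample(4:8, 1),
                                    n_chars = sample(2:6, 1),
                                    n_states = sample(2:4, 1),
                                    p_missing = 0.15, p_poly = 0.15) {
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  tr <- ape::rtree(n_taxa, tip.label = taxa)
  tr$edge.length <- NULL
  cells <- matrix(vector("list", n_taxa * n_chars), n_taxa, n_chars)
  for (i in seq_len(n_taxa)) for (j in seq_len(n_chars)) {
    r <- runif(1)
    cells[[i, j]] <-
      if (r < p_missing) integer(0)
      else if (r < p_missing + p_poly && n_states > 1)
        sort(sample(0:(n_states - 1), 2))
      else sample(0:(n_states - 1), 1)
  }
  rownames(cells) <- taxa
  list(tree = tr,
       cm = character_matrix(cells, ordered = runif(n_chars) < 0.5))
}

## random matrix (no tree) over given taxa, single states only
rand_matrix <- function(taxa, n_chars, n_states = 3, p_missing = 0) {
  cells <- matrix(vector("list", length(taxa) * n_chars),
                  length(taxa), n_chars)
  for (i in seq_along(taxa)) for (j in seq_len(n_chars))
    cells[[i, j]] <- if (runif(1) < p_missing) integer(0)
                     else sample(0:(n_states - 1), 1)
  rownames(cells) <- taxa
  character_matrix(cells)
}

## independent mbl oracle: order-free fixpoint iteration over the two
## constraints (node >= oldest descendant tip; parent >= child + min)
mbl_fixpoint_ages <- function(topology, tip_age, min_branch) {
  tr <- topology
  n_tip <- length(tr$tip.label)
  n_all <- n_tip + tr$Nnode
  age <- numeric(n_all)
  age[seq_len(n_tip)] <- tip_age[tr$tip.label]
  repeat {
    changed <- FALSE
    for (e in sample(nrow(tr$edge))) {      # deliberate random sweep order
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      lo <- age[ch] + min_branch
      if (age[p] < lo - 1e-12) { age[p] <- lo; changed <- TRUE }
    }
    if (!changed) break
  }
  names(age) <- c(tr$tip.label, paste0("N", (n_tip + 1):n_all))
  age
}

## rooted non-trivial clade sets by plain recursion over the edge matrix,
## independent of the package's internals
clade_key_set <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(nd) {
    if (nd <= n_tip) return(tree$tip.label[nd])
    unlist(lapply(kids[[as.character(nd)]], desc))
  }
  keys <- character(0)
  for (nd in (n_tip + 1):(n_tip + tree$Nnode)) {
    tips <- desc(nd)
    if (length(tips) >= 2 && length(tips) < n_tip)
      keys <- c(keys, paste(sort(tips), collapse = "|"))
  }
  unique(keys)
}

## independent multivariate-normal log-likelihood for lambda grid searches
mvn_loglik <- function(y, mu, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}
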