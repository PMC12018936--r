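`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_phylo <- function(x) inherits(x, "phylo")

.check_phylo <- function(tree, arg = "tree") {
  if (!.is_phylo(tree)) .stopf("`%s` must be an ape \"phylo\" object", arg)
  invisible(tree)
}

## effective sample size of an MCMC draw vector from the initial monotone
## positive sequence of autocorrelations
.ess <- function(x) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 100L), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  max(1, n / (1 + 2 * sum(rho)))
}

## lambda-scaled phylogenetic correlation structure: vcv of the time tree,
## scaled so the deepest tip has unit variance, with off-diagonals multiplied
## by lambda (Pagel transform)
.phylo_corr <- function(tree, lambda = 1, taxa = NULL) {
  .check_phylo(tree)
  if (is.null(tree$edge.length))
    .stopf("tree has no branch lengths; calibrate it first")
  C <- ape::vcv.phylo(tree)
  C <- C / max(diag(C))
  if (lambda != 1) {
    d <- diag(C)
    C <- C * lambda
    diag(C) <- d
  }
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(C))
    if (length(missing))
      .stopf("taxa absent from tree: %s", paste(missing, collapse = ", "))
    C <- C[taxa, taxa, drop = FALSE]
  }
  C
}
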