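# Synthetic data with the statistical structure the pipeline assumes:
# birth-death time trees with extinct tips, Mk-type discrete characters
# (ordered characters evolve as stepwise chains on the integer cline), and
# log-log HW -> TL allometry with Brownian-motion residuals of known lambda
# and sigma2. Each component draws from its own stream derived from the
# master seed, so adding draws to one component does not perturb the others.

#' Simulation configuration
#'
#' Defaults describe a desk-scale crocodyliform-like study: a few dozen taxa
#' with both fossil and extant tips, a morphological matrix with a fifth of
#' the characters ordered and a realistic fraction of missing cells, and a
#' near-isometric HW -> TL allometry (slope 1, intercept 0.9, i.e. TL about
#' 8 x HW) with strong phylogenetic signal.
#'
#' @param n_taxa total number of tips (extinct + extant).
#' @param n_chars number of discrete characters.
#' @param n_states states per character.
#' @param prop_ordered proportion of ordered (morphocline) characters.
#' @param rate substitution rate per Myr per character.
#' @param birth,death speciation/extinction rates per lineage per Myr.
#' @param slope,intercept,sigma2,lambda allometry truth on the log10 scale:
#'   `log10 TL = intercept + slope * log10 HW + phylogenetic residual`, with
#'   residual variance `sigma2` at the deepest tip and Pagel's `lambda`.
#' @param hw_range head-width range in cm (log-uniform draws).
#' @param prop_fossil proportion of tips treated as fossils (TL withheld).
#' @param n_specimens extant specimens measured per taxon.
#' @param missing_fraction fraction of matrix cells masked as missing.
#' @param seed master integer seed (mandatory).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 24L, n_chars = 60L, n_states = 3L,
                       prop_ordered = 0.2, rate = 0.02,
                       birth = 0.06, death = 0.03,
                       slope = 1, intercept = 0.9, sigma2 = 0.01,
                       lambda = 0.9, hw_range = c(10, 60),
                       prop_fossil = 0.3, n_specimens = 3L,
                       missing_fraction = 0.25, seed) {
  if (missing(seed)) .stopf("`seed` is mandatory")
  stopifnot(n_taxa >= 2L, n_chars >= 1L, n_states >= 1L,
            prop_ordered >= 0, prop_ordered <= 1,
            rate >= 0, birth >= 0, death >= 0, sigma2 >= 0,
            lambda >= 0, lambda <= 1, hw_range[1] > 0,
            hw_range[2] >= hw_range[1],
            missing_fraction >= 0, missing_fraction < 1,
            prop_fossil >= 0, prop_fossil < 1)
  structure(as.list(environment()), class = "sim_config")
}

## substream seeds below 2^31, derived from the master seed
.substream <- function(seed, k) (as.integer(seed) * 13L + k * 7919L) %% 2000000011L %% .Machine$integer.max

#' Simulate a birth-death time tree with extinct and extant tips
#'
#' Forward Gillespie simulation of a constant-rate birth-death process,
#' stopped when the total number of tips (extinct plus surviving) reaches
#' `n_taxa`. Extinct tips receive point ages (FAD = LAD) at their
#' extinction time; surviving tips have age 0. Retries (up to 100 times)
#' when the clade dies out too early.
#'
#' @param config a [sim_config()].
#' @return list with `tree` (calibrated `phylo`, durations in Myr,
#'   `$root.time` set) and `ages` (data frame `taxon`, `fad`, `lad`).
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream(config$seed, 1L))
  n <- config$n_taxa
  for (attempt in 1:100) {
    res <- .sim_bd_once(n, config$birth, config$death)
    if (!is.null(res)) break
    res <- NULL
  }
  if (is.null(res)) .stopf("clade died out in 100 attempts; raise birth rate")
  res
}

.sim_bd_once <- function(n, birth, death) {
  ## nodes: parent, birth time; alive lineages are open tips
  parent <- c(NA_integer_, 1L, 1L)
  t_start <- c(0, 0, 0)
  t_end <- rep(NA_real_, 3)
  is_tip <- c(FALSE, TRUE, TRUE)
  alive <- c(2L, 3L)
  t <- 0
  n_tips_total <- 2L
  while (n_tips_total < n) {
    if (!length(alive)) return(NULL)
    rate_tot <- length(alive) * (birth + death)
    if (rate_tot == 0) return(NULL)
    t <- t + stats::rexp(1, rate_tot)
    who <- alive[sample.int(length(alive), 1L)]
    if (stats::runif(1) < birth / (birth + death)) {
      ## speciation: `who` becomes internal, two new tips open
      t_end[who] <- t
      is_tip[who] <- FALSE
      for (k in 1:2) {
        parent <- c(parent, who)
        t_start <- c(t_start, t)
        t_end <- c(t_end, NA_real_)
        is_tip <- c(is_tip, TRUE)
      }
      alive <- c(setdiff(alive, who), length(parent) - 1L, length(parent))
      n_tips_total <- n_tips_total + 1L
    } else {
      t_end[who] <- t
      alive <- setdiff(alive, who)
      if (!length(alive)) return(NULL)
    }
  }
  present <- t + stats::rexp(1, length(alive) * birth + 1e-9) # a final beat
  t_end[is.na(t_end)] <- present

  tip_ids <- which(is_tip)
  node_ids <- which(!is_tip)
  tip_no <- stats::setNames(seq_along(tip_ids), tip_ids)
  node_no <- stats::setNames(length(tip_ids) + seq_along(node_ids), node_ids)
  lab <- sprintf("t%02d", seq_along(tip_ids))
  no_of <- function(id) {
    ifelse(is_tip[id], tip_no[as.character(id)], node_no[as.character(id)])
  }
  has_parent <- which(!is.na(parent))
  edge <- cbind(vapply(parent[has_parent], no_of, numeric(1)),
                vapply(has_parent, no_of, numeric(1)))
  edge_len <- t_end[has_parent] - t_start[has_parent]
  tree <- list(edge = matrix(as.integer(edge), ncol = 2),
               edge.length = edge_len, Nnode = length(node_ids),
               tip.label = lab)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "postorder")
  tree$root.time <- present
  age <- present - t_end[tip_ids]
  age[age < 1e-12] <- 0
  list(tree = tree,
       ages = data.frame(taxon = lab, fad = age, lad = age,
                         stringsAsFactors = FALSE))
}

## transition probability matrix of the equal-rates Mk chain; ordered
## characters step only between adjacent states on the cline
.mk_pmatrix <- function(k, rate, ordered, t) {
  if (k == 1L) return(matrix(1, 1, 1))
  if (ordered) {
    Q <- matrix(0, k, k)
    for (i in seq_len(k - 1)) {
      Q[i, i + 1] <- rate
      Q[i + 1, i] <- rate
    }
  } else {
    Q <- matrix(rate, k, k)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  eg <- eigen(Q, symmetric = TRUE)
  P <- eg$vectors %*% (exp(eg$values * t) * t(eg$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate an Mk-type character matrix on a tree
#'
#' Evolves each character along the tree's branches by a continuous-time
#' Markov chain with equal exchange rates; ordered characters are restricted
#' to adjacent-state steps on the integer cline (matching the Wagner cost
#' assumption). Root states are uniform. A missing-data mask is applied
#' uniformly at random.
#'
#' @param tree calibrated `phylo` with branch durations.
#' @param config a [sim_config()].
#' @return a [character_matrix()].
#' @export
simulate_matrix <- function(tree, config) {
  .check_phylo(tree)
  stopifnot(inherits(config, "sim_config"))
  if (config$n_states < 1L) .stopf("need at least one state")
  if (is.null(tree$edge.length)) .stopf("tree needs branch durations")
  set.seed(.substream(config$seed, 2L))
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  k <- config$n_states
  m <- config$n_chars
  ordered <- seq_len(m) <= round(config$prop_ordered * m)
  ## one preorder sweep; transition matrices cached per branch length
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- matrix(NA_integer_, n_all, m)
  root <- tr$edge[nrow(tr$edge), 1]
  states[root, ] <- sample.int(k, m, replace = TRUE)
  P_cache <- list(ordered = list(), unordered = list())
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    len <- tr$edge.length[e]
    key <- sprintf("%.9g", len)
    for (grp in c(TRUE, FALSE)) {
      slot <- if (grp) "ordered" else "unordered"
      if (is.null(P_cache[[slot]][[key]]))
        P_cache[[slot]][[key]] <- .mk_pmatrix(k, config$rate, grp, len)
    }
    for (j in seq_len(m)) {
      P <- P_cache[[if (ordered[j]) "ordered" else "unordered"]][[key]]
      states[ch, j] <- sample.int(k, 1L, prob = P[states[p, j], ])
    }
  }
  tip_states <- states[seq_len(n_tip), , drop = FALSE] - 1L
  mask <- matrix(stats::runif(n_tip * m) < config$missing_fraction, n_tip, m)
  cells <- matrix(vector("list", n_tip * m), n_tip, m)
  for (i in seq_len(n_tip)) for (j in seq_len(m))
    cells[[i, j]] <- if (mask[i, j]) integer(0) else tip_states[i, j]
  rownames(cells) <- tr$tip.label
  character_matrix(cells, ordered = ordered)
}

#' Simulate allometric head-width / total-length data on a tree
#'
#' Draws log10 head widths uniformly over the configured range, adds
#' phylogenetic Brownian residuals (lambda-scaled covariance, variance
#' `sigma2` at the deepest tip) to the linear log-log allometry, and splits
#' taxa into extant records (multiple specimens with small measurement
#' scatter) and fossils whose total length is withheld. The generating
#' truth is returned for recovery tests.
#'
#' @param tree calibrated `phylo`.
#' @param config a [sim_config()].
#' @return list with `extant` (records data frame), `fossil_hw`
#'   (`taxon`, `hw_cm`), and `truth` (list: `slope`, `intercept`, `sigma2`,
#'   `lambda`, `tl_cm` named vector incl. fossils).
#' @export
simulate_allometry <- function(tree, config) {
  .check_phylo(tree)
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream(config$seed, 3L))
  taxa <- tree$tip.label
  n <- length(taxa)
  ages <- node_ages(tree)[taxa]
  fossil_pool <- names(ages)[ages > 1e-9]
  n_fossil <- min(length(fossil_pool), round(config$prop_fossil * n))
  fossil <- if (n_fossil) sort(sample(fossil_pool, n_fossil)) else character(0)
  extant_taxa <- setdiff(taxa, fossil)

  log_hw <- stats::runif(n, log10(config$hw_range[1]), log10(config$hw_range[2]))
  C <- .phylo_corr(tree, config$lambda, taxa = taxa)
  resid <- if (config$sigma2 > 0)
    drop(crossprod(chol(C), stats::rnorm(n))) * sqrt(config$sigma2)
  else rep(0, n)
  log_tl <- config$intercept + config$slope * log_hw + resid
  names(log_tl) <- names(log_hw) <- taxa

  meas_sd <- 0.01   # log10-scale specimen measurement scatter
  ex <- do.call(rbind, lapply(extant_taxa, function(tx) {
    ns <- config$n_specimens
    data.frame(taxon = tx, specimen = sprintf("%s_s%d", tx, seq_len(ns)),
               hw_cm = 10^(log_hw[tx] + stats::rnorm(ns, 0, meas_sd)),
               tl_cm = 10^(log_tl[tx] + stats::rnorm(ns, 0, meas_sd)),
               stringsAsFactors = FALSE)
  }))
  fo <- data.frame(taxon = fossil,
                   hw_cm = 10^unname(log_hw[fossil]),
                   stringsAsFactors = FALSE)
  list(extant = ex, fossil_hw = fo,
       truth = list(slope = config$slope, intercept = config$intercept,
                    sigma2 = config$sigma2, lambda = config$lambda,
                    tl_cm = 10^log_tl))
}
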