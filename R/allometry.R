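# Head-width to total-length allometry with phylogenetic structure.
# The regression is log10(TL_cm) ~ log10(HW_cm) over extant taxa (specimens
# averaged per taxon on the log scale); residuals follow a Brownian-motion
# covariance from the time tree with Pagel's lambda scaling. Fossil total
# lengths are imputed from head width by a conjugate Gibbs sampler over the
# regression coefficients and residual variance, drawing each fossil's
# log-length from its Brownian conditional (kriging) distribution.

## per-taxon mean log10 measurements of extant records (tl present)
.aggregate_extant <- function(records) {
  rec <- records[!is.na(records$tl_cm), , drop = FALSE]
  if (any(rec$hw_cm <= 0) || any(rec$tl_cm <= 0))
    .stopf("measurements must be positive")
  sp <- split(rec, rec$taxon)
  data.frame(taxon = names(sp),
             x = vapply(sp, function(d) mean(log10(d$hw_cm)), numeric(1)),
             y = vapply(sp, function(d) mean(log10(d$tl_cm)), numeric(1)),
             n_specimens = vapply(sp, nrow, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

.gls_fit <- function(X, y, C) {
  L <- chol(C)
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  r <- ys - Xs %*% beta
  list(beta = drop(beta), rss = drop(crossprod(r)), XtX = XtX,
       logdet = 2 * sum(log(diag(L))))
}

#' Fit the extant head-width to total-length regression
#'
#' Ordinary (`OLS`) or phylogenetic (`PGLS`) least squares on per-taxon mean
#' log10 head width and total length. PGLS uses the lambda-scaled
#' Brownian-motion correlation from the calibrated tree.
#'
#' @param records data frame of extant allometry records (`taxon`,
#'   `specimen`, `hw_cm`, `tl_cm`), e.g. from [read_table()]. Rows without
#'   `tl_cm` are ignored.
#' @param tree calibrated `phylo` (required for PGLS).
#' @param mode `"OLS"` or `"PGLS"`.
#' @param lambda Pagel's lambda in `[0, 1]` used by PGLS (default 1).
#' @return an object of class `regression_model` with elements `intercept`,
#'   `slope` (log10 scale), `sigma2` (residual variance), `lambda`, `mode`
#'   and `taxa`.
#' @export
fit_regression <- function(records, tree = NULL, mode = c("OLS", "PGLS"),
                           lambda = 1) {
  mode <- match.arg(mode)
  if (lambda < 0 || lambda > 1) .stopf("`lambda` must be in [0, 1]")
  agg <- .aggregate_extant(records)
  n <- nrow(agg)
  if (n < 3L) .stopf("need >= 3 extant taxa with both HW and TL, got %d", n)
  X <- cbind(1, agg$x)
  C <- if (mode == "PGLS") {
    if (is.null(tree)) .stopf("PGLS needs a calibrated tree")
    .phylo_corr(tree, lambda, taxa = agg$taxon)
  } else diag(n)
  fit <- .gls_fit(X, agg$y, C)
  structure(list(intercept = fit$beta[1], slope = fit$beta[2],
                 sigma2 = fit$rss / (n - 2), lambda = lambda, mode = mode,
                 taxa = agg$taxon, n_taxa = n,
                 n_specimens = sum(agg$n_specimens), log_base = 10),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf(
    "%s allometry: log10(TL) = %.4f + %.4f log10(HW)  (sigma2 %.5f, lambda %.2f, %d taxa / %d specimens)\n",
    x$mode, x$intercept, x$slope, x$sigma2, x$lambda, x$n_taxa, x$n_specimens))
  invisible(x)
}

#' Maximum-likelihood Pagel's lambda of a trait
#'
#' Profiles the Gaussian likelihood of `trait ~ N(mu, sigma2 * C(lambda))`
#' over `lambda` in `[0, 1]` (off-diagonal covariance scaled by lambda) with
#' `mu` and `sigma2` concentrated out, by bounded one-dimensional
#' optimisation with the interval endpoints also checked.
#'
#' @param tree calibrated `phylo`.
#' @param trait named numeric vector of tip values (one per taxon).
#' @return list with `lambda`, `loglik` and `sigma2`.
#' @export
estimate_lambda <- function(tree, trait) {
  .check_phylo(tree)
  if (is.null(names(trait))) .stopf("`trait` must be named by taxon")
  trait <- trait[!is.na(trait)]
  if (length(trait) < 4L) .stopf("need >= 4 taxa to estimate lambda")
  if (stats::sd(trait) == 0)
    .stopf("trait is constant; lambda is undefined")
  C1 <- .phylo_corr(tree, 1, taxa = names(trait))
  n <- length(trait)
  X <- matrix(1, n, 1)
  ll <- function(lam) {
    C <- C1 * lam
    diag(C) <- diag(C1)
    fit <- .gls_fit(X, trait, C)
    s2 <- fit$rss / n
    -0.5 * (n * log(2 * pi * s2) + fit$logdet + n)
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, ll(0), ll(1))
  best <- which.max(vals)
  lam <- cand[best]
  C <- C1 * lam
  diag(C) <- diag(C1)
  fit <- .gls_fit(X, trait, C)
  list(lambda = lam, loglik = vals[best], sigma2 = fit$rss / n)
}

## restricted-likelihood profile of lambda for a GLS regression; REML keeps
## the lambda estimate from absorbing coefficient uncertainty
.estimate_lambda_gls <- function(tree, X, y, taxa) {
  C1 <- .phylo_corr(tree, 1, taxa = taxa)
  n <- length(y)
  p <- ncol(X)
  ll <- function(lam) {
    C <- C1 * lam
    diag(C) <- diag(C1)
    fit <- .gls_fit(X, y, C)
    s2 <- fit$rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + fit$logdet +
            determinant(fit$XtX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, 1)
  cand[which.max(c(opt$objective, ll(0), ll(1)))]
}

#' MCMC configuration for body-length imputation
#'
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed (mandatory).
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 10000L, burn_in = 1000L, thin = 10L, seed) {
  if (missing(seed)) .stopf("`seed` is mandatory")
  stopifnot(n_iter > burn_in, burn_in >= 0L, thin >= 1L)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Impute fossil total body length from head width
#'
#' Bayesian phylogenetic prediction under a Brownian-motion model: a Gibbs
#' sampler alternates the regression coefficients (flat prior) and residual
#' variance (inverse-gamma(0.001, 0.001) prior) conditional on the extant
#' data, and per draw samples each fossil's log10 total length from its
#' Brownian conditional distribution given the extant residuals (kriging
#' mean `x_f b + C_fo C_oo^-1 (y - X_o b)` and matching conditional
#' variance). Draws are back-transformed to cm. Lambda is plug-in: estimated
#' once from the OLS residuals of the extant regression unless supplied.
#'
#' @param tree calibrated `phylo` containing extant and fossil tips.
#' @param extant data frame of extant allometry records (see
#'   [fit_regression()]).
#' @param fossil_hw data frame with columns `taxon` and `hw_cm` (one row per
#'   fossil tip), or a named numeric vector of head widths in cm.
#' @param mode `"PGLS"` (default) or `"OLS"` covariance for the coefficient
#'   updates; the fossil draw always uses the phylogenetic conditional.
#' @param lambda optional fixed Pagel's lambda; estimated if `NULL`.
#' @param mcmc an [mcmc_config()].
#' @return data frame of class `prediction_result`: `taxon`, `mean_cm`,
#'   `q2.5_cm`, `q97.5_cm`, `ess`, `n_draws`, plus attributes `lambda` and
#'   `model` (the fitted [fit_regression()] model).
#' @export
predict_tl <- function(tree, extant, fossil_hw, mode = c("PGLS", "OLS"),
                       lambda = NULL, mcmc) {
  mode <- match.arg(mode)
  .check_phylo(tree)
  stopifnot(inherits(mcmc, "mcmc_config"))
  if (is.numeric(fossil_hw) && !is.null(names(fossil_hw)))
    fossil_hw <- data.frame(taxon = names(fossil_hw), hw_cm = unname(fossil_hw),
                            stringsAsFactors = FALSE)
  if (!all(c("taxon", "hw_cm") %in% names(fossil_hw)))
    .stopf("`fossil_hw` needs columns taxon and hw_cm")
  drop <- is.na(fossil_hw$hw_cm) | fossil_hw$hw_cm <= 0
  if (any(drop)) {
    .warnf("skipping fossil taxa without usable HW: %s",
           paste(fossil_hw$taxon[drop], collapse = ", "))
    fossil_hw <- fossil_hw[!drop, , drop = FALSE]
  }
  if (!nrow(fossil_hw)) .stopf("no fossil taxa with usable HW")
  agg <- .aggregate_extant(extant)
  n <- nrow(agg)
  if (n < 3L) .stopf("need >= 3 extant taxa with both HW and TL")
  miss <- setdiff(c(agg$taxon, fossil_hw$taxon), tree$tip.label)
  if (length(miss))
    .stopf("taxa absent from tree: %s", paste(miss, collapse = ", "))

  if (is.null(lambda))
    lambda <- .estimate_lambda_gls(tree, cbind(1, agg$x), agg$y, agg$taxon)

  all_taxa <- c(agg$taxon, fossil_hw$taxon)
  C <- .phylo_corr(tree, lambda, taxa = all_taxa)
  oo <- seq_len(n)
  ff <- n + seq_len(nrow(fossil_hw))
  C_oo <- C[oo, oo, drop = FALSE]
  C_fo <- C[ff, oo, drop = FALSE]
  C_ff <- C[ff, ff, drop = FALSE]
  Mi <- tryCatch(chol2inv(chol(C_oo)), error = function(e)
    .stopf("singular extant covariance; consider jittering zero-length branches"))
  X_o <- cbind(1, agg$x)
  y_o <- agg$y
  x_f <- log10(fossil_hw$hw_cm)
  X_f <- cbind(1, x_f)

  C_coef <- if (mode == "PGLS") Mi else diag(n)
  A <- crossprod(X_o, C_coef %*% X_o)
  A_inv <- solve(A)
  R_beta <- chol(A_inv)
  beta_hat <- drop(A_inv %*% crossprod(X_o, C_coef %*% y_o))
  W <- C_fo %*% Mi
  cond_var <- pmax(diag(C_ff - W %*% t(C_fo)), 0)

  a0 <- b0 <- 0.001
  set.seed(mcmc$seed)
  sigma2 <- max(drop(crossprod(y_o - X_o %*% beta_hat,
                               C_coef %*% (y_o - X_o %*% beta_hat))) / (n - 2),
                1e-12)
  keep <- floor((mcmc$n_iter - mcmc$burn_in) / mcmc$thin)
  draws <- matrix(NA_real_, keep, length(ff))
  beta_draws <- matrix(NA_real_, keep, 2,
                       dimnames = list(NULL, c("intercept", "slope")))
  kept <- 0L
  for (it in seq_len(mcmc$n_iter)) {
    beta <- beta_hat + sqrt(sigma2) * drop(crossprod(R_beta, rnorm(2)))
    r <- y_o - drop(X_o %*% beta)
    rss <- drop(crossprod(r, C_coef %*% r))
    sigma2 <- 1 / stats::rgamma(1, a0 + n / 2, b0 + rss / 2)
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
      kept <- kept + 1L
      mu_f <- drop(X_f %*% beta) + drop(W %*% r)
      draws[kept, ] <- mu_f + sqrt(sigma2 * cond_var) * rnorm(length(ff))
      beta_draws[kept, ] <- beta
    }
  }
  draws <- draws[seq_len(kept), , drop = FALSE]
  beta_draws <- beta_draws[seq_len(kept), , drop = FALSE]
  cm_draws <- 10^draws
  out <- data.frame(
    taxon = fossil_hw$taxon,
    mean_cm = colMeans(cm_draws),
    q2.5_cm = apply(cm_draws, 2, stats::quantile, probs = 0.025),
    q97.5_cm = apply(cm_draws, 2, stats::quantile, probs = 0.975),
    ess = apply(draws, 2, .ess),
    n_draws = kept,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("prediction_result", "data.frame")
  attr(out, "lambda") <- lambda
  attr(out, "model") <- fit_regression(extant, tree = tree, mode = mode,
                                       lambda = if (mode == "PGLS") lambda else 1)
  attr(out, "draws_log10") <- draws
  attr(out, "beta_draws") <- beta_draws
  out
}
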