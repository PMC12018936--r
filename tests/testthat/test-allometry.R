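make_records <- function(taxa, hw, tl) {
  data.frame(taxon = taxa, specimen = paste0(taxa, "_s1"),
             hw_cm = hw, tl_cm = tl, stringsAsFactors = FALSE)
}

test_that("perfectly collinear data are recovered exactly with zero residual variance", {
  hw <- c(10, 20, 30, 40, 50)
  tl <- 10^(0.9 + 1.1 * log10(hw))
  fit <- fit_regression(make_records(paste0("s", 1:5), hw, tl), mode = "OLS")
  expect_equal(fit$intercept, 0.9, tolerance = 1e-10)
  expect_equal(fit$slope, 1.1, tolerance = 1e-10)
  expect_equal(fit$sigma2, 0, tolerance = 1e-12)
})

test_that("OLS equals the normal-equations solution", {
  set.seed(21)
  hw <- runif(5, 10, 80)
  tl <- 10^(0.8 + 0.95 * log10(hw) + rnorm(5, 0, 0.05))
  fit <- fit_regression(make_records(paste0("s", 1:5), hw, tl), mode = "OLS")
  X <- cbind(1, log10(hw))
  beta <- solve(t(X) %*% X, t(X) %*% log10(tl))
  expect_equal(c(fit$intercept, fit$slope), drop(beta), tolerance = 1e-10)
})

test_that("PGLS under an identity correlation equals OLS", {
  set.seed(22)
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  hw <- runif(5, 10, 60)
  tl <- 10^(0.9 + log10(hw) + rnorm(5, 0, 0.05))
  rec <- make_records(letters[1:5], hw, tl)
  ols <- fit_regression(rec, mode = "OLS")
  pgls <- fit_regression(rec, tree = star, mode = "PGLS", lambda = 1)
  expect_equal(c(pgls$intercept, pgls$slope, pgls$sigma2),
               c(ols$intercept, ols$slope, ols$sigma2), tolerance = 1e-10)
})

test_that("specimens are averaged per taxon on the log scale", {
  rec <- rbind(make_records(c("a", "a"), c(10, 40), c(90, 90)),
               make_records(c("b", "c", "d"), c(20, 30, 50), c(150, 210, 320)))
  fit <- fit_regression(rec, mode = "OLS")
  agg_x <- mean(log10(c(10, 40)))
  rec2 <- rbind(make_records("a", 10^agg_x, 90),
                make_records(c("b", "c", "d"), c(20, 30, 50), c(150, 210, 320)))
  fit2 <- fit_regression(rec2, mode = "OLS")
  expect_equal(fit$slope, fit2$slope, tolerance = 1e-10)
})

test_that("lambda optimisation matches a fine grid search on a small tree", {
  set.seed(23)
  for (rep in 1:5) {
    tr <- ape::rtree(5, tip.label = letters[1:5])
    trait <- setNames(rnorm(5), letters[1:5])
    est <- estimate_lambda(tr, trait)
    C1 <- ape::vcv(tr); C1 <- C1 / max(diag(C1))
    grid <- seq(0, 1, by = 1e-4)
    ll <- vapply(grid, function(lam) {
      C <- C1 * lam; diag(C) <- diag(C1)
      ## profile mu and sigma2 out analytically
      Ci <- solve(C)
      mu <- sum(Ci %*% trait[rownames(C)]) / sum(Ci)
      s2 <- drop(t(trait[rownames(C)] - mu) %*% Ci %*% (trait[rownames(C)] - mu)) / 5
      mvn_loglik(trait[rownames(C)], rep(mu, 5), s2 * C)
    }, numeric(1))
    expect_equal(est$lambda, grid[which.max(ll)], tolerance = 2e-3)
    expect_equal(est$loglik, max(ll), tolerance = 1e-5)
  }
})

test_that("lambda is recovered from strong-signal simulations", {
  skip_if_not_installed("phytools")
  set.seed(24)
  hits <- 0L
  for (rep in 1:100) {
    tr <- ape::rtree(100)
    trait <- phytools::fastBM(tr)    # true lambda = 1
    est <- estimate_lambda(tr, trait)
    hits <- hits + (est$lambda >= 0.8)
  }
  expect_gte(hits, 90L)
})

test_that("constant traits make lambda undefined", {
  tr <- ape::rtree(5, tip.label = letters[1:5])
  expect_error(estimate_lambda(tr, setNames(rep(1, 5), letters[1:5])),
               "constant")
})

test_that("a fossil duplicating an extant tip at zero distance inherits its length", {
  tr <- ape::read.tree(text = "((A:0,F:0):1,(B:0.6,C:0.6):0.4);")
  rec <- make_records(c("A", "B", "C"), c(20, 30, 45), c(160, 230, 330))
  pred <- predict_tl(tr, rec, c(F = 20), lambda = 1,
                     mcmc = mcmc_config(600, 100, 1, seed = 5))
  expect_equal(pred$mean_cm, 160, tolerance = 1e-9)
  expect_equal(pred$q2.5_cm, pred$q97.5_cm, tolerance = 1e-9)
})

test_that("the MCMC predictive mean matches the closed-form GLS kriging mean", {
  set.seed(26)
  tr <- ape::rtree(7, tip.label = paste0("t", 1:7))
  extant <- paste0("t", 1:6); fossil <- "t7"
  hw <- runif(6, 10, 60)
  tl <- 10^(0.9 + log10(hw) + rnorm(6, 0, 0.08))
  rec <- make_records(extant, hw, tl)
  lam <- 0.85
  pred <- predict_tl(tr, rec, c(t7 = 33), lambda = lam,
                     mcmc = mcmc_config(20000, 2000, 2, seed = 6))
  ## direct matrix algebra oracle
  C <- ape::vcv(tr); C <- C / max(diag(C))
  d <- diag(C); C <- C * lam; diag(C) <- d
  o <- extant
  Coo <- C[o, o]; Cfo <- C[fossil, o, drop = FALSE]
  X <- cbind(1, log10(hw)); y <- log10(tl)
  Mi <- solve(Coo)
  beta <- solve(t(X) %*% Mi %*% X, t(X) %*% Mi %*% y)
  mu <- drop(cbind(1, log10(33)) %*% beta + Cfo %*% Mi %*% (y - X %*% beta))
  got <- mean(attr(pred, "draws_log10"))
  mc_se <- sd(attr(pred, "draws_log10")) / sqrt(pred$ess)
  expect_lt(abs(got - mu), max(4 * mc_se, 0.01))
})

test_that("with lambda 0 the predictive mean converges to the OLS point prediction", {
  set.seed(27)
  tr <- ape::rtree(8, tip.label = paste0("t", 1:8))
  hw <- runif(7, 10, 60)
  tl <- 10^(0.9 + log10(hw) + rnorm(7, 0, 0.05))
  rec <- make_records(paste0("t", 1:7), hw, tl)
  ols <- fit_regression(rec, mode = "OLS")
  pred <- predict_tl(tr, rec, c(t8 = 40), mode = "OLS", lambda = 0,
                     mcmc = mcmc_config(30000, 2000, 2, seed = 7))
  expect_equal(mean(attr(pred, "draws_log10")),
               ols$intercept + ols$slope * log10(40), tolerance = 5e-3)
})

test_that("predictions are positive, quantile-ordered and monotone in head width", {
  set.seed(28)
  cfg <- sim_config(n_taxa = 15, prop_fossil = 0.25, seed = 33)
  sim <- simulate_tree(cfg)
  al <- simulate_allometry(sim$tree, cfg)
  pred <- predict_tl(sim$tree, al$extant, al$fossil_hw,
                     mcmc = mcmc_config(2000, 400, 2, seed = 8))
  expect_true(all(pred$q2.5_cm > 0))
  expect_true(all(pred$q2.5_cm <= pred$mean_cm & pred$mean_cm <= pred$q97.5_cm))
  ## same fossil, larger head width, same seed stream
  f1 <- al$fossil_hw[1, , drop = FALSE]
  f2 <- f1; f2$hw_cm <- f2$hw_cm * 1.5
  p1 <- predict_tl(sim$tree, al$extant, f1, lambda = 0.9,
                   mcmc = mcmc_config(2000, 400, 2, seed = 9))
  p2 <- predict_tl(sim$tree, al$extant, f2, lambda = 0.9,
                   mcmc = mcmc_config(2000, 400, 2, seed = 9))
  expect_gt(p2$mean_cm, p1$mean_cm)
})

test_that("degenerate inputs are rejected or skipped with a warning", {
  rec <- make_records(c("a", "b"), c(10, 20), c(90, 150))
  expect_error(fit_regression(rec, mode = "OLS"), ">= 3")
  tr <- ape::rtree(4, tip.label = letters[1:4])
  rec3 <- make_records(letters[1:3], c(10, 20, 30), c(90, 150, 210))
  expect_error(
    expect_warning(
      predict_tl(tr, rec3, data.frame(taxon = "d", hw_cm = NA_real_),
                 lambda = 1, mcmc = mcmc_config(200, 50, 1, seed = 1)),
      "skipping"),
    "no fossil taxa")
})
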