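test_that("tree simulation is deterministic and produces consistent ages", {
  cfg <- sim_config(n_taxa = 12, seed = 55)
  a <- simulate_tree(cfg)
  b <- simulate_tree(cfg)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$ages, b$ages)
  expect_true(all(a$ages$fad == a$ages$lad))
  ## the age table agrees with the tree's own tip depths
  expect_equal(unname(node_ages(a$tree)[a$ages$taxon]), a$ages$fad,
               tolerance = 1e-9)
  expect_gt(min(a$tree$edge.length), 0)
  cherry <- simulate_tree(sim_config(n_taxa = 2, seed = 1))
  expect_equal(length(cherry$tree$tip.label), 2L)
})

test_that("a higher net diversification rate leaves more extant survivors", {
  n_extant <- function(birth, death, base) {
    mean(vapply(1:100, function(r) {
      sim <- simulate_tree(sim_config(n_taxa = 10, birth = birth,
                                      death = death, seed = base + r))
      sum(sim$ages$fad == 0)
    }, numeric(1)))
  }
  high <- n_extant(0.08, 0.01, 10000)
  low <- n_extant(0.04, 0.035, 20000)
  expect_gt(high, low)
})

test_that("character simulation honours rate limits and the true tree", {
  cfg0 <- sim_config(n_taxa = 10, n_chars = 20, rate = 0, seed = 60)
  sim <- simulate_tree(cfg0)
  cm0 <- simulate_matrix(sim$tree, cfg0)
  expect_identical(tree_length(sim$tree, cm0), 0L)

  ## the generating tree should usually be at least as short as a random one
  wins <- 0L
  for (r in 1:60) {
    cfg <- sim_config(n_taxa = 10, n_chars = 30, rate = 0.02,
                      missing_fraction = 0, seed = 300 + r)
    sim <- simulate_tree(cfg)
    cm <- simulate_matrix(sim$tree, cfg)
    set.seed(400 + r)
    rnd <- ape::rtree(10, tip.label = sample(sim$tree$tip.label))
    wins <- wins + (tree_length(sim$tree, cm) <= tree_length(rnd, cm))
  }
  expect_gte(wins, 57L)  # >= 95% of 60
})

test_that("tip states approach the uniform stationary distribution at high rate", {
  cfg <- sim_config(n_taxa = 30, n_chars = 300, n_states = 3, rate = 5,
                    prop_ordered = 0, missing_fraction = 0, seed = 71)
  sim <- simulate_tree(cfg)
  cm <- simulate_matrix(sim$tree, cfg)
  states <- unlist(cm$cells)
  freq <- tabulate(states + 1L, nbins = 3) / length(states)
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("allometric residuals carry the lambda-scaled Brownian covariance", {
  cfg <- sim_config(n_taxa = 8, sigma2 = 0.04, lambda = 0.7,
                    prop_fossil = 0, seed = 80)
  sim <- simulate_tree(cfg)
  R <- t(vapply(1:500, function(r) {
    cfgr <- cfg; cfgr$seed <- 80 + r
    al <- simulate_allometry(sim$tree, cfgr)
    agg <- aggregate(cbind(lhw = log10(hw_cm), ltl = log10(tl_cm)) ~ taxon,
                     al$extant, mean)
    res <- agg$ltl - cfg$intercept - cfg$slope * agg$lhw
    setNames(res, agg$taxon)[sim$tree$tip.label]
  }, numeric(8)))
  emp <- cov(R)
  C <- ape::vcv(sim$tree); C <- C / max(diag(C))
  d <- diag(C); C <- C * cfg$lambda; diag(C) <- d
  theo <- cfg$sigma2 * C[colnames(R), colnames(R)]
  ## empirical and theoretical covariances agree entrywise (MC tolerance)
  expect_lt(max(abs(emp - theo)), 0.015)
  expect_gt(cor(emp[upper.tri(emp)], theo[upper.tri(theo)]), 0.8)
})

test_that("allometry generation is reproducible and withholds fossil lengths", {
  cfg <- sim_config(n_taxa = 14, prop_fossil = 0.3, seed = 90)
  sim <- simulate_tree(cfg)
  a <- simulate_allometry(sim$tree, cfg)
  b <- simulate_allometry(sim$tree, cfg)
  expect_identical(a, b)
  expect_false(any(a$fossil_hw$taxon %in% a$extant$taxon))
  expect_true(all(c("slope", "intercept", "sigma2", "lambda", "tl_cm")
                  %in% names(a$truth)))
  ## noiseless limit: prediction recovers withheld lengths almost exactly
  cfg0 <- sim_config(n_taxa = 10, sigma2 = 0, prop_fossil = 0.3,
                     n_specimens = 1, seed = 91)
  sim0 <- simulate_tree(cfg0)
  al0 <- simulate_allometry(sim0$tree, cfg0)
  pred <- predict_tl(sim0$tree, al0$extant, al0$fossil_hw, lambda = 1,
                     mcmc = mcmc_config(2000, 400, 2, seed = 92))
  truth <- al0$truth$tl_cm[pred$taxon]
  ## only specimen measurement scatter (0.01 dex) separates them
  expect_equal(pred$mean_cm, unname(truth), tolerance = 0.05)
})
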