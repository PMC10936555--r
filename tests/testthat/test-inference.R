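make_cherry_fixture <- function() {
  tree <- ape::read.tree(text = "(A:60,B:60);")
  space <- build_state_space(1, 3, 1)
  tips <- list(tip_data("A", 2), tip_data("B", 3))
  list(tree = tree, space = space, tips = tips)
}

test_that("exponential log prior sums independent densities and rejects negatives", {
  expect_equal(log_prior(c(0, 0), prior_rate = 2), 2 * log(2))
  xs <- seq(0.1, 3, by = 0.4)
  lp <- vapply(xs, log_prior, numeric(1), prior_rate = 2)
  expect_true(all(diff(lp) < 0))
  expect_equal(log_prior(c(0.1, 0.2, 0.3), 2),
               sum(dexp(c(0.1, 0.2, 0.3), 2, log = TRUE)))
  expect_identical(log_prior(c(0.5, -0.1), 2), -Inf)
  expect_error(log_prior(0.5, prior_rate = 0), "prior_rate")
})

test_that("mcmc_config validates its protocol fields", {
  cfg <- mcmc_config(model = "clade_2p")
  expect_equal(cfg$n_generations, 200L)
  expect_equal(cfg$burnin, 100L)
  expect_equal(cfg$prior_rate, 2)
  expect_equal(cfg$init_high, 10)
  expect_error(mcmc_config(model = "clade_2p", burnin = 200), "burnin")
  expect_error(mcmc_config(model = "clade_2p", n_generations = 0), "n_generations")
})

test_that("identical seeds give bit-identical traces", {
  fx <- make_cherry_fixture()
  cfg <- mcmc_config(model = "clade_2p", n_generations = 25, burnin = 5, seed = 42)
  t1 <- run_mcmc(fx$tree, fx$tips, fx$space, cfg)
  t2 <- run_mcmc(fx$tree, fx$tips, fx$space, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- run_mcmc(fx$tree, fx$tips, fx$space,
                 mcmc_config(model = "clade_2p", n_generations = 25,
                             burnin = 5, seed = 43))
  expect_false(identical(t1$gamma, t3$gamma))
})

test_that("traces record every generation on both scales with valid rates", {
  fx <- make_cherry_fixture()
  cfg <- mcmc_config(model = "clade_3p", n_generations = 30, burnin = 10, seed = 2)
  tr <- run_mcmc(fx$tree, fx$tips, fx$space, cfg)
  expect_equal(nrow(tr), 30L)
  expect_true(all(c("gamma", "delta", "rho", "gamma_my", "lnL", "lnPrior")
                  %in% names(tr)))
  expect_true(all(tr$gamma >= 0 & tr$delta >= 0 & tr$rho >= 0))
  expect_equal(tr$gamma_my, tr$gamma / 60)   # unit-depth fit on a depth-60 tree
  expect_true(all(is.finite(tr$lnL)))
})

test_that("pooled traces obey the row-count protocol and resample tip counts", {
  fx <- make_cherry_fixture()
  cfg <- mcmc_config(model = "clade_2p", n_generations = 10, burnin = 5, seed = 1)
  pooled <- multi_tree_posterior(list(fx$tree), fx$tips, fx$space, cfg)
  expect_equal(nrow(pooled), 5L)

  # a tip with two retained counts must see both across many per-tree fits
  tips2 <- list(tip_data("A", c(2, 3)), tip_data("B", 3))
  trees <- rep(list(fx$tree), 40)
  cfg2 <- mcmc_config(model = "clade_2p", n_generations = 2, burnin = 1, seed = 7)
  pooled2 <- multi_tree_posterior(trees, tips2, fx$space, cfg2)
  expect_equal(nrow(pooled2), 40L)
  expect_equal(length(unique(pooled2$tree_id)), 40L)
  # recover which count was drawn per tree from the per-tree seed stream
  drawn <- vapply(seq_len(40), function(i) {
    set.seed(7 + i)
    c(2L, 3L)[sample.int(2L, 1L)]
  }, integer(1))
  expect_setequal(unique(drawn), c(2L, 3L))

  tree_other <- ape::read.tree(text = "(A:60,C:60);")
  expect_error(
    suppressWarnings(multi_tree_posterior(list(fx$tree, tree_other),
                                          tips2, fx$space, cfg2)),
    "tip set|fewer than 2"
  )
})

test_that("multi-count tips must be resolved before a single-tree fit", {
  fx <- make_cherry_fixture()
  tips2 <- list(tip_data("A", c(2, 3)), tip_data("B", 3))
  cfg <- mcmc_config(model = "clade_2p", n_generations = 5, burnin = 1, seed = 1)
  expect_error(run_mcmc(fx$tree, tips2, fx$space, cfg), "multi-count")
})

test_that("a chain with constant likelihood samples the exponential prior", {
  fx <- make_cherry_fixture()
  k <- fx$space$size
  flat <- list(A = rep(1 / k, k), B = rep(1 / k, k))
  cfg <- mcmc_config(model = "clade_2p", n_generations = 1500, burnin = 200,
                     prior_rate = 2, seed = 11)
  tr <- run_mcmc(fx$tree, fx$tips, fx$space, cfg, tip_vectors = flat)
  post <- tr[tr$gen > cfg$burnin, ]
  for (p in c("gamma", "delta")) {
    se <- batch_se(post[[p]])
    expect_lt(abs(mean(post[[p]]) - 0.5), 3 * se + 1e-9)
  }
})

test_that("posterior credible intervals tighten with more tips", {
  width_for <- function(n_tips, seed) {
    tree <- simulate_yule_tree(n_tips, 1, seed = seed)
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
    space <- build_state_space(4, 30, 1)
    sim <- simulate_evolution(tree, rate_params(2, 1, n_trait_levels = 1),
                              space, c(12, 0), seed = seed + 1)
    cfg <- mcmc_config(model = "clade_2p", n_generations = 150, burnin = 50,
                       seed = seed)
    tr <- run_mcmc(tree, sim$tips, space, cfg)
    post <- tr[tr$gen > cfg$burnin, ]
    ci <- credible_interval(post$gamma, 0.95)
    ci[2] - ci[1]
  }
  expect_lt(width_for(200, seed = 31), width_for(50, seed = 31))
})

test_that("informative data pull the posterior above the prior-only likelihood", {
  tree <- simulate_yule_tree(20, 1, seed = 13)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  space <- build_state_space(4, 25, 1)
  sim <- simulate_evolution(tree, rate_params(2, 1, n_trait_levels = 1),
                            space, c(10, 0), seed = 14)
  cfg <- mcmc_config(model = "clade_2p", n_generations = 120, burnin = 40, seed = 5)
  tr <- run_mcmc(tree, sim$tips, space, cfg)
  post_mean_lnL <- mean(tr$lnL[tr$gen > cfg$burnin])

  names(sim$tips) <- vapply(sim$tips, `[[`, character(1), "species")
  tipvecs <- lapply(sim$tips[tree$tip.label],
                    function(tp) tip_likelihood_vector(tp, tp$counts, space))
  set.seed(6)
  prior_lnL <- replicate(60, {
    pars <- rate_params(rexp(1, 2), rexp(1, 2), n_trait_levels = 1)
    prune_log_likelihood(tree, tipvecs, build_q_matrix(space, pars))
  })
  expect_gt(post_mean_lnL, mean(prior_lnL))
})

test_that("an over-narrow state space is reported, not silently fitted", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  space <- build_state_space(2, 3, 1)
  tips <- list(tip_data("A", 2), tip_data("B", 3))
  cfg <- mcmc_config(model = "clade_2p", n_generations = 5, burnin = 1, seed = 1)
  # count 5 outside [2, 3]: the tip vector itself errors, naming the species
  expect_error(run_mcmc(tree, list(tip_data("A", 2), tip_data("B", 5)),
                        space, cfg), "B")
})

test_that("trace round-trips through CSV with its configuration sidecar", {
  fx <- make_cherry_fixture()
  cfg <- mcmc_config(model = "clade_2p", n_generations = 12, burnin = 4, seed = 3)
  tr <- run_mcmc(fx$tree, fx$tips, fx$space, cfg)
  path <- file.path(tempdir(), "trace.csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
  expect_equal(attr(back, "config")$model, "clade_2p")
  expect_equal(unname(attr(back, "depths")), unname(attr(tr, "depths")))
})
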