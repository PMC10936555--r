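test_that("Yule trees: cherry base case, determinism, expected depth", {
  tr <- simulate_yule_tree(2, 1, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 2L)
  expect_true(ape::is.ultrametric(tr))

  a <- simulate_yule_tree(50, 1, seed = 9)
  b <- simulate_yule_tree(50, 1, seed = 9)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_error(simulate_yule_tree(1, 1, seed = 1), "n_tips")

  n <- 20
  depths <- vapply(1:300, function(s) {
    max(ape::node.depth.edgelength(simulate_yule_tree(n, 1, seed = 1000 + s)))
  }, numeric(1))
  expected <- sum(1 / (2:n))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("perturbed tree sets keep topology and centre on the input depth", {
  base <- simulate_yule_tree(30, 1, seed = 4)
  base_post <- ape::reorder.phylo(base, "postorder")
  same <- perturb_tree_set(base, 3, sd_log = 0, seed = 5)
  for (tr in same) expect_equal(tr$edge.length, base_post$edge.length)

  reps <- perturb_tree_set(base, 100, sd_log = 0.1, seed = 6)
  for (tr in reps[c(1, 50, 100)]) {
    expect_true(ape::is.ultrametric(tr, tol = 1e-6))
    expect_identical(tr$edge, base_post$edge)      # topology preserved
    expect_identical(tr$tip.label, base_post$tip.label)
    expect_true(all(tr$edge.length > 0))
    expect_false(identical(tr$edge.length, base_post$edge.length))
  }

  d0 <- max(ape::node.depth.edgelength(base))
  depths <- vapply(reps, function(tr) max(ape::node.depth.edgelength(tr)),
                   numeric(1))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - d0), 3 * se + 0.01 * d0)
  expect_error(perturb_tree_set(base, 2, sd_log = -0.1, seed = 1), "sd_log")
})

test_that("Gillespie simulation: frozen dynamics, monotone fissions, Poisson event count", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  space <- build_state_space(1, 30, 1)

  frozen <- simulate_evolution(tree, rate_params(0, 0, n_trait_levels = 1),
                               space, c(10, 0), seed = 1)
  expect_equal(frozen$tip_states$count, rep(10L, 3))
  expect_equal(nrow(frozen$event_log), 0L)

  up <- simulate_evolution(tree, rate_params(2, 0, n_trait_levels = 1),
                           space, c(5, 0), seed = 2)
  expect_true(all(up$tip_states$count >= 5))
  expect_true(all(up$event_log$type == "fission"))

  cherry <- ape::read.tree(text = "(A:1,B:1);")
  n_events <- vapply(1:4000, function(s) {
    nrow(simulate_evolution(cherry, rate_params(1, 0, n_trait_levels = 1),
                            space, c(10, 0), seed = 5000 + s)$event_log)
  }, numeric(1))
  se <- sd(n_events) / sqrt(length(n_events))
  expect_lt(abs(mean(n_events) - 2), 3 * se)   # total tree length x rate

  expect_error(simulate_evolution(cherry, rate_params(1, 0, n_trait_levels = 1),
                                  space, c(31, 0), seed = 1), "root_state")
})

test_that("wing loss is irreversible in simulation and event logs replay exactly", {
  space <- build_state_space(1, 25, 2)
  pars <- rate_params(c(2, 1), c(1, 0.5), c(0.2, 0.1), q_loss = 1.5,
                      q_gain = 0, n_trait_levels = 2)
  for (s in 1:10) {
    tree <- simulate_yule_tree(15, 1, seed = 400 + s)
    sim <- simulate_evolution(tree, pars, space, c(10, 1), seed = 500 + s)
    expect_false(any(sim$event_log$type == "gain"))
    # once wingless on a path, never winged again: replay checks lineage order
    replayed <- replay_event_log(tree, sim$event_log,
                                 c(10, 1))
    expect_equal(replayed$count, sim$tip_states$count)
    expect_equal(replayed$trait, sim$tip_states$trait)
  }
})

test_that("genus-level wing-probability imputation", {
  sp_names <- c(paste0("cal", 1:25), "cal_unknown", "poly1", "lone")
  status <- c(rep("wingless", 16), rep("winged", 9), "unknown",
              "polymorphic", "wingless")
  names(status) <- sp_names
  genus <- c(rep("Calathus", 26), "Poly", "Lone")
  names(genus) <- sp_names
  p <- impute_wing_probability(status, genus)
  expect_equal(unname(p["cal_unknown"]), 0.64)
  expect_equal(unname(p["poly1"]), 0.5)
  expect_equal(unname(p["lone"]), 1)

  status2 <- c(a = "unknown", b = "wingless")
  genus2 <- c(a = "G1", b = "G2")
  expect_error(impute_wing_probability(status2, genus2), "a")

  # polymorphic congeners count one half
  status3 <- c(x1 = "wingless", x2 = "polymorphic", x3 = "unknown")
  genus3 <- c(x1 = "G", x2 = "G", x3 = "G")
  expect_equal(unname(impute_wing_probability(status3, genus3)["x3"]), 0.75)
})

test_that("synthetic studies allocate multi-count tips exactly and reproduce byte-for-byte", {
  cfg <- study_config(n_tips = 100, n_trees = 5, frac_multicount = 0.1,
                      seed = 31)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  unlink(c(d1, d2), recursive = TRUE)
  st <- make_synthetic_study(cfg, dir = d1)
  make_synthetic_study(cfg, dir = d2)

  n_counts <- vapply(st$tips, function(tp) length(tp$counts), integer(1))
  expect_equal(sum(n_counts == 2), 10L)
  expect_equal(sum(n_counts > 2), 0L)

  for (f in c("trees.nwk", "tips.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # fixture reads back into fit-ready objects
  study <- read_study(d1)
  expect_equal(length(study$trees), 5L)
  expect_equal(length(study$tips), 100L)
  expect_equal(study$truth$rates_unit$gamma, cfg$gamma)
  p <- vapply(study$tips, `[[`, numeric(1), "p_wingless")
  expect_true(all(p >= 0 & p <= 1))
  expect_true(any(p > 0 & p < 1))   # some imputed probabilistic tips
})
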