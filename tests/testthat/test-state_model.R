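test_that("state space construction, size, and index bijection", {
  sp <- build_state_space(3, 34, 2)
  expect_equal(sp$size, 64L)
  expect_equal(build_state_space(1, 1, 1)$size, 1L)
  expect_error(build_state_space(5, 4, 1), "max_count")
  expect_error(build_state_space(0, 4, 1), "min_count")
  expect_error(build_state_space(1, 4, 3), "trait_levels")

  for (ntl in 1:2) {
    sp <- build_state_space(2, 9, ntl)
    for (idx in seq_len(sp$size)) {
      st <- state_of(sp, idx)
      expect_identical(state_index(sp, st$count, st$trait), idx)
    }
    expect_error(state_index(sp, 10), "bounds")
  }
})

test_that("Q matrix matches hand-derived transition rules", {
  sp <- build_state_space(1, 3, 1)
  Q <- build_q_matrix(sp, rate_params(gamma = 1, delta = 0.5))
  expect_equal(Q["2", "3"], 1)
  expect_equal(Q["2", "1"], 0.5)
  expect_equal(Q["2", "2"], -1.5)
  # at the upper bound the fission move is dropped, not rerouted
  expect_equal(Q["3", "3"], -0.5)

  # fission and WGD coincide on the same target from count 1
  Q2 <- build_q_matrix(sp, rate_params(gamma = 1, delta = 0, rho = 0.2))
  expect_equal(Q2["1", "2"], 1.2)

  expect_equal(unclass(build_q_matrix(sp, rate_params(0, 0, 0))),
               matrix(0, 3, 3, dimnames = list(sp$labels, sp$labels)),
               ignore_attr = TRUE)

  expect_error(rate_params(gamma = -1, delta = 0), "gamma")
  expect_error(build_q_matrix(build_state_space(1, 3, 2),
                              rate_params(1, 1, n_trait_levels = 1)),
               "trait level")
})

test_that("Q rows sum to zero and only permitted transitions are nonzero", {
  set.seed(11)
  for (rep in 1:20) {
    ntl <- sample(1:2, 1)
    sp <- build_state_space(sample(1:4, 1), sample(6:12, 1), ntl)
    pars <- rate_params(runif(ntl, 0, 3), runif(ntl, 0, 3), runif(ntl, 0, 2),
                        q_loss = if (ntl == 2) runif(1) else 0,
                        q_gain = if (ntl == 2) runif(1) else 0,
                        n_trait_levels = ntl)
    Q <- build_q_matrix(sp, pars)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_true(all(Q[upper.tri(Q) | lower.tri(Q)] >= 0))
    for (i in seq_len(sp$size)) {
      si <- state_of(sp, i)
      for (j in seq_len(sp$size)) {
        if (i == j || Q[i, j] == 0) next
        sj <- state_of(sp, j)
        allowed <- (sj$trait == si$trait &&
                      sj$count %in% c(si$count + 1L, si$count - 1L, 2L * si$count)) ||
                   (sj$count == si$count && sj$trait != si$trait)
        expect_true(allowed)
      }
    }
  }
})

test_that("transition probabilities: identity at t = 0, series at small t, stationarity at large t", {
  sp <- build_state_space(1, 3, 1)
  Q <- build_q_matrix(sp, rate_params(gamma = 1, delta = 0.5))
  expect_equal(unname(unclass(transition_probabilities(Q, 0))), diag(3))

  t <- 0.01
  P <- transition_probabilities(Q, t)
  approx2 <- diag(3) + unclass(Q) * t
  expect_lt(max(abs(unclass(P) - approx2)), 10 * t^2 * max(abs(Q))^2)

  Pinf <- transition_probabilities(Q, 1000)
  pi_hat <- oracle_stationary(Q)
  for (r in 1:3) expect_lt(max(abs(Pinf[r, ] - pi_hat)), 1e-6)
  expect_lt(max(abs(sweep(unclass(Pinf), 2, Pinf[1, ]))), 1e-6)

  expect_error(transition_probabilities(Q, -1), ">= 0")
})

test_that("probability matrices are stochastic and match an independent series oracle", {
  set.seed(21)
  for (rep in 1:10) {
    ntl <- sample(1:2, 1)
    sp <- build_state_space(2, sample(4:7, 1), ntl)
    Q <- build_q_matrix(sp, rate_params(runif(ntl, 0, 2), runif(ntl, 0, 2),
                                        runif(ntl, 0, 1),
                                        q_loss = if (ntl == 2) runif(1) else 0,
                                        n_trait_levels = ntl))
    t <- runif(1, 0, 3)
    P <- transition_probabilities(Q, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1))
    expect_lt(max(abs(unclass(P) - oracle_expm(unclass(Q), t))), 1e-9)
  }
})

test_that("counts cannot decrease without fusions, and wings cannot be regained", {
  sp <- build_state_space(2, 8, 1)
  Q <- build_q_matrix(sp, rate_params(gamma = 1.3, delta = 0, rho = 0.4))
  for (t in c(0.1, 1, 5)) {
    P <- transition_probabilities(Q, t)
    for (i in seq_len(sp$size)) {
      below <- which(state_of(sp, seq_len(sp$size))$count <
                       state_of(sp, i)$count)
      if (length(below)) expect_equal(max(P[i, below]), 0)
    }
  }

  sp2 <- build_state_space(2, 6, 2)
  Q2 <- build_q_matrix(sp2, rate_params(c(1, 1), c(0.5, 0.5), q_loss = 0.7,
                                        q_gain = 0, n_trait_levels = 2))
  P2 <- transition_probabilities(Q2, 2)
  states <- state_of(sp2, seq_len(sp2$size))
  wingless <- which(states$trait == 0L)
  winged <- which(states$trait == 1L)
  expect_equal(max(P2[wingless, winged]), 0)
})

test_that("relabelling trait levels permutes the Q matrix", {
  sp <- build_state_space(2, 6, 2)
  pars <- rate_params(c(1.5, 0.5), c(0.7, 0.2), c(0.1, 0.3),
                      q_loss = 0.4, q_gain = 0.25, n_trait_levels = 2)
  swapped <- rate_params(rev(pars$gamma), rev(pars$delta), rev(pars$rho),
                         q_loss = pars$q_gain, q_gain = pars$q_loss,
                         n_trait_levels = 2)
  Q <- build_q_matrix(sp, pars)
  Qs <- build_q_matrix(sp, swapped)
  states <- state_of(sp, seq_len(sp$size))
  perm <- state_index(sp, states$count, 1L - states$trait)
  as_plain <- function(x) matrix(as.numeric(x), nrow(x))
  expect_equal(as_plain(Q), as_plain(unclass(Qs)[perm, perm]))
})

test_that("default state-space bounds bracket the data without exploding", {
  sp <- default_state_space(c(5, 9, 12))
  expect_equal(sp$min_count, 4L)
  expect_equal(sp$max_count, 24L)
  expect_equal(default_state_space(c(1, 30))$min_count, 1L)
  expect_equal(default_state_space(c(1, 30))$max_count, 50L)
})
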