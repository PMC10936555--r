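# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the matrix exponential is a hand-written
# scaling-and-squaring Taylor series, and the tree likelihood is a direct
# summation over all interior-node state assignments.

# exp(A) by scaling and squaring with a truncated Taylor series
oracle_expm <- function(A, t = 1) {
  A <- A * t
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  B <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:30) {
    term <- term %*% B / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# Log-likelihood by explicit summation over every assignment of states to
# interior nodes (feasible for <= 3 tips). Combines root partials the same
# way as the requested root mode, but the per-state partials themselves come
# from brute-force enumeration.
oracle_loglik <- function(tree, tip_vectors, Q, root_mode = "flat") {
  k <- nrow(Q)
  phy <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(phy$tip.label)
  n_int <- phy$Nnode
  Pmats <- lapply(seq_len(nrow(phy$edge)),
                  function(e) oracle_expm(unclass(Q), phy$edge.length[e]))
  int_nodes <- n_tip + seq_len(n_int)
  grids <- expand.grid(rep(list(seq_len(k)), n_int))
  partial_root <- numeric(k)
  for (g in seq_len(nrow(grids))) {
    assign_int <- as.integer(grids[g, ])
    names(assign_int) <- int_nodes
    w <- 1
    for (e in seq_len(nrow(phy$edge))) {
      par_state <- assign_int[as.character(phy$edge[e, 1L])]
      chd <- phy$edge[e, 2L]
      if (chd <= n_tip) {
        w <- w * sum(Pmats[[e]][par_state, ] * tip_vectors[[phy$tip.label[chd]]])
      } else {
        w <- w * Pmats[[e]][par_state, assign_int[as.character(chd)]]
      }
    }
    r <- assign_int[as.character(n_tip + 1L)]
    partial_root[r] <- partial_root[r] + w
  }
  # enumeration multiplies over interior nodes including the root, so each
  # root state's partial is isolated; non-root interiors were summed out by
  # the grid sum
  d <- partial_root
  val <- switch(root_mode,
    flat = mean(d),
    obs_weighted = sum(d^2) / sum(d)
  )
  log(val)
}

# stationary distribution of a rate matrix from the null space of t(Q)
oracle_stationary <- function(Q) {
  Qm <- unclass(Q)
  ev <- eigen(t(Qm))
  i <- which.min(abs(ev$values))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

# batch-means Monte Carlo standard error for a (possibly autocorrelated) chain
batch_se <- function(x, n_batches = 50L) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1L) * bs + 1L):(b * bs)]),
                  numeric(1L))
  stats::sd(means) / sqrt(n_batches)
}

# brute-force Kendall tau over all pairs, plus exact permutation p-value
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc_stat <- function(yy) {
    s <- 0
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- s + sign(x[j] - x[i]) * sign(yy[j] - yy[i])
      }
    }
    s
  }
  s_obs <- conc_stat(y)
  tau <- s_obs / choose(n, 2)
  perms <- gtools_permutations(n)
  stats <- apply(perms, 1L, function(p) conc_stat(y[p]))
  p_val <- mean(abs(stats) >= abs(s_obs))
  list(tau = tau, p_value = p_val)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

# replay an event log from the root and return the implied tip states
replay_event_log <- function(tree, event_log, root_state) {
  phy <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(phy$tip.label)
  cnt <- integer(n_tip + phy$Nnode); trt <- integer(n_tip + phy$Nnode)
  cnt[n_tip + 1L] <- root_state[1L]; trt[n_tip + 1L] <- root_state[2L]
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; chd <- phy$edge[e, 2L]
    ct <- cnt[par]; tr <- trt[par]
    evs <- event_log[event_log$edge == e, , drop = FALSE]
    if (nrow(evs)) {
      evs <- evs[order(evs$time), , drop = FALSE]
      for (r in seq_len(nrow(evs))) {
        stopifnot(evs$from_count[r] == ct, evs$from_trait[r] == tr)
        ct <- evs$to_count[r]; tr <- evs$to_trait[r]
      }
    }
    cnt[chd] <- ct; trt[chd] <- tr
  }
  data.frame(species = phy$tip.label, count = cnt[seq_len(n_tip)],
             trait = trt[seq_len(n_tip)])
}

random_small_case <- function(seed) {
  set.seed(seed)
  n_tip <- sample(2:3, 1L)
  tree <- ape::rcoal(n_tip)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree)) *
    stats::runif(1L, 0.3, 2)
  two_traits <- stats::runif(1L) < 0.5
  n_counts <- sample(2:4, 1L)
  span <- n_counts - 1L
  mn <- sample(1:5, 1L)
  space <- build_state_space(mn, mn + span, if (two_traits) 2L else 1L)
  if (space$size > 8L) space <- build_state_space(mn, mn + 2L, space$n_trait_levels)
  pars <- rate_params(
    gamma = stats::runif(space$n_trait_levels, 0, 2),
    delta = stats::runif(space$n_trait_levels, 0, 2),
    rho = stats::runif(space$n_trait_levels, 0, 1),
    q_loss = if (two_traits) stats::runif(1L, 0, 1) else 0,
    q_gain = if (two_traits) stats::runif(1L, 0, 0.5) else 0,
    n_trait_levels = space$n_trait_levels
  )
  Q <- build_q_matrix(space, pars)
  tip_vectors <- lapply(tree$tip.label, function(lb) {
    ct <- sample(space$min_count:space$max_count, 1L)
    tip_likelihood_vector(
      tip_data(lb, ct, if (two_traits) stats::runif(1L) else NA_real_),
      ct, space
    )
  })
  names(tip_vectors) <- tree$tip.label
  list(tree = tree, space = space, Q = Q, tip_vectors = tip_vectors)
}
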