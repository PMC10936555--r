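#' Rate parameters of the chromosome-number model
#'
#' Bundles the per-trait-level rates of the model: fission (`gamma`,
#' count i -> i + 1), fusion (`delta`, i -> i - 1) and whole-genome
#' duplication (`rho`, i -> 2i), plus the trait transition rates `q_loss`
#' (winged -> wingless) and `q_gain` (wingless -> winged, 0 by default so
#' wing loss is irreversible). For one-trait-level (clade) models supply
#' scalars; for two-level models length-2 vectors ordered
#' (wingless, winged). Scalars are recycled.
#'
#' @param gamma fission rate(s), per unit tree length.
#' @param delta fusion rate(s).
#' @param rho whole-genome-duplication rate(s); 0 disables WGD.
#' @param q_loss winged -> wingless transition rate.
#' @param q_gain wingless -> winged transition rate (default 0).
#' @param n_trait_levels 1 or 2; inferred from the rate vectors if omitted.
#' @return an object of class `rate_params`.
#' @export
rate_params <- function(gamma, delta, rho = 0, q_loss = 0, q_gain = 0,
                        n_trait_levels = NULL) {
  if (is.null(n_trait_levels)) {
    n_trait_levels <- max(length(gamma), length(delta), length(rho))
  }
  if (!(n_trait_levels %in% c(1L, 2L))) stop("n_trait_levels must be 1 or 2")
  rec <- function(x, nm) {
    if (!length(x) %in% c(1L, n_trait_levels)) {
      stop(nm, " must have length 1 or ", n_trait_levels)
    }
    x <- rep_len(as.numeric(x), n_trait_levels)
    if (any(!is.finite(x)) || any(x < 0)) stop(nm, " must be finite and >= 0")
    x
  }
  q_chk <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 0) stop(nm, " must be a single rate >= 0")
    as.numeric(x)
  }
  structure(
    list(
      gamma = rec(gamma, "gamma"),
      delta = rec(delta, "delta"),
      rho = rec(rho, "rho"),
      q_loss = q_chk(q_loss, "q_loss"),
      q_gain = q_chk(q_gain, "q_gain"),
      n_trait_levels = as.integer(n_trait_levels)
    ),
    class = "rate_params"
  )
}

# Enumerate the moves leaving state (count, trait): targets, rates, and move
# type. Moves whose target count falls outside the space are dropped (no mass
# rerouted to the boundary); this single helper backs both the Q matrix and
# the stochastic simulator so the two describe the same bounded process.
# Returns plain parallel vectors (hot path).
ctmc_moves <- function(count, trait, params, space) {
  lv <- trait + 1L
  cand_count <- c(count + 1L, count - 1L, 2L * count)
  cand_trait <- c(trait, trait, trait)
  cand_rate <- c(params$gamma[lv], params$delta[lv], params$rho[lv])
  cand_type <- c("fission", "fusion", "wgd")
  if (space$n_trait_levels == 2L) {
    cand_count <- c(cand_count, count)
    cand_trait <- c(cand_trait, 1L - trait)
    cand_rate <- c(cand_rate, if (trait == 1L) params$q_loss else params$q_gain)
    cand_type <- c(cand_type, if (trait == 1L) "loss" else "gain")
  }
  keep <- cand_rate > 0 & cand_count >= space$min_count &
    cand_count <= space$max_count
  list(count = cand_count[keep], trait = cand_trait[keep],
       rate = cand_rate[keep], type = cand_type[keep])
}

#' Build the instantaneous rate matrix of the chromosome-number model
#'
#' From state (i, s) the permitted transitions are: fission to (i+1, s) at
#' rate `gamma[s]`, fusion to (i-1, s) at rate `delta[s]`, whole-genome
#' duplication to (2i, s) at rate `rho[s]`, and a trait flip at constant
#' count at rate `q_loss` (winged -> wingless) or `q_gain`. Transitions
#' whose target count leaves the state space are dropped, so their rate is
#' simply absent from the exit rate (the diagonal); widen the space if this
#' boundary behaviour matters for your data. When `2i == i + 1` (i.e. i = 1)
#' the fission and duplication rates add on the shared target entry.
#'
#' @param space a [build_state_space()] object.
#' @param params a [rate_params()] object with matching trait levels.
#' @return a `space$size` x `space$size` matrix of class `q_matrix` with the
#'   state space attached as attribute `"space"`; rows sum to zero.
#' @examples
#' sp <- build_state_space(1, 3, 1)
#' build_q_matrix(sp, rate_params(gamma = 1, delta = 0.5))
#' @export
build_q_matrix <- function(space, params) {
  stopifnot(inherits(space, "state_space"), inherits(params, "rate_params"))
  if (space$n_trait_levels != params$n_trait_levels) {
    stop("state space has ", space$n_trait_levels,
         " trait level(s) but rate_params has ", params$n_trait_levels)
  }
  k <- space$size
  Q <- matrix(0, k, k, dimnames = list(space$labels, space$labels))
  ntl <- space$n_trait_levels
  for (idx in seq_len(k)) {
    idx0 <- idx - 1L
    ct <- space$min_count + idx0 %/% ntl
    tr <- idx0 %% ntl
    mv <- ctmc_moves(ct, tr, params, space)
    if (length(mv$rate)) {
      j <- (mv$count - space$min_count) * ntl + mv$trait + 1L
      for (m in seq_along(j)) Q[idx, j[m]] <- Q[idx, j[m]] + mv$rate[m]
      Q[idx, idx] <- -sum(Q[idx, -idx])
    }
  }
  attr(Q, "space") <- space
  class(Q) <- c("q_matrix", class(Q))
  Q
}

# Propagator for exp(Q t) acting on conditional-likelihood vectors.
# Primary path: one eigendecomposition per likelihood call, then two
# matrix-vector products per branch; accepted only if it reconstructs Q to
# ~1e-10 relative (eigenvector conditioning degrades on large spaces).
# Fallback for vector products: uniformization, i.e. the Poisson-weighted
# series exp(-Lt) sum_k (Lt)^k/k! P^k v with P = I + Q/L, which is
# unconditionally stable for the moderate L*t of tree branches. Full-matrix
# requests fall back to Matrix::expm. Results do not depend on the path
# taken beyond ~1e-11.
ctmc_propagator <- function(Q) {
  Qm <- unclass(Q)
  attr(Qm, "space") <- NULL
  dimnames(Qm) <- NULL
  k <- nrow(Qm)
  eg <- tryCatch(eigen(Qm), error = function(e) NULL)
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      err <- max(Mod(eg$vectors %*% (eg$values * Vi) - Qm))
      if (err < 1e-10 * max(1, max(abs(Qm)))) {
        V <- eg$vectors; values <- eg$values
        if (max(abs(Im(values))) < 1e-14 && is.double(V)) {
          values <- Re(values)
        }
        return(list(method = "eigen", V = V, Vi = Vi, values = values, n = k))
      }
    }
  }
  lam <- max(-diag(Qm), 0)
  Pu <- Qm / max(lam, .Machine$double.xmin)
  diag(Pu) <- diag(Pu) + 1
  list(method = "unif", Q = Qm, Pu = Pu, lam = lam, n = k,
       cache = new.env(parent = emptyenv()))
}

unif_apply <- function(prop, t, v, tol = 1e-13) {
  lt <- prop$lam * t
  if (lt == 0) return(v)
  w <- exp(-lt)
  acc <- w * v
  x <- v
  k <- 0L
  while (k < 100000L) {
    k <- k + 1L
    x <- prop$Pu %*% x
    w <- w * lt / k
    acc <- acc + w * x
    if (w < tol && k > lt) break
  }
  drop(acc)
}

prop_matrix <- function(prop, t) {
  if (t == 0) return(diag(prop$n))
  if (prop$method == "eigen") {
    P <- Re(prop$V %*% (exp(prop$values * t) * prop$Vi))
  } else {
    key <- format(t, digits = 17)
    P <- prop$cache[[key]]
    if (is.null(P)) {
      P <- as.matrix(Matrix::expm(prop$Q * t))
      prop$cache[[key]] <- P
    }
  }
  P[P < 0] <- 0
  P
}

prop_apply <- function(prop, t, v) {
  if (t == 0) return(v)
  if (prop$method == "eigen") {
    x <- Re(prop$V %*% (exp(prop$values * t) * (prop$Vi %*% v)))
    x[x < 0] <- 0
    drop(x)
  } else if (prop$lam * t < 700) {
    x <- unif_apply(prop, t, v)
    x[x < 0] <- 0
    x
  } else {
    drop(prop_matrix(prop, t) %*% v)
  }
}

# Batched propagation: columns of X are conditional-likelihood vectors, each
# with its own branch length. One BLAS-3 pass per series term (or per
# eigen projection) replaces per-edge matrix-vector products.
prop_apply_batch <- function(prop, tvec, X) {
  if (prop$method == "eigen") {
    E <- exp(outer(prop$values, tvec))
    Y <- Re(prop$V %*% (E * (prop$Vi %*% X)))
  } else if (max(prop$lam * tvec) < 700) {
    lt <- prop$lam * tvec
    ns <- nrow(X)
    w <- exp(-lt)
    Y <- X * rep(w, each = ns)
    Z <- X
    k <- 0L
    lt_max <- max(lt)
    repeat {
      k <- k + 1L
      Z <- prop$Pu %*% Z
      w <- w * lt / k
      Y <- Y + Z * rep(w, each = ns)
      if ((max(w) < 1e-13 && k > lt_max) || k > 100000L) break
    }
  } else {
    Y <- X
    for (j in seq_along(tvec)) Y[, j] <- prop_apply(prop, tvec[j], X[, j])
    return(Y)
  }
  zero <- tvec == 0
  if (any(zero)) Y[, zero] <- X[, zero]
  Y[Y < 0] <- 0
  Y
}

#' Transition probabilities over a branch
#'
#' Computes `exp(Q * t)`, the matrix of state-to-state transition
#' probabilities after time `t` under the instantaneous rate matrix `Q`.
#'
#' @param Q a square rate matrix (rows summing to zero), typically from
#'   [build_q_matrix()].
#' @param t branch length (>= 0), in the same time units as the rates.
#' @return a stochastic matrix: entries in `[0, 1]`, rows summing to 1.
#' @export
transition_probabilities <- function(Q, t) {
  if (!is.matrix(unclass(Q)) || nrow(Q) != ncol(Q)) stop("Q must be square")
  if (length(t) != 1L || !is.finite(t) || t < 0) stop("t must be a single value >= 0")
  P <- prop_matrix(ctmc_propagator(Q), t)
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}
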