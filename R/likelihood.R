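#' Per-species tip data
#'
#' One species' observed chromosome data: one or more male haploid autosome
#' counts (multiple reported counts are treated as equally likely
#' alternatives and resampled per model fit) and, for trait-linked analyses,
#' the probability that the species is wingless (0.5 for species reported as
#' wing-polymorphic; genus-level imputed values such as 0.64 via
#' [impute_wing_probability()]).
#'
#' @param species species label.
#' @param counts nonempty vector of positive integer counts.
#' @param p_wingless probability in `[0, 1]`, or `NA` for count-only data.
#' @return an object of class `tip_data`.
#' @export
tip_data <- function(species, counts, p_wingless = NA_real_) {
  if (!is.character(species) || length(species) != 1L || !nzchar(species)) {
    stop("species must be a nonempty string")
  }
  counts <- as.numeric(counts)
  if (!length(counts) || any(!is.finite(counts)) || any(counts != round(counts)) ||
      any(counts < 1)) {
    stop("counts for species '", species, "' must be positive integers")
  }
  if (!is.na(p_wingless) && (p_wingless < 0 || p_wingless > 1)) {
    stop("p_wingless for species '", species, "' must be in [0, 1]")
  }
  structure(list(species = species, counts = as.integer(unique(counts)),
                 p_wingless = as.numeric(p_wingless)),
            class = "tip_data")
}

#' Likelihood vector for one tip
#'
#' Places probability mass on the states compatible with the observed data:
#' for a two-trait space, `p_wingless` at (count, wingless) and
#' `1 - p_wingless` at (count, winged); for a count-only space, a one-hot
#' vector at the chosen count.
#'
#' @param tip a [tip_data()] object.
#' @param chosen_count the single count used for this fit (multi-count tips
#'   are resolved upstream by uniform resampling).
#' @param space a [build_state_space()] object.
#' @return a probability vector over the states of `space`, summing to 1.
#' @export
tip_likelihood_vector <- function(tip, chosen_count, space) {
  stopifnot(inherits(tip, "tip_data"), inherits(space, "state_space"))
  if (chosen_count < space$min_count || chosen_count > space$max_count) {
    stop("count ", chosen_count, " for species '", tip$species,
         "' lies outside the state space [", space$min_count, ", ",
         space$max_count, "]")
  }
  v <- numeric(space$size)
  if (space$n_trait_levels == 1L) {
    v[state_index(space, chosen_count)] <- 1
  } else {
    p <- tip$p_wingless
    if (is.na(p)) {
      stop("species '", tip$species,
           "' has no p_wingless but the state space has two trait levels")
    }
    v[state_index(space, chosen_count, 0L)] <- p
    v[state_index(space, chosen_count, 1L)] <- 1 - p
  }
  v
}

tree_depth <- function(tree) {
  n_tip <- length(tree$tip.label)
  max(ape::node.depth.edgelength(tree)[seq_len(n_tip)])
}

check_ultrametric <- function(tree, rel_tol = 1e-6) {
  n_tip <- length(tree$tip.label)
  d <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
  if ((max(d) - min(d)) > rel_tol * max(d)) {
    stop("tree is not ultrametric within relative tolerance ", rel_tol)
  }
  invisible(TRUE)
}

# Precompute everything about a tree the pruning pass needs: postorder
# edges grouped into levels (every edge in a level has a fully resolved
# child), so each level is one batched propagation.
make_pruning_plan <- function(tree) {
  phy <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  parent <- phy$edge[, 1L]
  child <- phy$edge[, 2L]
  pending <- tabulate(parent, nbins = n_node)
  node_ready <- c(rep(TRUE, n_tip), rep(FALSE, phy$Nnode))
  edge_done <- logical(length(parent))
  batches <- list()
  while (!all(edge_done)) {
    b <- which(!edge_done & node_ready[child])
    batches[[length(batches) + 1L]] <- b
    for (j in b) {
      p <- parent[j]
      pending[p] <- pending[p] - 1L
      if (pending[p] == 0L) node_ready[p] <- TRUE
    }
    edge_done[b] <- TRUE
  }
  list(n_tip = n_tip, n_node = n_node, parent = parent, child = child,
       elen = phy$edge.length, batches = batches,
       tip_label = phy$tip.label, root = n_tip + 1L)
}

# Core pruning pass over a plan. tip_mat: k x n_tip matrix of tip
# likelihood vectors in plan tip order.
prune_ll_core <- function(plan, tip_mat, prop, root_mode, root_state = NULL) {
  k <- nrow(tip_mat)
  partial <- matrix(1, k, plan$n_node)
  partial[, seq_len(plan$n_tip)] <- tip_mat
  log_scale <- 0
  for (b in plan$batches) {
    X <- partial[, plan$child[b], drop = FALSE]
    Y <- prop_apply_batch(prop, plan$elen[b], X)
    s <- colSums(Y)
    if (any(!is.finite(s) | s <= 0)) {
      bad <- b[which(!is.finite(s) | s <= 0)[1L]]
      stop("non-finite or zero partial likelihood on the branch above node ",
           plan$child[bad], " (length ", plan$elen[bad], ")")
    }
    log_scale <- log_scale + sum(log(s))
    Y <- Y * rep(1 / s, each = k)
    for (j in seq_along(b)) {
      p <- plan$parent[b[j]]
      partial[, p] <- partial[, p] * Y[, j]
    }
  }
  d <- partial[, plan$root]
  val <- switch(root_mode,
    flat = mean(d),
    obs_weighted = sum(d^2) / sum(d),
    fixed = d[root_state]
  )
  if (!is.finite(val) || val < 0) stop("non-finite likelihood at the root")
  log(val) + log_scale
}

#' Pruning log-likelihood of tip data on a tree
#'
#' Felsenstein's pruning algorithm: conditional likelihood vectors are
#' propagated from the tips to the root through per-branch transition
#' probabilities `exp(Q t)` and combined at the root according to
#' `root_mode`. Partial vectors are rescaled at every edge so long trees do
#' not underflow.
#'
#' @param tree a rooted `phylo` tree with nonnegative branch lengths.
#' @param tip_vectors named list mapping every tip label of `tree` to a
#'   likelihood vector over the states of `Q`'s space (see
#'   [tip_likelihood_vector()]).
#' @param Q rate matrix from [build_q_matrix()].
#' @param root_mode how root partials `d_r` are combined: `"obs_weighted"`
#'   (default; weights proportional to the partials themselves, i.e.
#'   `sum(d^2)/sum(d)`), `"flat"` (mean over states), or `"fixed"` (the
#'   partial of `root_state`).
#' @param root_state state index (or label) used when `root_mode = "fixed"`.
#' @return the log-likelihood (a single real number).
#' @export
prune_log_likelihood <- function(tree, tip_vectors, Q,
                                 root_mode = c("obs_weighted", "flat", "fixed"),
                                 root_state = NULL) {
  root_mode <- match.arg(root_mode)
  stopifnot(inherits(tree, "phylo"))
  k <- nrow(Q)
  n_tip <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, names(tip_vectors))
  if (length(missing)) {
    stop("no tip likelihood vector for: ", paste(missing, collapse = ", "))
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (root_mode == "fixed") {
    if (is.null(root_state)) stop("root_mode = 'fixed' needs root_state")
    if (is.character(root_state)) {
      root_state <- match(root_state, rownames(Q))
      if (is.na(root_state)) stop("unknown root state label")
    }
  }
  plan <- make_pruning_plan(tree)
  tip_mat <- matrix(0, k, n_tip)
  for (i in seq_len(n_tip)) {
    v <- tip_vectors[[plan$tip_label[i]]]
    if (length(v) != k) {
      stop("tip vector for '", plan$tip_label[i], "' has length ", length(v),
           ", expected ", k)
    }
    tip_mat[, i] <- v
  }
  prune_ll_core(plan, tip_mat, ctmc_propagator(Q), root_mode, root_state)
}

#' Drop tree tips that lack karyotype data
#'
#' Species present in the tree but absent from the tip table cannot inform
#' the model and are pruned before analysis, with a warning listing them.
#'
#' @param tree a `phylo` tree.
#' @param species character vector of species with data.
#' @return the pruned tree.
#' @export
drop_unscored_tips <- function(tree, species) {
  extra <- setdiff(tree$tip.label, species)
  if (!length(extra)) return(tree)
  if (length(extra) >= length(tree$tip.label) - 1L) {
    stop("fewer than 2 tree tips have data")
  }
  warning("pruning ", length(extra), " tree tip(s) without data: ",
          paste(utils::head(extra, 5L), collapse = ", "),
          if (length(extra) > 5L) ", ..." else "")
  ape::drop.tip(tree, extra)
}
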