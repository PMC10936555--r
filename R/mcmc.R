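#' MCMC configuration
#'
#' Settings for the Bayesian fit. Defaults follow the sampling protocol the
#' package is built around: chains initialised from uniform(0, 10) draws,
#' an exponential prior with rate 2 on every free rate, 200 generations per
#' tree with the first 100 discarded as burnin, and trees rescaled to unit
#' root-to-tip depth during fitting (reported rates are converted back to
#' per-million-year units using each tree's own depth).
#'
#' @param model one of `"trait_full"` (per-trait fission/fusion/WGD plus
#'   wing loss), `"trait_noWGD"` (WGD rate fixed at zero), `"clade_2p"`
#'   (count-only fission + fusion) or `"clade_3p"` (count-only fission +
#'   fusion + WGD).
#' @param n_generations generations per tree (one generation = one slice
#'   update of every free parameter).
#' @param burnin generations discarded per tree when pooling.
#' @param prior_rate rate of the exponential prior on each free parameter,
#'   on the fitting (unit-tree) scale. The value 2 reads the conventional
#'   "exponential with shape parameter 2" as rate 2 (mean 0.5); set it
#'   yourself if you prefer the mean-2 reading.
#' @param init_low,init_high bounds of the uniform initialisation.
#' @param slice_width initial bracket width of the slice sampler.
#' @param seed integer master seed; per-tree seeds are `seed + tree index`.
#' @param trait_reversible if `TRUE`, wing gain (`q_gain`) is a free
#'   parameter; by default wings can be lost but not regained.
#' @param tree_scale `"unit_depth"` (default; root-to-tip depth scaled to
#'   1), `"unit_length"` (total branch length scaled to 1) or `"none"`
#'   (fit on the branch lengths as given).
#' @param root_mode passed to [prune_log_likelihood()].
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(model = c("trait_full", "trait_noWGD", "clade_2p", "clade_3p"),
                        n_generations = 200L, burnin = 100L, prior_rate = 2,
                        init_low = 0, init_high = 10, slice_width = 1,
                        seed = 1L, trait_reversible = FALSE,
                        tree_scale = c("unit_depth", "unit_length", "none"),
                        root_mode = c("obs_weighted", "flat", "fixed")) {
  model <- match.arg(model)
  tree_scale <- match.arg(tree_scale)
  root_mode <- match.arg(root_mode)
  n_generations <- as.integer(n_generations)
  burnin <- as.integer(burnin)
  if (n_generations < 1L) stop("n_generations must be >= 1")
  if (burnin < 0L || burnin >= n_generations) {
    stop("burnin must satisfy 0 <= burnin < n_generations")
  }
  if (!is.finite(prior_rate) || prior_rate <= 0) stop("prior_rate must be > 0")
  if (!(init_low < init_high)) stop("init_low must be < init_high")
  if (!is.finite(slice_width) || slice_width <= 0) stop("slice_width must be > 0")
  structure(list(model = model, n_generations = n_generations, burnin = burnin,
                 prior_rate = prior_rate, init_low = init_low,
                 init_high = init_high, slice_width = slice_width,
                 seed = as.integer(seed), trait_reversible = isTRUE(trait_reversible),
                 tree_scale = tree_scale, root_mode = root_mode),
            class = "mcmc_config")
}

#' Free parameters of each model
#'
#' @param model model name as in [mcmc_config()].
#' @param trait_reversible whether wing gain is free.
#' @return character vector of free parameter names, in update order.
#' @export
free_param_names <- function(model, trait_reversible = FALSE) {
  switch(model,
    clade_2p = c("gamma", "delta"),
    clade_3p = c("gamma", "delta", "rho"),
    trait_noWGD = c("gamma_wingless", "gamma_winged",
                    "delta_wingless", "delta_winged", "q_loss",
                    if (trait_reversible) "q_gain"),
    trait_full = c("gamma_wingless", "gamma_winged",
                   "delta_wingless", "delta_winged",
                   "rho_wingless", "rho_winged", "q_loss",
                   if (trait_reversible) "q_gain"),
    stop("unknown model: ", model)
  )
}

params_from_vector <- function(model, x, trait_reversible = FALSE) {
  nm <- free_param_names(model, trait_reversible)
  names(x) <- nm
  if (model %in% c("clade_2p", "clade_3p")) {
    rate_params(gamma = x[["gamma"]], delta = x[["delta"]],
                rho = if (model == "clade_3p") x[["rho"]] else 0,
                n_trait_levels = 1L)
  } else {
    rate_params(gamma = c(x[["gamma_wingless"]], x[["gamma_winged"]]),
                delta = c(x[["delta_wingless"]], x[["delta_winged"]]),
                rho = if (model == "trait_full") {
                  c(x[["rho_wingless"]], x[["rho_winged"]])
                } else 0,
                q_loss = x[["q_loss"]],
                q_gain = if (trait_reversible) x[["q_gain"]] else 0,
                n_trait_levels = 2L)
  }
}

#' Log prior density of the free parameters
#'
#' Independent exponential priors (rate `prior_rate`) on every free
#' parameter. Negative values return `-Inf` (a rejected state), not an
#' error, so samplers can evaluate freely.
#'
#' @param params numeric vector of free parameter values.
#' @param prior_rate exponential rate (> 0).
#' @return the summed log density.
#' @export
log_prior <- function(params, prior_rate = 2) {
  if (!is.finite(prior_rate) || prior_rate <= 0) stop("prior_rate must be > 0")
  params <- as.numeric(params)
  if (any(!is.finite(params)) || any(params < 0)) return(-Inf)
  sum(stats::dexp(params, rate = prior_rate, log = TRUE))
}

# One univariate slice-sampling update (Neal 2003, step-out + shrinkage),
# on [0, Inf). f must return the log target; fx0 = f(x0) is passed in so a
# sweep costs one evaluation per proposal, not per parameter.
slice_update1 <- function(x0, f, fx0, w, max_steps = 1000L) {
  y <- fx0 - stats::rexp(1L)
  u <- stats::runif(1L)
  L <- x0 - w * u
  R <- L + w
  if (L < 0) {
    L <- 0
  } else {
    k <- max_steps
    while (k > 0L && f(L) > y) {
      L <- L - w
      if (L < 0) { L <- 0; break }
      k <- k - 1L
    }
  }
  k <- max_steps
  while (k > 0L && f(R) > y) {
    R <- R + w
    k <- k - 1L
  }
  repeat {
    x1 <- L + stats::runif(1L) * (R - L)
    fx1 <- f(x1)
    if (fx1 >= y) return(list(x = x1, fx = fx1))
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Run one MCMC chain on one tree
#'
#' Fits the chosen model by univariate slice sampling of each free
#' parameter per generation against the log posterior (pruning
#' log-likelihood + exponential log prior). The tree is rescaled according
#' to `config$tree_scale` before fitting; the trace carries each parameter
#' both on the fitting scale and converted to events per million years
#' (fitting-scale rate divided by the scale factor, i.e. by the tree depth
#' in My under the default unit-depth scaling).
#'
#' @param tree rooted ultrametric `phylo` tree, branch lengths in millions
#'   of years (any time unit works; "My" columns are then per that unit).
#' @param tips list of [tip_data()] objects covering every tree tip, each
#'   already resolved to a single count (see [multi_tree_posterior()] for
#'   multi-count resampling).
#' @param space a [build_state_space()] object consistent with the model's
#'   trait levels.
#' @param config an [mcmc_config()].
#' @param tree_id integer tag recorded in the trace.
#' @param tip_vectors optional named list of tip likelihood vectors that
#'   overrides the vectors built from `tips` (useful for calibration runs,
#'   e.g. uniform vectors give a constant likelihood so the chain samples
#'   the prior).
#' @return a `posterior_trace` data.frame with one row per generation
#'   (burnin included): `tree_id`, `gen`, each free parameter on the
#'   fitting scale and as `<name>_my`, `lnL` and `lnPrior`. Identical
#'   seeds give identical traces.
#' @export
run_mcmc <- function(tree, tips, space, config, tree_id = 1L,
                     tip_vectors = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(space, "state_space"),
            inherits(config, "mcmc_config"))
  want_traits <- if (config$model %in% c("trait_full", "trait_noWGD")) 2L else 1L
  if (space$n_trait_levels != want_traits) {
    stop("model '", config$model, "' needs a state space with ", want_traits,
         " trait level(s)")
  }
  if (is.null(tip_vectors)) {
    names(tips) <- vapply(tips, `[[`, character(1L), "species")
    missing <- setdiff(tree$tip.label, names(tips))
    if (length(missing)) {
      stop("no tip data for: ", paste(missing, collapse = ", "))
    }
    tip_vectors <- lapply(tips[tree$tip.label], function(tp) {
      if (length(tp$counts) != 1L) {
        stop("species '", tp$species, "' has ", length(tp$counts),
             " counts; resolve multi-count tips before run_mcmc ",
             "(multi_tree_posterior resamples them per fit)")
      }
      tip_likelihood_vector(tp, tp$counts, space)
    })
  }
  depth_my <- tree_depth(tree)
  scale <- switch(config$tree_scale,
    unit_depth = { check_ultrametric(tree); depth_my },
    unit_length = sum(tree$edge.length),
    none = 1
  )
  fit_tree <- tree
  fit_tree$edge.length <- tree$edge.length / scale

  nm <- free_param_names(config$model, config$trait_reversible)
  p <- length(nm)
  plan <- make_pruning_plan(fit_tree)
  tip_mat <- matrix(0, space$size, plan$n_tip)
  for (i in seq_len(plan$n_tip)) {
    v <- tip_vectors[[plan$tip_label[i]]]
    if (length(v) != space$size) {
      stop("tip vector for '", plan$tip_label[i], "' has length ", length(v),
           ", expected ", space$size)
    }
    tip_mat[, i] <- v
  }
  eval_post <- function(x) {
    lnP <- log_prior(x, config$prior_rate)
    if (!is.finite(lnP)) return(list(lp = -Inf, lnL = -Inf, lnP = lnP))
    pars <- params_from_vector(config$model, x, config$trait_reversible)
    Q <- build_q_matrix(space, pars)
    lnL <- prune_ll_core(plan, tip_mat, ctmc_propagator(Q), config$root_mode)
    list(lp = lnL + lnP, lnL = lnL, lnP = lnP)
  }

  set.seed(config$seed)
  cur <- NULL
  for (try in seq_len(100L)) {
    x <- stats::runif(p, config$init_low, config$init_high)
    x[x < 0] <- 0
    cand <- eval_post(x)
    if (is.finite(cand$lp)) { cur <- cand; break }
  }
  if (is.null(cur)) {
    stop("no finite posterior after 100 initial draws; the state space may ",
         "be too narrow for the observed counts -- widen min/max_count")
  }

  out <- matrix(NA_real_, config$n_generations, 2L * p + 2L)
  for (gen in seq_len(config$n_generations)) {
    for (j in seq_len(p)) {
      fj <- function(v) {
        xx <- x
        xx[j] <- v
        res <- eval_post(xx)
        last_eval <<- res
        res$lp
      }
      last_eval <- cur
      upd <- slice_update1(x[j], fj, cur$lp, config$slice_width)
      x[j] <- upd$x
      cur <- last_eval
    }
    out[gen, ] <- c(x, x / scale, cur$lnL, cur$lnP)
  }
  trace <- data.frame(tree_id = as.integer(tree_id), gen = seq_len(config$n_generations),
                      out, check.names = FALSE)
  colnames(trace) <- c("tree_id", "gen", nm, paste0(nm, "_my"), "lnL", "lnPrior")
  new_posterior_trace(trace, config = config,
                      depths = stats::setNames(depth_my, as.character(tree_id)))
}

#' Construct a posterior trace object
#'
#' Tags a per-generation sample data.frame with the configuration and tree
#' depths it came from. Mostly used internally and by downstream summaries;
#' exposed so traces can be rebuilt from CSV.
#'
#' @param df data.frame with columns `tree_id`, `gen`, the free parameters
#'   (fitting scale and `_my`), `lnL`, `lnPrior`.
#' @param config the [mcmc_config()] used.
#' @param depths named numeric vector of original tree depths (My) by tree id.
#' @return the data.frame with class `posterior_trace` and metadata
#'   attributes `config` and `depths`.
#' @export
new_posterior_trace <- function(df, config, depths) {
  stopifnot(is.data.frame(df), inherits(config, "mcmc_config"))
  structure(df, config = config, depths = depths,
            class = c("posterior_trace", "data.frame"))
}

#' Pooled Bayesian fit across a posterior tree set
#'
#' Replicates the MCMC over a set of trees (typically draws from a
#' phylogenetic posterior): for each tree, every multi-count tip has one
#' count drawn uniformly at random, one chain is run, burnin generations
#' are dropped, and the post-burnin samples are pooled. Per-My rescaling
#' uses each tree's own depth. With 100 trees, 200 generations and burnin
#' 100 the pooled trace has exactly 10,000 rows. Tree tips without data
#' are pruned (with a warning) before fitting.
#'
#' @param trees list of `phylo` trees sharing a tip set.
#' @param tips list of [tip_data()] objects.
#' @param space a [build_state_space()].
#' @param config an [mcmc_config()]; per-tree seeds are
#'   `config$seed + tree index`.
#' @return a pooled `posterior_trace` with
#'   `length(trees) * (n_generations - burnin)` rows.
#' @export
multi_tree_posterior <- function(trees, tips, space, config) {
  if (!length(trees)) stop("need at least one tree")
  names(tips) <- vapply(tips, `[[`, character(1L), "species")
  trees <- lapply(trees, drop_unscored_tips, species = names(tips))
  tipsets <- lapply(trees, function(tr) sort(tr$tip.label))
  if (length(trees) > 1L && !all(vapply(tipsets[-1L], identical, logical(1L), tipsets[[1L]]))) {
    stop("trees do not share a common tip set after pruning")
  }
  pieces <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    seed_i <- config$seed + i
    set.seed(seed_i)
    resolved <- lapply(tips[tipsets[[1L]]], function(tp) {
      ct <- if (length(tp$counts) > 1L) {
        tp$counts[sample.int(length(tp$counts), 1L)]
      } else tp$counts
      tip_data(tp$species, ct, tp$p_wingless)
    })
    cfg_i <- config
    cfg_i$seed <- seed_i
    tr <- run_mcmc(trees[[i]], resolved, space, cfg_i, tree_id = i)
    pieces[[i]] <- tr[tr$gen > config$burnin, , drop = FALSE]
  }
  pooled <- do.call(rbind, lapply(pieces, as.data.frame))
  rownames(pooled) <- NULL
  depths <- do.call(c, lapply(pieces, attr, "depths"))
  new_posterior_trace(pooled, config = config, depths = depths)
}

#' @export
print.posterior_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("posterior_trace:", nrow(x), "samples,", length(unique(x$tree_id)),
      "tree(s), model", cfg$model, "\n")
  invisible(x)
}

#' Write / read a posterior trace as CSV
#'
#' The CSV holds the samples; the configuration is echoed to a JSON sidecar
#' (`<path>.json`) so a trace can be rebuilt exactly.
#'
#' @param trace a `posterior_trace`.
#' @param path CSV path.
#' @return `write_trace()` the path, invisibly; `read_trace()` the rebuilt
#'   `posterior_trace`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  cfg <- attr(trace, "config")
  side <- list(config = unclass(cfg), depths = as.list(attr(trace, "depths")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(mcmc_config, side$config)
  depths <- unlist(side$depths)
  new_posterior_trace(df, config = cfg, depths = depths)
}
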