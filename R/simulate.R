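#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Forward simulation: starting from two lineages at the root, while k
#' lineages are alive the next split arrives after an Exp(k * birth_rate)
#' wait on a uniformly chosen lineage; after the n-th lineage appears one
#' final Exp(n * birth_rate) wait sets the present. The expected root-to-tip
#' depth is therefore `sum(1/(k * birth_rate))` for k = 2..n.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0), per unit time.
#' @param seed integer seed; the same seed gives an identical tree.
#' @return an ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed) {
  if (length(n_tips) != 1L || n_tips != round(n_tips) || n_tips < 2L) {
    stop("n_tips must be an integer >= 2")
  }
  if (!is.finite(birth_rate) || birth_rate <= 0) stop("birth_rate must be > 0")
  n_tips <- as.integer(n_tips)
  set.seed(seed)
  n_edge <- 2L * n_tips - 2L
  edge <- matrix(0L, n_edge, 2L)
  elen <- numeric(n_edge)
  e <- 0L
  next_node <- n_tips + 2L               # root is n_tips + 1
  parent <- rep(n_tips + 1L, 2L)          # active lineages' parent nodes
  start <- c(0, 0)                        # and birth times
  t_now <- 0
  k <- 2L
  while (k < n_tips) {
    t_now <- t_now + stats::rexp(1L, k * birth_rate)
    j <- sample.int(k, 1L)
    m <- next_node
    next_node <- next_node + 1L
    e <- e + 1L
    edge[e, ] <- c(parent[j], m)
    elen[e] <- t_now - start[j]
    parent[j] <- m; start[j] <- t_now
    parent <- c(parent, m); start <- c(start, t_now)
    k <- k + 1L
  }
  t_now <- t_now + stats::rexp(1L, n_tips * birth_rate)
  for (i in seq_len(n_tips)) {
    e <- e + 1L
    edge[e, ] <- c(parent[i], i)
    elen[e] <- t_now - start[i]
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("t", seq_len(n_tips)),
                        Nnode = n_tips - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Perturbed pseudo-posterior tree set
#'
#' Emulates a set of trees drawn from a Bayesian phylogenetic posterior:
#' each replicate multiplies every branch length by independent lognormal
#' noise (median 1, log-sd `sd_log`) and is then re-ultrametrised by a
#' proportional depth correction: every node height is rescaled by
#' `target / m(v)`, where `m(v)` is the depth of the node's deepest
#' descendant tip and the target depth is the replicate's mean perturbed
#' tip depth. The map is monotone along every root-to-tip path, so all
#' branch lengths stay positive, every tip lands exactly at the target
#' depth, and topology is preserved.
#'
#' @param tree ultrametric `phylo` to perturb.
#' @param n_trees number of replicates (>= 1).
#' @param sd_log standard deviation of log branch-length noise (>= 0;
#'   0 returns identical copies).
#' @param seed integer seed.
#' @return list of `phylo` trees.
#' @export
perturb_tree_set <- function(tree, n_trees, sd_log, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (!is.finite(sd_log) || sd_log < 0) stop("sd_log must be >= 0")
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  lapply(seq_len(n_trees), function(i) {
    phy <- post
    phy$edge.length <- phy$edge.length *
      exp(stats::rnorm(length(phy$edge.length), 0, sd_log))
    h <- ape::node.depth.edgelength(phy)          # height below root, per node
    target <- mean(h[seq_len(n_tip)])
    # m(v): deepest descendant-tip height, by postorder accumulation
    m <- h
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1L]; chd <- phy$edge[e, 2L]
      if (m[chd] > m[par]) m[par] <- m[chd]
    }
    H <- h * target / m
    phy$edge.length <- H[phy$edge[, 2L]] - H[phy$edge[, 1L]]
    phy
  })
}

#' Exact stochastic simulation of chromosome evolution along a tree
#'
#' Gillespie simulation of the bounded (count, trait) Markov process: on
#' each branch, waiting times are exponential with the current state's
#' total exit rate and the transition is chosen proportionally to the
#' per-target rates; children inherit the parent branch's end state. Moves
#' whose target count would leave the state space are removed from the
#' exit rate, exactly matching the rate matrix built by
#' [build_q_matrix()].
#'
#' @param tree rooted `phylo`.
#' @param params a [rate_params()].
#' @param space a [build_state_space()] with matching trait levels.
#' @param root_state length-2 integer vector `c(count, trait)` (trait 0 for
#'   count-only spaces).
#' @param seed integer seed.
#' @return list with `tips` (list of [tip_data()]; `p_wingless` is 1 for
#'   wingless tips and 0 for winged tips on two-trait spaces), `tip_states`
#'   (data.frame species/count/trait), `event_log` (data.frame edge, node,
#'   time along the branch, type, from/to count and trait), `root_state`,
#'   `params`, `space`.
#' @export
simulate_evolution <- function(tree, params, space, root_state, seed) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "rate_params"),
            inherits(space, "state_space"))
  if (space$n_trait_levels != params$n_trait_levels) {
    stop("space and params disagree on trait levels")
  }
  rc <- root_state[1L]; rt <- if (length(root_state) > 1L) root_state[2L] else 0L
  if (rc < space$min_count || rc > space$max_count ||
      rt < 0L || rt >= space$n_trait_levels) {
    stop("root_state outside the state space")
  }
  set.seed(seed)
  phy <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  count_at <- integer(n_node); trait_at <- integer(n_node)
  count_at[n_tip + 1L] <- rc; trait_at[n_tip + 1L] <- rt
  ev_edge <- integer(0); ev_node <- integer(0); ev_time <- numeric(0)
  ev_type <- character(0)
  ev_fc <- integer(0); ev_ft <- integer(0); ev_tc <- integer(0); ev_tt <- integer(0)
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; chd <- phy$edge[e, 2L]
    len <- phy$edge.length[e]
    ct <- count_at[par]; tr <- trait_at[par]
    t_at <- 0
    repeat {
      mv <- ctmc_moves(ct, tr, params, space)
      n_mv <- length(mv$rate)
      total <- sum(mv$rate)
      if (total <= 0) break
      w <- stats::rexp(1L, total)
      if (t_at + w > len) break
      t_at <- t_at + w
      j <- if (n_mv == 1L) 1L else sample.int(n_mv, 1L, prob = mv$rate)
      ev_edge <- c(ev_edge, e); ev_node <- c(ev_node, chd)
      ev_time <- c(ev_time, t_at); ev_type <- c(ev_type, mv$type[j])
      ev_fc <- c(ev_fc, ct); ev_ft <- c(ev_ft, tr)
      ev_tc <- c(ev_tc, mv$count[j]); ev_tt <- c(ev_tt, mv$trait[j])
      ct <- mv$count[j]; tr <- mv$trait[j]
    }
    count_at[chd] <- ct; trait_at[chd] <- tr
  }
  event_log <- data.frame(edge = ev_edge, node = ev_node, time = ev_time,
                          type = ev_type, from_count = ev_fc,
                          from_trait = ev_ft, to_count = ev_tc,
                          to_trait = ev_tt, stringsAsFactors = FALSE)
  tip_states <- data.frame(species = phy$tip.label,
                           count = count_at[seq_len(n_tip)],
                           trait = trait_at[seq_len(n_tip)],
                           stringsAsFactors = FALSE)
  tips <- lapply(seq_len(n_tip), function(i) {
    tip_data(tip_states$species[i], tip_states$count[i],
             p_wingless = if (space$n_trait_levels == 2L) {
               as.numeric(tip_states$trait[i] == 0L)
             } else NA_real_)
  })
  list(tips = tips, tip_states = tip_states, event_log = event_log,
       root_state = c(count = rc, trait = rt), params = params, space = space)
}

#' Genus-level imputation of winglessness probabilities
#'
#' Species scored winged or wingless get probability 0 or 1 of being
#' wingless; species reported wing-polymorphic get 0.5; species with no
#' wing data get the fraction of their scored congeners that are wingless
#' (polymorphic congeners counting 0.5). A genus of 16 wingless and 9
#' winged scored species thus imputes 0.64 for its unscored members.
#'
#' @param trait_table named character vector, species -> one of
#'   `"winged"`, `"wingless"`, `"polymorphic"`, `"unknown"`.
#' @param genus_of named character vector, species -> genus, covering every
#'   species in `trait_table`.
#' @return named numeric vector of `p_wingless` per species.
#' @export
impute_wing_probability <- function(trait_table, genus_of) {
  trait_table <- unlist(trait_table)
  genus_of <- unlist(genus_of)
  sp <- names(trait_table)
  if (is.null(sp) || any(!nzchar(sp))) stop("trait_table must be named by species")
  bad <- setdiff(sp, names(genus_of))
  if (length(bad)) stop("no genus for: ", paste(bad, collapse = ", "))
  ok <- trait_table %in% c("winged", "wingless", "polymorphic", "unknown")
  if (!all(ok)) {
    stop("invalid trait status for: ", paste(sp[!ok], collapse = ", "))
  }
  score <- c(winged = 0, wingless = 1, polymorphic = 0.5)
  p <- stats::setNames(rep(NA_real_, length(sp)), sp)
  scored <- trait_table != "unknown"
  p[scored] <- score[trait_table[scored]]
  unknown <- sp[!scored]
  orphans <- character(0)
  for (s in unknown) {
    cong <- sp[scored & genus_of[sp] == genus_of[[s]] & sp != s]
    if (!length(cong)) {
      orphans <- c(orphans, s)
    } else {
      p[s] <- mean(score[trait_table[cong]])
    }
  }
  if (length(orphans)) {
    stop("no scored congener for: ", paste(orphans, collapse = ", "))
  }
  p
}

#' Configuration for a synthetic study
#'
#' Defaults emulate the statistical structure of a family-level beetle
#' karyotype analysis: a 100-tip ultrametric tree with 100 lognormally
#' perturbed pseudo-posterior replicates; true per-unit-depth rates of a
#' plausible magnitude with faster chromosome-number increase in wingless
#' lineages and irreversible wing loss from a winged root; a root count of
#' 15 autosomes with counts bounded in 1..35; one tip in ten carrying two
#' conflicting count reports (the true count and a neighbour); and a
#' quarter of tips with unknown wing state whose probabilities are imputed
#' from pseudo-genus congeners.
#'
#' @param n_tips tips in the tree.
#' @param birth_rate Yule speciation rate (tree later rescaled).
#' @param depth_my root-to-tip depth the tree is scaled to, in My.
#' @param n_trees pseudo-posterior replicates.
#' @param sd_log branch-length noise log-sd for [perturb_tree_set()].
#' @param gamma,delta,rho,q_loss true rates on the unit-depth scale
#'   (length-2 vectors ordered wingless, winged for the chromosome rates).
#' @param root_count,root_trait root state (trait 1 = winged).
#' @param min_count,max_count simulation/state-space bounds.
#' @param frac_multicount fraction of tips given a second, neighbouring
#'   count (deterministic allocation: exactly `round(frac * n_tips)` tips).
#' @param frac_prob_trait fraction of tips whose wing state is withheld and
#'   imputed from congeners.
#' @param genus_size tips per pseudo-genus used for imputation.
#' @param seed integer master seed.
#' @return a list of class `study_config`.
#' @export
study_config <- function(n_tips = 100L, birth_rate = 1, depth_my = 200,
                         n_trees = 100L, sd_log = 0.05,
                         gamma = c(2, 1), delta = c(1, 0.8),
                         rho = c(0.1, 0.05), q_loss = 0.5,
                         root_count = 15L, root_trait = 1L,
                         min_count = 1L, max_count = 35L,
                         frac_multicount = 0.1, frac_prob_trait = 0.25,
                         genus_size = 8L, seed = 1L) {
  if (frac_multicount < 0 || frac_multicount > 1) {
    stop("frac_multicount must be in [0, 1]")
  }
  if (frac_prob_trait < 0 || frac_prob_trait > 1) {
    stop("frac_prob_trait must be in [0, 1]")
  }
  structure(as.list(environment()), class = "study_config")
}

#' Generate a complete synthetic study
#'
#' Builds a self-contained synthetic dataset with known truth: a Yule tree
#' scaled to `depth_my`, a perturbed pseudo-posterior tree set, tip
#' chromosome counts and wing states simulated under the trait-linked
#' model, conflicting second counts for a fixed fraction of tips, and
#' genus-imputed wing probabilities for tips whose state is withheld. If
#' `dir` is given the fixture is written to disk (`trees.nwk` with one
#' Newick per line, `tips.csv`, `truth.json`); identical seeds give
#' byte-identical fixtures.
#'
#' @param config a [study_config()].
#' @param dir optional output directory.
#' @return (invisibly, when writing) a list with `trees`, `tips`,
#'   `tip_table`, `truth` (true rates on unit and per-My scales, root
#'   state, seed, config echo), `event_log`, `space`.
#' @export
make_synthetic_study <- function(config = study_config(), dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  base <- simulate_yule_tree(cfg$n_tips, cfg$birth_rate, seed = cfg$seed)
  base$edge.length <- base$edge.length / tree_depth(base)  # unit depth
  space <- build_state_space(cfg$min_count, cfg$max_count, 2L)
  truth <- rate_params(cfg$gamma, cfg$delta, cfg$rho, q_loss = cfg$q_loss,
                       n_trait_levels = 2L)
  sim <- simulate_evolution(base, truth, space,
                            c(cfg$root_count, cfg$root_trait),
                            seed = cfg$seed + 1L)
  st <- sim$tip_states

  # conflicting literature reports: exactly round(frac * n) tips get the
  # true count plus a neighbouring count (+/- 1, reflected at the bounds)
  set.seed(cfg$seed + 2L)
  n_multi <- round(cfg$frac_multicount * cfg$n_tips)
  multi_idx <- if (n_multi > 0L) sample.int(cfg$n_tips, n_multi) else integer(0)
  counts <- lapply(seq_len(cfg$n_tips), function(i) {
    ct <- st$count[i]
    if (!(i %in% multi_idx)) return(ct)
    step <- if (stats::runif(1L) < 0.5) -1L else 1L
    alt <- ct + step
    if (alt < cfg$min_count || alt > cfg$max_count) alt <- ct - step
    sort(c(ct, alt))
  })

  # withhold wing state for a fraction of tips and impute from pseudo-genus
  # congeners (keeping at least one scored species per genus)
  genus <- paste0("g", ceiling(seq_len(cfg$n_tips) / cfg$genus_size))
  names(genus) <- st$species
  status <- ifelse(st$trait == 0L, "wingless", "winged")
  names(status) <- st$species
  n_unknown <- round(cfg$frac_prob_trait * cfg$n_tips)
  unk <- character(0)
  # spread the unknowns round-robin across genera so every genus keeps
  # several scored congeners to impute from
  while (length(unk) < n_unknown) {
    grew <- FALSE
    for (g in unique(genus)) {
      if (length(unk) >= n_unknown) break
      members <- setdiff(st$species[genus == g], unk)
      if (length(members) < 2L) next
      unk <- c(unk, sample(members, 1L))
      grew <- TRUE
    }
    if (!grew) break
  }
  status[unk] <- "unknown"
  p_wingless <- impute_wing_probability(status, genus)

  tips <- lapply(seq_len(cfg$n_tips), function(i) {
    tip_data(st$species[i], counts[[i]], p_wingless[[st$species[i]]])
  })
  tip_table <- data.frame(
    species = st$species,
    genus = unname(genus[st$species]),
    counts = vapply(counts, paste, character(1L), collapse = ";"),
    p_wingless = unname(p_wingless[st$species]),
    true_count = st$count,
    true_trait = ifelse(st$trait == 0L, "wingless", "winged"),
    stringsAsFactors = FALSE
  )

  my_tree <- base
  my_tree$edge.length <- my_tree$edge.length * cfg$depth_my
  trees <- perturb_tree_set(my_tree, cfg$n_trees, cfg$sd_log,
                            seed = cfg$seed + 3L)
  truth_list <- list(
    rates_unit = list(gamma = truth$gamma, delta = truth$delta,
                      rho = truth$rho, q_loss = truth$q_loss),
    rates_per_my = list(gamma = truth$gamma / cfg$depth_my,
                        delta = truth$delta / cfg$depth_my,
                        rho = truth$rho / cfg$depth_my,
                        q_loss = truth$q_loss / cfg$depth_my),
    root_state = list(count = cfg$root_count, trait = cfg$root_trait),
    n_events = nrow(sim$event_log),
    seed = cfg$seed,
    config = unclass(cfg)
  )
  out <- list(trees = trees, tips = tips, tip_table = tip_table,
              truth = truth_list, event_log = sim$event_log, space = space)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_newick_set(trees, file.path(dir, "trees.nwk"))
    utils::write.csv(tip_table[, c("species", "counts", "p_wingless")],
                     file.path(dir, "tips.csv"), row.names = FALSE)
    jsonlite::write_json(truth_list, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
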