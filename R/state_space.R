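#' Discrete state space over (chromosome count, trait)
#'
#' Builds the state space used by the chromosome-number Markov model: every
#' combination of a haploid autosome count in `min_count:max_count` with one
#' of `n_trait_levels` trait levels. With two trait levels the convention is
#' fixed throughout the package: level 0 = wingless, level 1 = winged, so
#' rate-difference statistics (wingless minus winged) have a deterministic
#' sign.
#'
#' @param min_count smallest haploid autosome count admitted (>= 1).
#' @param max_count largest haploid autosome count admitted.
#' @param n_trait_levels 1 for clade-level (count-only) models, 2 for
#'   trait-linked models.
#' @return an object of class `state_space` with fields `min_count`,
#'   `max_count`, `n_trait_levels`, `size` and `labels` (labels are
#'   `"count|trait"` for two-level spaces, `"count"` otherwise).
#' @examples
#' build_state_space(3, 34, 2)$size  # 64
#' @export
build_state_space <- function(min_count, max_count, n_trait_levels = 1L) {
  if (length(min_count) != 1L || !is.finite(min_count) || min_count != round(min_count) ||
      min_count < 1) {
    stop("min_count must be a single integer >= 1")
  }
  if (length(max_count) != 1L || !is.finite(max_count) || max_count != round(max_count) ||
      max_count < min_count) {
    stop("max_count must be a single integer >= min_count")
  }
  if (length(n_trait_levels) != 1L || !(n_trait_levels %in% c(1L, 2L))) {
    stop("n_trait_levels must be 1 or 2")
  }
  min_count <- as.integer(min_count)
  max_count <- as.integer(max_count)
  n_trait_levels <- as.integer(n_trait_levels)
  counts <- min_count:max_count
  labels <- if (n_trait_levels == 2L) {
    as.vector(vapply(counts, function(ct) {
      paste0(ct, "|", c("wingless", "winged"))
    }, character(2L)))
  } else {
    as.character(counts)
  }
  structure(
    list(
      min_count = min_count,
      max_count = max_count,
      n_trait_levels = n_trait_levels,
      size = length(counts) * n_trait_levels,
      labels = labels
    ),
    class = "state_space"
  )
}

#' Map (count, trait) to a state index and back
#'
#' `state_index()` returns the 1-based index of a state; `state_of()` inverts
#' it. Both are vectorised and round-trip exactly.
#'
#' @param space a `state_space`.
#' @param count haploid autosome count(s).
#' @param trait trait level(s), 0-based (0 = wingless, 1 = winged); ignored
#'   for one-level spaces.
#' @param index state index (1-based).
#' @return `state_index()`: integer indices in `[1, space$size]`;
#'   `state_of()`: a data.frame with columns `count` and `trait`.
#' @export
state_index <- function(space, count, trait = 0L) {
  stopifnot(inherits(space, "state_space"))
  if (any(count < space$min_count | count > space$max_count)) {
    stop("count outside state space bounds [", space$min_count, ", ",
         space$max_count, "]")
  }
  if (any(trait < 0L | trait >= space$n_trait_levels)) {
    stop("trait level outside [0, ", space$n_trait_levels - 1L, "]")
  }
  as.integer((count - space$min_count) * space$n_trait_levels + trait + 1L)
}

#' @rdname state_index
#' @export
state_of <- function(space, index) {
  stopifnot(inherits(space, "state_space"))
  if (any(index < 1L | index > space$size)) stop("state index out of range")
  idx0 <- as.integer(index) - 1L
  data.frame(
    count = space$min_count + idx0 %/% space$n_trait_levels,
    trait = idx0 %% space$n_trait_levels
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("state_space:", x$size, "states; counts", x$min_count, "..",
      x$max_count, ";", x$n_trait_levels, "trait level(s)\n")
  invisible(x)
}

#' Default state-space bounds around observed counts
#'
#' The default bounds admit at least one fusion below the smallest observed
#' count and one whole-genome duplication above the largest (capped at 50 so
#' matrices stay small); users can always override them.
#'
#' @param counts integer vector of observed haploid autosome counts.
#' @param n_trait_levels passed through to [build_state_space()].
#' @param cap upper cap on `max_count` (default 50).
#' @return a `state_space`.
#' @export
default_state_space <- function(counts, n_trait_levels = 1L, cap = 50L) {
  counts <- as.integer(counts)
  if (!length(counts) || any(!is.finite(counts)) || any(counts < 1L)) {
    stop("counts must be positive integers")
  }
  build_state_space(max(1L, min(counts) - 1L),
                    min(2L * max(counts), as.integer(cap)),
                    n_trait_levels)
}
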