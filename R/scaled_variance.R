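#' Coefficient of variation of chromosome counts
#'
#' Sample standard deviation (n - 1 denominator; clade record sets are
#' small, so the estimator choice is material) divided by the mean.
#'
#' @param counts numeric vector of at least two positive counts.
#' @return the CV (dimensionless, >= 0).
#' @export
coefficient_of_variation <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("CV needs at least 2 values")
  if (any(!is.finite(counts))) stop("non-finite counts")
  m <- mean(counts)
  if (m <= 0) stop("CV undefined for mean <= 0")
  stats::sd(counts) / m
}

#' Fossil-scaled coefficient of variation
#'
#' The phylogeny-free rate proxy: a clade's CV of chromosome counts divided
#' by the age (My) of its oldest fossil. Optionally multiplied by 100 for
#' presentation.
#'
#' @param cv coefficient of variation (>= 0).
#' @param age_my fossil-based clade age in millions of years (> 0).
#' @param x100 if `TRUE`, report the value times 100.
#' @return the scaled CV.
#' @export
scaled_cv <- function(cv, age_my, x100 = FALSE) {
  if (any(!is.finite(age_my)) || any(age_my <= 0)) stop("age_my must be > 0")
  if (any(!is.finite(cv)) || any(cv < 0)) stop("cv must be >= 0")
  out <- cv / age_my
  if (isTRUE(x100)) out * 100 else out
}

#' Kendall rank correlation (tau-b) with two-sided p-value
#'
#' Tie-corrected tau-b via [stats::cor.test()]: exact enumeration p-value
#' for n <= 10 without ties, normal approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `tau` and `p_value`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("tau undefined for all-tied input")
  }
  has_ties <- anyDuplicated(x) || anyDuplicated(y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = length(x) <= 10L && !has_ties))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and `p_value` (two-sided t-test).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined with zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Clade summary table of scaled-variance rate proxies
#'
#' For each clade, computes (or accepts) the CV of its chromosome counts,
#' divides by the fossil age to get the scaled CV, and — when model-based
#' mean rates are supplied — reports the Kendall correlation between the
#' two rate measures as an attribute.
#'
#' @param clades data.frame with columns `clade`, `age_my`, and either
#'   `cv` or a list-column `counts` of per-clade count vectors; optional
#'   `mean_model_rate`.
#' @param x100 multiply `scv` (and `mean_model_rate`, if present) by 100
#'   for presentation.
#' @return the input with columns `n_records`, `cv`, `scv` added; if model
#'   rates are present, attribute `"tau"` holds [kendall_tau()] of
#'   `mean_model_rate` vs `scv`.
#' @export
clade_summary_table <- function(clades, x100 = FALSE) {
  stopifnot(is.data.frame(clades), all(c("clade", "age_my") %in% names(clades)))
  if (!"cv" %in% names(clades)) {
    if (!"counts" %in% names(clades)) stop("need a 'cv' or 'counts' column")
    clades$n_records <- vapply(clades$counts, length, integer(1L))
    clades$cv <- vapply(clades$counts, coefficient_of_variation, numeric(1L))
  } else if (!"n_records" %in% names(clades)) {
    clades$n_records <- NA_integer_
  }
  clades$scv <- scaled_cv(clades$cv, clades$age_my, x100 = x100)
  if (isTRUE(x100) && "mean_model_rate" %in% names(clades)) {
    clades$mean_model_rate <- clades$mean_model_rate * 100
  }
  if ("mean_model_rate" %in% names(clades) && nrow(clades) >= 3L) {
    attr(clades, "tau") <- kendall_tau(clades$mean_model_rate, clades$scv)
  }
  clades
}
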