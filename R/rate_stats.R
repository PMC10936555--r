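#' Central (or HPD) credible interval
#'
#' Central quantile interval at `(1 - level)/2` and `1 - (1 - level)/2`,
#' with linear interpolation between order statistics (`stats::quantile`
#' type 7). A shortest-interval (empirical HPD) variant is available via
#' `method = "hpd"`; the central interval is the default because it needs
#' no density estimation and reproduces exactly.
#'
#' @param samples nonempty numeric vector of posterior samples.
#' @param level coverage in (0, 1); default 0.95.
#' @param method `"central"` (default) or `"hpd"`.
#' @return numeric vector `c(low, high)`.
#' @export
credible_interval <- function(samples, level = 0.95,
                              method = c("central", "hpd")) {
  method <- match.arg(method)
  samples <- as.numeric(samples)
  if (!length(samples)) stop("empty sample vector")
  if (any(!is.finite(samples))) stop("non-finite samples")
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly in (0, 1)")
  }
  if (method == "central") {
    unname(stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                           type = 7))
  } else {
    s <- sort(samples)
    n <- length(s)
    m <- min(n, max(1L, ceiling(level * n)))
    if (m >= n) return(c(s[1L], s[n]))
    widths <- s[m:n] - s[seq_len(n - m + 1L)]
    i <- which.min(widths)
    c(s[i], s[i + m - 1L])
  }
}

trace_config <- function(trace) {
  cfg <- attr(trace, "config")
  if (is.null(cfg)) stop("trace carries no mcmc_config attribute")
  cfg
}

#' Posterior rate-difference statistic (Delta-R)
#'
#' For a trait-linked model, the per-sample difference of a rate between
#' trait states, wingless minus winged, on the per-million-year scale.
#' A credible interval entirely above zero supports a faster rate in
#' wingless lineages; one entirely below zero, in winged lineages; one
#' spanning zero supports no rate difference.
#'
#' @param trace a `posterior_trace` from a `trait_full` or `trait_noWGD`
#'   fit.
#' @param parameter `"fission"` (gamma), `"fusion"` (delta) or `"wgd"`
#'   (rho).
#' @param level credible-interval coverage.
#' @return an object of class `delta_r_result`: `parameter`, `samples`,
#'   `mean`, `ci_low`, `ci_high`, `fraction_negative`, `n`.
#' @export
delta_r <- function(trace, parameter = c("fission", "fusion", "wgd"),
                    level = 0.95) {
  parameter <- match.arg(parameter)
  cfg <- trace_config(trace)
  if (!cfg$model %in% c("trait_full", "trait_noWGD")) {
    stop("delta_r needs a trait-linked trace; got model '", cfg$model,
         "' (use clade_mean_rate for clade-level traces)")
  }
  base <- switch(parameter, fission = "gamma", fusion = "delta", wgd = "rho")
  cols <- paste0(base, c("_wingless_my", "_winged_my"))
  if (!all(cols %in% names(trace))) {
    stop("trace has no per-trait columns for '", parameter,
         "' (model '", cfg$model, "')")
  }
  samples <- trace[[cols[1L]]] - trace[[cols[2L]]]
  ci <- credible_interval(samples, level)
  structure(list(parameter = parameter, samples = samples,
                 mean = mean(samples), ci_low = ci[1L], ci_high = ci[2L],
                 fraction_negative = mean(samples < 0),
                 n = length(samples)),
            class = "delta_r_result")
}

#' @export
print.delta_r_result <- function(x, ...) {
  cat(sprintf("DeltaR_%s: mean %.4g, 95%% CI [%.4g, %.4g], P(<0) = %.3f (n = %d)\n",
              x$parameter, x$mean, x$ci_low, x$ci_high,
              x$fraction_negative, x$n))
  invisible(x)
}

#' Clade-level posterior mean rate
#'
#' For a clade (count-only) model: in each generation the arithmetic mean
#' of the model's free chromosome rates (per My) — fission and fusion for
#' the two-parameter model, plus whole-genome duplication for the
#' three-parameter model — then the posterior mean and credible interval of
#' those per-generation means.
#'
#' @param trace a `posterior_trace` from a `clade_2p` or `clade_3p` fit.
#' @param level credible-interval coverage.
#' @return an object of class `clade_rate_result`: `samples` (per-sample
#'   mean rates), `mean`, `ci_low`, `ci_high`, `n`.
#' @export
clade_mean_rate <- function(trace, level = 0.95) {
  cfg <- trace_config(trace)
  if (!cfg$model %in% c("clade_2p", "clade_3p")) {
    stop("clade_mean_rate needs a clade-level trace; got model '", cfg$model,
         "' (use delta_r for trait-linked traces)")
  }
  cols <- paste0(free_param_names(cfg$model), "_my")
  samples <- unname(rowMeans(as.data.frame(trace)[, cols, drop = FALSE]))
  ci <- credible_interval(samples, level)
  structure(list(samples = samples, mean = mean(samples),
                 ci_low = ci[1L], ci_high = ci[2L], n = length(samples)),
            class = "clade_rate_result")
}

#' @export
print.clade_rate_result <- function(x, ...) {
  cat(sprintf("clade mean rate: %.4g /My, 95%% CI [%.4g, %.4g] (n = %d)\n",
              x$mean, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Convert a unit-tree rate to events per million years
#'
#' Rates fitted on a tree rescaled to unit depth are divided by the tree's
#' original root-to-tip depth in My.
#'
#' @param rate_unit rate(s) on the unit-tree scale (>= 0).
#' @param depth_my original tree depth in millions of years (> 0).
#' @return rate(s) in events per million years.
#' @export
rescale_to_my <- function(rate_unit, depth_my) {
  if (any(!is.finite(depth_my)) || any(depth_my <= 0)) {
    stop("depth_my must be > 0")
  }
  if (any(rate_unit < 0)) stop("rates must be >= 0")
  rate_unit / depth_my
}
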