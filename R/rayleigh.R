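#' Uptake fractionation factor from reservoir evolution
#'
#' Closed-system Rayleigh estimator for the fractionation on uptake from a
#' finite solution reservoir:
#' epsilon = (delta_final - delta_init) / ln(f), with f the fraction of Cd
#' remaining in the solution. The estimate is signed; with plants isotopically
#' lighter than the solution the residue gets heavier (delta_final > delta_init)
#' and ln f < 0, so epsilon < 0. Reports often quote the magnitude.
#'
#' @param delta_init,delta_final initial and final solution delta114Cd (permil).
#' @param f_remaining fraction of Cd remaining in solution, 0 < f < 1.
#' @return epsilon in permil (signed).
#' @export
#' @examples
#' uptake_epsilon(-0.36, -0.345, 0.95)  # ~ -0.292
uptake_epsilon <- function(delta_init, delta_final, f_remaining) {
  if (any(f_remaining <= 0) || any(f_remaining >= 1)) {
    stop("uptake_epsilon: f_remaining must lie strictly between 0 and 1")
  }
  (delta_final - delta_init) / log(f_remaining)
}

#' Single-plant sequestration/mobilisation fractionation factor
#'
#' Applies the within-plant Rayleigh relation, delta_mob = delta_tot +
#' epsilon * ln(f_mob), to one plant: epsilon = Delta_sink-tot / ln(f_sink),
#' where the sink is the mobilised pool (leaves or shoots) and the total plant
#' is the source.
#'
#' @param d_sink_tot apparent fractionation Delta114Cd_sink-tot (permil).
#' @param f_sink fraction of total plant Cd in the sink, 0 < f < 1 (f = 1 is
#'   only admissible with Delta = 0, where epsilon is undefined).
#' @return epsilon in permil.
#' @export
seq_mob_epsilon_single <- function(d_sink_tot, f_sink) {
  if (any(f_sink <= 0) || any(f_sink > 1)) {
    stop("seq_mob_epsilon_single: f_sink must lie in (0, 1]")
  }
  out <- numeric(length(d_sink_tot))
  at_one <- f_sink == 1
  if (any(at_one & d_sink_tot != 0)) {
    stop("seq_mob_epsilon_single: f_sink = 1 with nonzero Delta is inconsistent")
  }
  out[at_one] <- NA_real_  # undefined 0/0: flagged, not an error
  out[!at_one] <- d_sink_tot[!at_one] / log(f_sink[!at_one])
  out
}

#' Forced-origin Rayleigh fractionation fit
#'
#' Least-squares fit of apparent sink-total fractionations against the log
#' sink fraction, with the line forced through (f = 1, Delta = 0): a sink
#' holding all of the plant's Cd cannot be fractionated from it. The slope is
#' the pooled fractionation factor:
#' epsilon = sum(w x y) / sum(w x^2) with x = ln(f_sink), y = Delta_sink-tot.
#'
#' @param f_sink vector of sink Cd fractions (0 < f <= 1).
#' @param d_sink_tot vector of Delta114Cd_sink-tot values (permil).
#' @param sink label, "leaf" or "shoot" (bookkeeping only).
#' @param weights optional non-negative weights (e.g. inverse variance);
#'   default unweighted.
#' @return object of class `rayleigh_fit`: `epsilon` (permil), `sink`,
#'   `n_points`, `residual_sd` (permil, n - 1 denominator), `per_point_epsilon`,
#'   `residuals`, `f_sink`, `d_sink_tot`.
#' @export
#' @examples
#' f <- c(0.2, 0.4, 0.6)
#' fit_rayleigh(f, -0.13 * log(f), sink = "leaf")$epsilon  # -0.13
fit_rayleigh <- function(f_sink, d_sink_tot, sink = c("leaf", "shoot"),
                         weights = NULL) {
  sink <- match.arg(sink)
  stopifnot(length(f_sink) == length(d_sink_tot), length(f_sink) >= 1)
  if (any(f_sink <= 0) || any(f_sink > 1)) {
    stop("fit_rayleigh: all f_sink must lie in (0, 1]")
  }
  x <- log(f_sink)
  if (all(x == 0)) stop("fit_rayleigh: singular design, all f_sink = 1")
  w <- if (is.null(weights)) rep(1, length(x)) else {
    stopifnot(length(weights) == length(x), all(weights >= 0))
    weights
  }
  eps <- sum(w * x * d_sink_tot) / sum(w * x^2)
  res <- d_sink_tot - eps * x
  structure(list(
    epsilon = eps, sink = sink, n_points = length(x),
    residual_sd = if (length(x) > 1) stats::sd(res) else 0,
    per_point_epsilon = ifelse(x == 0, NA_real_, d_sink_tot / x),
    residuals = res, f_sink = f_sink, d_sink_tot = d_sink_tot,
    weighted = !is.null(weights)
  ), class = "rayleigh_fit")
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  cat(sprintf(
    "Rayleigh fit (%s sink, forced through Delta = 0 at f = 1)\n  epsilon = %.4f permil (|epsilon| = %.4f), n = %d, residual sd = %.4f permil\n",
    x$sink, x$epsilon, abs(x$epsilon), x$n_points, x$residual_sd))
  invisible(x)
}

#' Composition of the accumulated removed pool in a closed Rayleigh system
#'
#' For a reservoir evolving as delta_res = delta_init + epsilon * ln(f), the
#' pool removed so far (the accumulated product) has
#' delta_prod = delta_init - epsilon * f * ln(f) / (1 - f),
#' which satisfies the exact mass balance
#' f * delta_res + (1 - f) * delta_prod = delta_init. As f -> 1 the product
#' composition tends to delta_init + epsilon (the instantaneous offset).
#'
#' @param delta_init initial reservoir composition (permil).
#' @param epsilon fractionation factor (permil).
#' @param f fraction remaining in the reservoir, 0 < f < 1.
#' @return delta of the accumulated removed pool (permil).
#' @export
#' @examples
#' accumulated_product_delta(-0.36, -0.277, 0.95)  # ~ -0.630
accumulated_product_delta <- function(delta_init, epsilon, f) {
  if (any(f <= 0) || any(f >= 1)) {
    stop("accumulated_product_delta: f must lie strictly between 0 and 1")
  }
  delta_init - epsilon * f * log(f) / (1 - f)
}
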