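#' Kruskal-Wallis comparison with an exact small-sample option
#'
#' Rank-based omnibus comparison of two or more groups. The H statistic uses
#' the standard tie correction. The p-value comes from the chi-square
#' approximation (df = k - 1) except when the total sample size is at most
#' `exact_max`, where the exact permutation distribution of H over all
#' distinct assignments of the pooled observations to the group sizes is
#' enumerated instead. The test is inherently two-sided (omnibus).
#'
#' @param groups list of two or more numeric vectors, each nonempty; ties
#'   allowed.
#' @param exact_max largest total n for which the exact permutation p-value is
#'   computed (default 12; enumeration grows combinatorially).
#' @return object of class `group_comparison`: `h`, `p_value`, `method`
#'   ("exact permutation" or "chi-square approximation"), `df`, `group_sizes`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
kruskal_wallis <- function(groups, exact_max = 12L) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("kruskal_wallis: every group must be nonempty")
  }
  x <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, integer(1))
  k <- length(sizes)
  n <- sum(sizes)
  h_obs <- .kw_h(x, rep.int(seq_len(k), sizes))
  if (n <= exact_max) {
    p <- .kw_exact_p(x, sizes, h_obs)
    method <- "exact permutation"
  } else {
    p <- if (h_obs == 0) 1 else stats::pchisq(h_obs, df = k - 1, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  structure(list(h = h_obs, p_value = p, method = method, df = k - 1L,
                 group_sizes = sizes), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f (df = %d), p = %.4g [%s; n = %s]\n",
              x$h, x$df, x$p_value, x$method,
              paste(x$group_sizes, collapse = "+")))
  if (!is.null(x$variable)) {
    cat(sprintf("  variable %s by %s\n", x$variable, x$factor))
  }
  invisible(x)
}

# tie-corrected Kruskal-Wallis H for pooled data x with group labels g.
# Delegated to the standard implementation; all identical values (zero rank
# variance) is a degenerate case the standard errors on, defined here as H = 0.
.kw_h <- function(x, g) {
  if (length(unique(x)) == 1) return(0)
  unname(stats::kruskal.test(x, factor(g))$statistic)
}

# exact permutation p: enumerate all distinct assignments of the pooled values
# to groups of the given sizes and count H >= H_obs. Enumeration walks
# combinations of indices recursively so each multiset partition is visited
# once.
.kw_exact_p <- function(x, sizes, h_obs) {
  n <- length(x)
  idx_all <- seq_len(n)
  count <- 0L
  total <- 0L
  assign_groups <- function(remaining, gi, labels) {
    if (gi > length(sizes)) {
      h <- .kw_h(x, labels)
      total <<- total + 1L
      if (h >= h_obs - 1e-12) count <<- count + 1L
      return(invisible(NULL))
    }
    if (gi == length(sizes)) {  # last group takes the rest
      labels[remaining] <- gi
      return(assign_groups(integer(0), gi + 1L, labels))
    }
    # equal-size groups swapped give identical H, so counting every labelling
    # leaves the exceedance ratio exact
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (pk in picks) {
      labels[pk] <- gi
      assign_groups(setdiff(remaining, pk), gi + 1L, labels)
    }
    invisible(NULL)
  }
  assign_groups(idx_all, 1L, integer(n))
  count / total
}

#' Pooled two-group comparison of a derived plant variable
#'
#' Pools plants across treatments by a shared design flag (e.g. presence of
#' hydroponic Fe) and compares a derived variable between the two pools with
#' [kruskal_wallis()]. Significance is conventionally assessed at p < 0.05.
#'
#' @param derived per-plant table from [derive_plants()] (or any data frame).
#' @param factor_col name of a logical/two-level column partitioning the rows.
#' @param variable name of the numeric column to compare.
#' @param exact_max passed to [kruskal_wallis()].
#' @return a `group_comparison` with `variable` and `factor` fields attached.
#' @export
pooled_group_compare <- function(derived, factor_col, variable,
                                 exact_max = 12L) {
  stopifnot(factor_col %in% names(derived), variable %in% names(derived))
  fac <- derived[[factor_col]]
  vals <- derived[[variable]]
  keep <- !is.na(fac) & !is.na(vals)
  fac <- fac[keep]; vals <- vals[keep]
  levels <- unique(fac)
  if (length(levels) < 2) {
    stop("pooled_group_compare: '", factor_col, "' does not partition the data into two groups")
  }
  groups <- lapply(levels, function(l) vals[fac == l])
  out <- kruskal_wallis(groups, exact_max = exact_max)
  out$variable <- variable
  out$factor <- factor_col
  out$significant <- out$p_value < 0.05
  out
}
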