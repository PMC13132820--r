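#' Kruskal-Wallis rank test across outcome groups
#'
#' Tie-corrected Kruskal-Wallis H: mid-ranks are assigned over the pooled
#' sample, `H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2`, divided by
#' the tie correction `C = 1 - sum(t^3 - t)/(N^3 - N)`; the p-value is
#' asymptotic chi-square with `groups - 1` degrees of freedom. The
#' degenerate case where every observation is identical (C = 0) is
#' reported as H = 0, p = 1 with a warning.
#'
#' @param groups list of >= 2 non-empty numeric vectors (total N >= 3).
#' @param variable optional variable name carried into the result.
#' @return A `group_test_result`: list with `variable`, `statistic`,
#'   `statistic_kind = "kruskal_wallis"`, `df`, `p_raw`, `q_fdr` (NA until
#'   FDR correction over a family).
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))$statistic  # 2.4
#' @export
kruskal_wallis <- function(groups, variable = NA_character_) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L || any(!lengths(groups)))
    stop("need >= 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("need total N >= 3")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    warning("all observations identical; H defined as 0")
    return(group_test_result(variable, 0, "kruskal_wallis",
                             length(groups) - 1L, 1))
  }
  kt <- stats::kruskal.test(x, g)
  group_test_result(variable, unname(kt$statistic), "kruskal_wallis",
                    unname(kt$parameter), unname(kt$p.value))
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square `sum (O - E)^2 / E` on an r x c count
#' table with `df = (r-1)(c-1)`. No continuity correction is applied
#' (matching the convention under which a deterministic binary mapping
#' yields chi-square = N exactly).
#'
#' @param table r x c matrix of nonnegative integer counts, all row and
#'   column sums > 0.
#' @param variable optional variable name carried into the result.
#' @return A `group_test_result` with `statistic_kind = "chi_square"`.
#' @export
chi_square_independence <- function(table, variable = NA_character_) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0))
    stop("zero row margin at row ", paste(which(rs == 0), collapse = ", "))
  if (any(cs == 0))
    stop("zero column margin at column ", paste(which(cs == 0), collapse = ", "))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  group_test_result(variable, unname(ct$statistic), "chi_square",
                    unname(ct$parameter), unname(ct$p.value))
}

group_test_result <- function(variable, statistic, kind, df, p_raw,
                              q_fdr = NA_real_) {
  structure(list(variable = variable, statistic = statistic,
                 statistic_kind = kind, df = as.integer(df),
                 p_raw = p_raw, q_fdr = q_fdr),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.3f (df = %d), p = %.4g%s\n",
              if (is.na(x$variable)) "test" else x$variable,
              if (x$statistic_kind == "chi_square") "chi-square" else "H",
              x$statistic, x$df, x$p_raw,
              if (is.na(x$q_fdr)) "" else sprintf(", q = %.4g", x$q_fdr)))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. A constant input vector makes the
#' coefficient undefined; it is returned as `NA` with attribute
#' `undefined = TRUE` and a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or flagged `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  stats::cor(x, y, method = "spearman")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate correction over the jointly tested
#' family: after ascending sort, `q(i) = min_{j >= i} p(j) * m / j`,
#' mapped back to input order and capped at 1.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Size-weighted pooled mean
#'
#' Recovers the pooled cohort mean from per-group means and group sizes.
#'
#' @param group_means numeric vector of group means.
#' @param group_sizes integer vector of group sizes (> 0), same length.
#' @return The size-weighted mean.
#' @examples
#' pooled_group_mean(c(0, 0, 92.2), c(70, 49, 33))  # 20.0 g/day
#' @export
pooled_group_mean <- function(group_means, group_sizes) {
  if (length(group_means) != length(group_sizes))
    stop("group_means and group_sizes must have equal length")
  if (any(group_sizes <= 0)) stop("group sizes must be positive")
  stats::weighted.mean(group_means, group_sizes)
}
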