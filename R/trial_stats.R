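new_test_result <- function(test_name, statistic, p_value, method, n_per_group) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(test_name = test_name, statistic = statistic,
         p_value = min(p_value, 1), sidedness = "two-sided",
         method = method, n_per_group = n_per_group),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s, two-sided): statistic = %g, P = %s [n = %s]\n",
              x$test_name, x$method, x$statistic, format_p(x$p_value),
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided rank-sum comparison of two continuous samples. The exact null
#' distribution is used when `n1 * n2 <= 400` and the pooled data contain
#' no ties; otherwise the normal approximation with midrank tie correction
#' and continuity correction is used. The method taken is recorded in the
#' result. The reported statistic is the U of the smaller sample (of the
#' first sample on equal sizes).
#'
#' @param x,y Numeric samples, both non-empty.
#' @return A `test_result` with the U statistic (in `[0, n1*n2]`), the
#'   two-sided p-value and the method used.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 * n2 <= 400) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  p <- wt$p.value
  # a pooled sample with no variation carries no evidence either way
  if (is.nan(p)) p <- 1
  wt$p.value <- min(p, 1)
  u_x <- unname(wt$statistic)      # U associated with the first sample
  u_y <- n1 * n2 - u_x
  statistic <- if (n1 <= n2) u_x else u_y
  new_test_result("mann_whitney_u", statistic, wt$p.value,
                  if (exact) "exact" else "normal_approx", c(n1, n2))
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided exact test on a 2x2 contingency table: with the margins
#' fixed, the p-value sums the hypergeometric probabilities of all tables
#' whose point probability does not exceed that of the observed table
#' (minimum-likelihood rule), with a relative tolerance for ties. The
#' result is invariant to transposing the table and to swapping its rows.
#'
#' @param table A 2x2 matrix of non-negative integer counts with at least
#'   one positive margin.
#' @return A `test_result`; the statistic is the conditional
#'   maximum-likelihood odds ratio estimate.
#' @examples
#' fisher_exact(matrix(c(1, 19, 3, 16), nrow = 2, byrow = TRUE))  # P = .34
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(table) == 0) stop("at least one margin must be positive", call. = FALSE)
  ft <- fisher.test(table, alternative = "two.sided")
  new_test_result("fisher_exact", unname(ft$estimate), ft$p.value,
                  "exact_min_likelihood", rowSums(table))
}

#' Two-sample t-test power at a given per-arm size
#'
#' Power of the two-sided two-sample t test at level `alpha` against a
#' standardized difference `effect_size`, with `n` patients per arm:
#' noncentrality `effect_size * sqrt(n / 2)` on `2n - 2` degrees of
#' freedom.
#'
#' @param n Patients per arm (>= 2).
#' @param effect_size Standardized mean difference (Cohen's d), > 0.
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
t_test_power <- function(n, effect_size, alpha = 0.05) {
  df <- 2 * n - 2
  tcrit <- qt(1 - alpha / 2, df)
  ncp <- effect_size * sqrt(n / 2)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) + pt(-tcrit, df, ncp = ncp)
}

#' A priori sample size for a two-sample t test
#'
#' Smallest integer number of patients per arm such that the two-sided
#' two-sample t test at level `alpha` attains the requested power against
#' the standardized effect size, computed by iterating `n` through the
#' noncentral t power function.
#'
#' @param effect_size Standardized mean difference (Cohen's d), > 0.
#' @param power Requested power, in (0, 1).
#' @param alpha Two-sided significance level, in (0, 1).
#' @return Integer patients per arm.
#' @examples
#' sample_size_two_sample_t(1.095, power = 0.90, alpha = 0.05)  # 19 per arm
#' @export
sample_size_two_sample_t <- function(effect_size, power = 0.90, alpha = 0.05) {
  if (!is.finite(effect_size) || effect_size <= 0) {
    stop("effect_size must be positive", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- 2L
  while (t_test_power(n, effect_size, alpha) < power) {
    n <- n + 1L
    if (n > 1e6) stop("sample size exceeds 1e6 per arm; check inputs",
                      call. = FALSE)
  }
  n
}

#' Format a p-value in report style
#'
#' Journal-style formatting: two decimals without a leading zero (".34"),
#' "<.001" below 0.001, and ">.99" above 0.99.
#'
#' @param p A p-value in `[0, 1]`.
#' @return Character.
#' @export
format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) return("<.001")
    if (pi > 0.99) return(">.99")
    sub("^0", "", sprintf("%.2f", pi))
  }, character(1))
}
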