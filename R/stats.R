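#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-group test of equality of location. Observations are
#' mid-ranked jointly; the statistic
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \tfrac{N+1}{2})^2}
#' is divided by the tie-correction factor \eqn{1 - \sum (t^3 - t)/(N^3 - N)}
#' (one term per tied value, t tied observations). Ties are pervasive in
#' spine-density data (quotients of small integer counts), so the
#' correction is always applied. The p value is the upper chi-square tail
#' with `k - 1` degrees of freedom.
#'
#' @param groups a list of numeric vectors, one per group (at least 2
#'   groups, each non-empty).
#' @return An object of class `"kw_test"`: list with `H`, `df`, `p`,
#'   `n` (total observations).
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))  # H = 7.2
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)  # mid-ranks
  rbar <- tapply(r, g, mean)
  n_i <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  t <- table(x)
  C <- 1 - sum(t^3 - t) / (N^3 - N)
  H <- H / C
  df <- length(groups) - 1L
  structure(
    list(H = H, df = df, p = stats::pchisq(H, df, lower.tail = FALSE), n = N),
    class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis (tie-corrected): H = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p))
  invisible(x)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(lengths(groups) < 1L))
    stop("every group needs at least one observation")
  x <- unlist(groups, use.names = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("observations must be finite numerics")
  if (length(unique(x)) < 2L)
    stop("degenerate data: all observations are identical")
  invisible(TRUE)
}

#' Dunn's pairwise post hoc Z test
#'
#' Pairwise comparison of mean ranks following a Kruskal-Wallis test.
#' For groups a and b,
#' \deqn{Z_{ab} = \frac{\bar R_a - \bar R_b}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_a} +
#'   \frac{1}{n_b}\right)}}}
#' with ranks and tie terms computed on the pooled sample. p values are
#' two-sided normal tails, optionally adjusted for multiple comparisons.
#' No adjustment is the default, matching the raw-Z reporting style of the
#' source analyses; Bonferroni and Holm are available.
#'
#' @param groups a list of numeric vectors, one per group; names are used
#'   as group labels.
#' @param adjust multiplicity adjustment: `"none"` (default),
#'   `"bonferroni"` or `"holm"`.
#' @return Data frame with one row per unordered pair: `group_a`,
#'   `group_b`, `Z`, `p_raw`, `p_adjusted`, `code` (significance code of
#'   the adjusted p, see [significance_code()]).
#' @export
dunn_posthoc <- function(groups, adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  check_groups(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- lengths(groups)
  t <- table(x)
  sigma2 <- N * (N + 1) / 12 - sum(t^3 - t) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  Z <- apply(pairs, 2, function(ab) {
    a <- ab[1]; b <- ab[2]
    (rbar[a] - rbar[b]) / sqrt(sigma2 * (1 / n_i[a] + 1 / n_i[b]))
  })
  p_raw <- 2 * stats::pnorm(-abs(Z))
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  data.frame(
    group_a = labels[pairs[1, ]], group_b = labels[pairs[2, ]],
    Z = Z, p_raw = p_raw, p_adjusted = p_adj,
    code = significance_code(p_adj),
    stringsAsFactors = FALSE
  )
}

#' Shapiro-Wilk normality gate
#'
#' Advisory normality check on a density sample (delegates to
#' [stats::shapiro.test()]). The analysis pipeline always proceeds
#' nonparametrically regardless of the outcome; the result is reported so
#' the choice of rank tests is auditable.
#'
#' @param values numeric vector, 3 to 5000 observations.
#' @param alpha significance level for the flag (default 0.05).
#' @return List with `W`, `p` and `is_normal` (`p >= alpha`).
#' @export
normality_check <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("normality_check requires between 3 and 5000 observations")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value,
       is_normal = sw$p.value >= alpha)
}

#' Significance codes
#'
#' Maps p values to the star codes used in the reported tables:
#' p < 0.0001 `****`; p < 0.001 `***`; p < 0.01 `**`; p < 0.05 `*`;
#' otherwise `ns`. A p of exactly 0.05 is `ns` (the star thresholds are
#' strict).
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out
}
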