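#' Normality screen with estimated parameters (Monte-Carlo Lilliefors)
#'
#' Kolmogorov-Smirnov distance between the empirical CDF of a sample and the
#' normal distribution with the sample's own mean and SD. Because the
#' parameters are estimated from the data, the classical KS null distribution
#' does not apply; the p-value is obtained by Monte Carlo under the
#' composite null (standard-normal samples of the same size, parameters
#' re-estimated on each draw), i.e. a simulated Lilliefors test.
#'
#' @param x Numeric sample, `n >= 4`, nonzero variance.
#' @param n_mc Number of Monte-Carlo null draws (default 10000).
#' @param seed Seed for the null simulation.
#' @return A list with `statistic` (the KS distance) and `p_value`.
#' @export
ks_normality <- function(x, n_mc = 10000, seed = 1L) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance: normality screen undefined", call. = FALSE)
  d_obs <- lilliefors_distance(x)
  d_null <- with_seed(seed, {
    vapply(seq_len(n_mc), function(b) lilliefors_distance(stats::rnorm(n)),
           numeric(1))
  })
  list(statistic = d_obs, p_value = (1 + sum(d_null >= d_obs)) / (1 + n_mc))
}

# KS distance of a sample from N(mean(x), sd(x)), via the sorted-sample form.
lilliefors_distance <- function(x) {
  n <- length(x)
  p <- stats::pnorm(sort(x), mean = mean(x), sd = stats::sd(x))
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided test that two samples originate from the same population, with
#' midrank handling of ties: an exact p-value when both groups together have
#' at most 50 observations and there are no ties, a normal approximation with
#' tie-corrected variance and continuity correction otherwise (the standard
#' [stats::wilcox.test()] behaviour). The returned `U` counts pairs where `a`
#' exceeds `b` (ties half-weighted), so swapping the groups maps `U` to
#' `n_a * n_b - U` with the same p-value.
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @return A list with `U` and `p_value`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact two-sided p = 1/3
mann_whitney <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 observations", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Hedges' g standardized effect size
#'
#' Pooled-SD standardized mean difference with the small-sample bias
#' correction `J = 1 - 3 / (4 (n_a + n_b) - 9)`:
#' \deqn{g = J \cdot \frac{\bar b - \bar a}{s_{pooled}}.}
#' Positive values mean group `b` exceeds group `a`. Conventionally 0.2 is a
#' small, 0.5 a medium and 0.8 a large effect.
#'
#' @param a,b Numeric samples (>= 2 each); pooled SD must be positive.
#' @return Hedges' g.
#' @export
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("both groups need at least 2 observations", call. = FALSE)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) stop("zero pooled SD: effect size undefined", call. = FALSE)
  j <- 1 - 3 / (4 * (na + nb) - 9)
  j * (mean(b) - mean(a)) / sp
}

#' Group comparison of every index in a cohort table
#'
#' For each (index, parameter) column of a cohort table: group means, the
#' Mann-Whitney U and two-sided p, Hedges' g (positive when the control group
#' exceeds the impaired group) and a significance flag at level `alpha`. No
#' multiple-testing correction is applied by default, matching the reference
#' analysis; `p_adjust = "holm"` is available.
#'
#' @param table A cohort table (as from [make_cohort()] or
#'   [table1_cohort()]) with columns `group`, `key`, `value`, where `group`
#'   has exactly two levels.
#' @param alpha Significance level (default 0.05).
#' @param groups Character vector of the two group labels, impaired first;
#'   defaults to `c("SZ", "CNT")`.
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()];
#'   `"none"` (default) or any method it supports.
#' @return A data frame, one row per index column: `key`, `mean_a`, `mean_b`
#'   (and 2-decimal display roundings), `U`, `p_value`, `hedges_g`,
#'   `significant`.
#' @export
summarize_cohort <- function(table, alpha = 0.05, groups = c("SZ", "CNT"),
                             p_adjust = "none") {
  stopifnot(is.data.frame(table), all(c("group", "key", "value") %in% names(table)))
  keys <- unique(table$key)
  out <- lapply(keys, function(k) {
    sub <- table[table$key == k, ]
    a <- sub$value[sub$group == groups[1]]
    b <- sub$value[sub$group == groups[2]]
    if (length(a) == 0L || length(b) == 0L)
      stop(sprintf("index '%s': a group is empty", k), call. = FALSE)
    mw <- mann_whitney(a, b)
    g <- tryCatch(hedges_g(a, b), error = function(e) NA_real_)
    data.frame(key = k,
               mean_a = mean(a), mean_b = mean(b),
               mean_a_2dec = round_half_away(mean(a), 2),
               mean_b_2dec = round_half_away(mean(b), 2),
               n_a = length(a), n_b = length(b),
               U = mw$U, p_value = mw$p_value, hedges_g = g,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_value_adj <- stats::p.adjust(res$p_value, method = p_adjust)
  res$significant <- res$p_value_adj < alpha
  attr(res, "groups") <- groups
  attr(res, "alpha") <- alpha
  res
}
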