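# Outcome statistics: coalition frequency tables, the chi-square goodness of
# fit test and its effect size (Cohen's w), noncentral chi-square power and
# minimum detectable effect size, odds ratios, and Cohen's d.

#' Coalition frequency table
#'
#' Observed coalition frequencies with the expected proportions they are
#' tested against. Build it from counts, or directly from printed proportions
#' and a sample size (study summaries are often reported that way; the
#' implied counts `p * n` need not be integers and are used as-is).
#'
#' @param counts named non-negative counts per coalition label.
#' @param proportions named observed proportions (must sum to 1); requires
#'   `n`.
#' @param n total number of triads (required with `proportions`, inferred
#'   from `counts` otherwise).
#' @param expected expected proportions under the null: `"uniform"` (default,
#'   the one-third-each benchmark when three coalitions can form) or a named
#'   numeric vector summing to 1.
#' @return an object of class `coalsim_freqtab` with fields `labels`,
#'   `counts`, `n`, `p`, and `expected`.
#' @examples
#' freq_table(proportions = c(BC = 0.67, AC = 0.29, AB = 0.04), n = 52)
#' @export
freq_table <- function(counts = NULL, proportions = NULL, n = NULL,
                       expected = "uniform") {
  if (is.null(counts) == is.null(proportions)) {
    stop_coalsim("bad_table", "give exactly one of counts or proportions")
  }
  if (!is.null(counts)) {
    if (is.null(names(counts)) || any(counts < 0)) {
      stop_coalsim("bad_table", "counts must be named and non-negative")
    }
    n <- sum(counts)
    if (n <= 0) stop_coalsim("bad_table", "counts sum to zero")
    p <- counts / n
  } else {
    if (is.null(n)) {
      stop_coalsim("bad_table", "proportions need a total n")
    }
    if (is.null(names(proportions)) ||
        abs(sum(proportions) - 1) > 1e-6 || any(proportions < 0)) {
      stop_coalsim("bad_table",
                   "proportions must be named, non-negative, and sum to 1")
    }
    p <- proportions
    counts <- proportions * n
  }
  k <- length(p)
  if (identical(expected, "uniform")) {
    expected <- stats::setNames(rep(1 / k, k), names(p))
  }
  if (!setequal(names(expected), names(p)) ||
      abs(sum(expected) - 1) > 1e-6) {
    stop_coalsim("bad_table",
                 "expected proportions must match the labels and sum to 1")
  }
  expected <- expected[names(p)]
  structure(
    list(labels = names(p), counts = as.numeric(counts), n = as.numeric(n),
         p = as.numeric(stats::setNames(p, names(p))),
         expected = as.numeric(expected)),
    class = "coalsim_freqtab"
  )
}

#' @export
print.coalsim_freqtab <- function(x, ...) {
  cat(sprintf("Coalition frequencies (n = %g triads):\n", x$n))
  df <- data.frame(coalition = x$labels, count = x$counts,
                   observed = round(x$p, 4), expected = round(x$expected, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Frequency table from simulated outcomes
#'
#' Tabulates the formed coalitions of a session over the coalitions that can
#' form under its game configuration (so never-formed coalitions count as
#' zero), with uniform expected proportions over those feasible coalitions --
#' the standard "every coalition one-third of the time" benchmark when three
#' coalitions are formable.
#'
#' @param x a session result, list of outcomes, or outcome data frame.
#' @param config the [game_config()]; taken from the session result when
#'   available.
#' @param expected as in [freq_table()].
#' @return a `coalsim_freqtab` over formed triads only.
#' @export
outcome_freq_table <- function(x, config = NULL, expected = "uniform") {
  if (inherits(x, "coalsim_session_result")) {
    config <- config %||% x$session$game
    x <- x$table
  }
  if (!is.data.frame(x)) x <- outcomes_table(x)
  formed <- x$coalition[x$status == "FORMED"]
  labels <- if (!is.null(config)) names(feasible_coalitions(config))
            else sort(unique(formed))
  counts <- vapply(labels, function(l) sum(formed == l), numeric(1))
  freq_table(counts = counts, expected = expected)
}

#' Cohen's w effect size for a frequency table
#'
#' `w = sqrt(sum((p_i - pi_i)^2 / pi_i))`, the effect size of the chi-square
#' goodness-of-fit test: 0 when the observed distribution matches the
#' expectation, with 0.1/0.3/0.5 the conventional small/medium/large
#' landmarks.
#'
#' @param table a [freq_table()].
#' @return Cohen's w (unrounded; round only for display).
#' @examples
#' cohens_w(freq_table(proportions = c(BC = 0.67, AC = 0.29, AB = 0.04),
#'                     n = 52)) # ~0.78
#' @export
cohens_w <- function(table) {
  stopifnot(inherits(table, "coalsim_freqtab"))
  if (any(table$expected <= 0)) {
    stop_coalsim("zero_expected", "all expected proportions must be > 0")
  }
  sqrt(sum((table$p - table$expected)^2 / table$expected))
}

#' Chi-square goodness-of-fit test
#'
#' The test statistic is `n * w^2` (identical to the usual Pearson statistic
#' on counts), with `k - 1` degrees of freedom and an upper-tail central
#' chi-square p value.
#'
#' @param table a [freq_table()].
#' @return list with `statistic`, `df`, and `p.value`.
#' @export
chisq_gof <- function(table) {
  w <- cohens_w(table)
  stat <- table$n * w^2
  df <- length(table$p) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Power and minimum detectable effect of the goodness-of-fit test
#'
#' `gof_power()` returns the probability that the chi-square goodness-of-fit
#' test rejects at level `alpha` when the true effect size is `w` with `n`
#' observations: the upper tail of the noncentral chi-square distribution
#' with noncentrality `lambda = n * w^2` beyond the central critical value.
#' `min_detectable_w()` inverts it: the smallest `w` detected with the given
#' `power`, found by bisecting on `lambda` over `[1e-6, 1e3]` to a `1e-10`
#' bracket. The two functions are mutual inverses.
#'
#' @param w Cohen's w effect size (`> 0`).
#' @param n number of observations (triads).
#' @param df degrees of freedom of the test (`k - 1`).
#' @param alpha significance level.
#' @param power target power in `(0, 1)`.
#' @return a power in `[0, 1]`, resp. an effect size `w`.
#' @examples
#' min_detectable_w(0.80, n = 52, df = 2) # ~0.43
#' gof_power(0.78, n = 52, df = 2)        # essentially 1
#' @export
gof_power <- function(w, n, df = 2, alpha = 0.05) {
  stopifnot(w >= 0, n >= 1, df >= 1, alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = n * w^2, lower.tail = FALSE)
}

#' @rdname gof_power
#' @export
min_detectable_w <- function(power = 0.80, n, df = 2, alpha = 0.05) {
  stopifnot(power > 0, power < 1, n >= 1, df >= 1, alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df)
  f <- function(lambda) {
    stats::pchisq(crit, df, ncp = lambda, lower.tail = FALSE) - power
  }
  lo <- 1e-6
  hi <- 1e3
  if (f(lo) > 0 || f(hi) < 0) {
    stop_coalsim("no_root", "power equation has no root in the bracket")
  }
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  sqrt((lo + hi) / 2 / n)
}

#' Odds ratio between two proportions
#'
#' `OR = [p1 / (1 - p1)] / [p2 / (1 - p2)]`. The count form
#' `odds_ratio_counts(x1, n1, x2, n2)` is the same quantity computed from
#' successes out of totals.
#'
#' @param p1,p2 proportions strictly inside (0, 1).
#' @param x1,x2 success counts; `n1,n2` totals.
#' @return the odds ratio (`> 0`; 1 when the proportions are equal).
#' @examples
#' odds_ratio(0.673, 0.576) # ~1.51
#' @export
odds_ratio <- function(p1, p2) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1)) {
    stop_coalsim("boundary_proportion",
                 "proportions must be strictly between 0 and 1")
  }
  (p1 / (1 - p1)) / (p2 / (1 - p2))
}

#' @rdname odds_ratio
#' @export
odds_ratio_counts <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x2 >= 0, n1 > x1, n2 > x2)
  if (x1 == 0 || x2 == 0) {
    stop_coalsim("boundary_proportion", "zero cells give a degenerate odds ratio")
  }
  (x1 / (n1 - x1)) / (x2 / (n2 - x2))
}

#' Cohen's d for two independent groups
#'
#' Standardized mean difference with the pooled standard deviation
#' `s_p = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param m1,m2 group means.
#' @param sd1,sd2 group standard deviations (`> 0`).
#' @param n1,n2 group sizes (`>= 2`).
#' @return Cohen's d.
#' @examples
#' cohens_d(4.48, 1.77, 171, 3.60, 1.89, 170) # ~0.48
#' @export
cohens_d <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (!is.finite(s_pooled) || s_pooled <= 0) {
    stop_coalsim("bad_pooled_sd", "pooled standard deviation is not positive")
  }
  (m1 - m2) / s_pooled
}

#' Effect summary for a frequency table
#'
#' Bundles the quantities usually reported together for a coalition
#' distribution: Cohen's w, the goodness-of-fit statistic and p value, the
#' achieved power at the observed w, and the minimum detectable effect size
#' at the design power. Values are unrounded; round only for display.
#'
#' @param table a [freq_table()].
#' @param alpha significance level.
#' @param power design power for the minimum detectable effect size.
#' @return list with `n`, `w`, `statistic`, `df`, `p.value`, `power_at_w`,
#'   and `mdes`.
#' @export
effect_summary <- function(table, alpha = 0.05, power = 0.80) {
  w <- cohens_w(table)
  gof <- chisq_gof(table)
  degenerate <- gof$df < 1 # a single category leaves nothing to test
  list(
    n = table$n, w = w, statistic = gof$statistic, df = gof$df,
    p.value = gof$p.value,
    power_at_w = if (degenerate) NA_real_
                 else if (w > 0) gof_power(w, table$n, gof$df, alpha)
                 else alpha,
    mdes = if (degenerate) NA_real_
           else min_detectable_w(power, table$n, gof$df, alpha)
  )
}
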