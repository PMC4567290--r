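#' Goodness-of-fit chi-square against a reference proportion
#'
#' Two-cell goodness-of-fit test of `k` successes in `n` trials against a
#' reference proportion `p0`, with no continuity correction:
#' `chi2 = (k - n p0)^2 / (n p0) + ((n - k) - n (1 - p0))^2 / (n (1 - p0))`,
#' on 1 degree of freedom. This is the test used to compare an observed
#' mitotype or morphotype frequency (e.g. in managed or feral hives) against
#' the frequency seen among foraging workers, or against an expected
#' misclassification rate. Expected cells below 5 trigger a warning only —
#' small expecteds are inherent to some of the published comparisons.
#'
#' @param k Observed successes (0 <= k <= n).
#' @param n Trials.
#' @param p0 Reference proportion in (0, 1).
#' @return Object of class `afb_gof` with `chi2`, `df`, `p_value`, `observed`,
#'   `expected`.
#' @export
#' @examples
#' gof_chisq(3, 24, 0.65)  # managed hives vs foraging workers
gof_chisq <- function(k, n, p0) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p0) == 1L)
  if (is.na(k) || is.na(n) || k < 0 || n < 1 || k > n) {
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  }
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) {
    stop("p0 must lie strictly between 0 and 1", call. = FALSE)
  }
  observed <- c(success = k, failure = n - k)
  expected <- c(success = n * p0, failure = n * (1 - p0))
  if (any(expected == 0)) stop("expected cell count of zero", call. = FALSE)
  if (any(expected < 5)) {
    warning("expected cell count below 5; chi-square approximation is rough",
            call. = FALSE)
  }
  chi2 <- sum((observed - expected)^2 / expected)
  structure(list(
    chi2 = chi2, df = 1L,
    p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
    observed = observed, expected = expected
  ), class = "afb_gof")
}

#' @export
print.afb_gof <- function(x, ...) {
  cat(sprintf("chi-square goodness of fit: X2 = %.5g, DF = %d, P = %.4g\n",
              x$chi2, x$df, x$p_value))
  cat("observed:", paste(sprintf("%g", x$observed), collapse = ", "), "\n")
  cat("expected:", paste(sprintf("%.3f", x$expected), collapse = ", "), "\n")
  invisible(x)
}

#' Site-heterogeneity chi-square against a binomial null
#'
#' Tests whether the per-site counts of African-mitotype workers (0..k of the
#' k workers sampled per site) are consistent with drawing k workers
#' independently from a single population with African-mitotype frequency
#' `p_hat`. Expected cell `j` is `N_sites * C(k, j) * p_hat^j *
#' (1 - p_hat)^(k - j)`. The published convention tests on `df = k` even
#' though `p_hat` is estimated from the same data; the stricter `df = k - 1`
#' is available via `df_convention = "conservative"`.
#'
#' @param category_counts Integer vector of length `k + 1`: number of sites
#'   with 0, 1, ..., k African-mitotype workers (see
#'   [site_category_histogram()]).
#' @param p_hat Estimated African-mitotype frequency in (0, 1).
#' @param df_convention `"paper"` (df = k, default) or `"conservative"`
#'   (df = k - 1).
#' @return Object of class `afb_gof`.
#' @export
#' @examples
#' heterogeneity_chisq(c(14, 21, 26, 34), 0.65)
heterogeneity_chisq <- function(category_counts, p_hat,
                                df_convention = c("paper", "conservative")) {
  df_convention <- match.arg(df_convention)
  k <- length(category_counts) - 1L
  if (k < 1L) stop("need counts for at least categories 0 and 1", call. = FALSE)
  if (any(category_counts < 0) || anyNA(category_counts)) {
    stop("category counts must be non-negative", call. = FALSE)
  }
  if (!is.finite(p_hat) || p_hat <= 0 || p_hat >= 1) {
    stop("p_hat must lie strictly between 0 and 1", call. = FALSE)
  }
  n_sites <- sum(category_counts)
  expected <- n_sites * stats::dbinom(0:k, size = k, prob = p_hat)
  if (any(expected == 0)) stop("expected cell count of zero", call. = FALSE)
  chi2 <- sum((category_counts - expected)^2 / expected)
  df <- if (df_convention == "paper") k else k - 1L
  structure(list(
    chi2 = chi2, df = as.integer(df),
    p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE),
    observed = stats::setNames(category_counts, 0:k),
    expected = stats::setNames(expected, 0:k)
  ), class = "afb_gof")
}

#' Pooled-variance two-sample t test
#'
#' Classic equal-variance two-sample t test on `df = n_a + n_b - 2`, used to
#' compare mean discriminant scores of workers (or colonies) carrying African
#' versus European mitochondria. One group may be as small as the published
#' feral comparison (3 vs 7) as long as the pooled variance remains defined
#' (`n_a + n_b >= 3`). The one-tailed p-value is the tail probability in the
#' direction of the observed difference.
#'
#' @param scores_a,scores_b Numeric score vectors for the two groups.
#' @param tails `"two"` (default) or `"one"`.
#' @return Object of class `afb_ttest` with `t`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `tails`.
#' @export
#' @examples
#' pooled_t(c(1, 2, 3), c(4, 5, 6))
pooled_t <- function(scores_a, scores_b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  na <- length(scores_a)
  nb <- length(scores_b)
  if (na < 1L || nb < 1L || na + nb < 3L) {
    stop("need at least one score per group and n_a + n_b >= 3", call. = FALSE)
  }
  if (anyNA(scores_a) || anyNA(scores_b)) stop("scores contain NA", call. = FALSE)
  ma <- mean(scores_a)
  mb <- mean(scores_b)
  df <- na + nb - 2L
  sp2 <- (sum((scores_a - ma)^2) + sum((scores_b - mb)^2)) / df
  if (sp2 == 0) {
    if (ma == mb) {
      t <- 0
    } else {
      stop("zero pooled variance with unequal means (infinite t)", call. = FALSE)
    }
  } else {
    t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  p_one <- stats::pt(-abs(t), df = df)
  structure(list(
    t = t, df = as.integer(df),
    p_value = if (tails == "two") 2 * p_one else p_one,
    mean_a = ma, mean_b = mb, tails = tails
  ), class = "afb_ttest")
}

#' @export
print.afb_ttest <- function(x, ...) {
  cat(sprintf("pooled t test (%s-tailed): t = %.4g, DF = %d, P = %.4g\n",
              x$tails, x$t, x$df, x$p_value))
  cat(sprintf("group means: %.4f vs %.4f\n", x$mean_a, x$mean_b))
  invisible(x)
}

#' African-mitotype frequency with Wilson interval
#'
#' Estimates the African-mitotype frequency from confident binary mitotype
#' calls and reports a Wilson score confidence interval (well-behaved at
#' extreme frequencies, where the Wald interval degenerates). Indeterminate
#' or non-mitotype calls are excluded and counted.
#'
#' @param calls Character vector of calls (`"african"` / `"european"`; other
#'   values are excluded), or a data frame with columns `call` and
#'   `confident` as from [call_markers()].
#' @param conf Confidence level (default 0.95).
#' @return Object of class `afb_freq` with `p_hat`, `ci` (length-2), `n`,
#'   `n_excluded`.
#' @export
#' @examples
#' estimate_frequency(c(rep("african", 193), rep("european", 105)))
estimate_frequency <- function(calls, conf = 0.95) {
  if (is.data.frame(calls)) {
    keep <- if ("confident" %in% names(calls)) calls$confident else TRUE
    calls <- calls$call[keep]
  }
  cls <- .call_class(calls)
  usable <- cls %in% c("african", "european")
  n <- sum(usable)
  if (n == 0L) stop("no confident african/european calls", call. = FALSE)
  n_afr <- sum(cls[usable] == "african")
  p_hat <- n_afr / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  structure(list(
    p_hat = p_hat,
    ci = c(lower = max(0, centre - half), upper = min(1, centre + half)),
    n = n,
    n_excluded = length(calls) - n
  ), class = "afb_freq")
}

#' @export
print.afb_freq <- function(x, ...) {
  cat(sprintf("African-mitotype frequency: %.4f (Wilson 95%% CI %.4f-%.4f), n = %d",
              x$p_hat, x$ci[["lower"]], x$ci[["upper"]], x$n))
  if (x$n_excluded > 0) cat(sprintf(" (%d call(s) excluded)", x$n_excluded))
  cat("\n")
  invisible(x)
}
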