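# Shared one-row result constructor: every test in the battery returns the
# same columns so results rbind directly into test_results.tsv.
.test_result <- function(test, groups, statistic, df = NA_real_,
                         n = NA_integer_, m = NA_integer_,
                         p_raw = NA_real_, p_adjusted = NA_real_,
                         correction = "none") {
  data.frame(test = test, groups = groups, statistic = statistic,
             df = df, n = n, m = m, p_raw = p_raw, p_adjusted = p_adjusted,
             correction = correction, stringsAsFactors = FALSE)
}

#' Bonferroni correction
#'
#' @param p raw p-values.
#' @param m_tests family size (defaults to `length(p)`).
#' @return `pmin(1, m_tests * p)`.
#' @export
bonferroni <- function(p, m_tests = length(p)) {
  stopifnot(m_tests >= 1)
  pmin(1, m_tests * p)
}

#' Chi-square goodness-of-fit test
#'
#' \deqn{\chi^2 = \sum_{i=1}^{k} (O_i - E_i)^2 / E_i}
#' with an upper-tail p-value from the chi-square distribution on k - 1
#' degrees of freedom.
#'
#' @param observed observed counts (k >= 2).
#' @param expected expected counts, all > 0, same length.
#' @param groups label stored in the result row.
#' @return One-row test-result data.frame.
#' @export
#' @examples
#' chi2_gof(c(8, 2), c(5, 5))  # statistic 3.6, df 1
chi2_gof <- function(observed, expected, groups = "gof") {
  k <- length(observed)
  if (k < 2) stop("need at least 2 categories")
  if (length(expected) != k) stop("observed and expected lengths differ")
  if (any(expected <= 0)) stop("all expected counts must be > 0")
  stat <- sum((observed - expected)^2 / expected)
  df <- k - 1
  .test_result("chi2_gof", groups, stat, df = df,
               p_raw = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Kruskal-Wallis rank test
#'
#' \deqn{H = \frac{12}{N(N+1)} \sum_{i=1}^{k} R_i^2/n_i - 3(N+1)}
#' with midranks for ties and, by default, the standard tie correction
#' (H divided by \eqn{1 - \sum(t^3 - t)/(N^3 - N)}); the p-value comes from
#' the chi-square approximation on k - 1 degrees of freedom.
#'
#' @param values numeric observations.
#' @param groups group labels, same length; k >= 2 non-empty groups.
#' @param tie_correction apply the tie correction (default TRUE); FALSE
#'   evaluates the uncorrected textbook formula.
#' @return One-row test-result data.frame. When every value is identical the
#'   statistic is 0 and p = 1.
#' @export
#' @examples
#' kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))  # H = 7.2
kruskal_wallis <- function(values, groups, tie_correction = TRUE) {
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  N <- length(values)
  gl <- unique(groups)
  k <- length(gl)
  if (k < 2) stop("need at least 2 groups")
  if (N < 3) stop("need at least 3 observations")
  r <- rank(values)
  Ri <- tapply(r, groups, sum)
  ni <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  if (tie_correction) {
    t <- table(values)
    corr <- 1 - sum(t^3 - t) / (N^3 - N)
    if (corr == 0) {
      # all values identical: no evidence against the null
      return(.test_result("kruskal_wallis", paste(gl, collapse = "|"),
                          0, df = k - 1, p_raw = 1))
    }
    H <- H / corr
  }
  .test_result("kruskal_wallis", paste(gl, collapse = "|"), H, df = k - 1,
               p_raw = stats::pchisq(H, k - 1, lower.tail = FALSE))
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. The statistic is
#' \eqn{U = R_1 - n(n+1)/2} with \eqn{R_1} the rank sum of the first sample
#' (midranks for ties); \eqn{U + U' = nm}. The two-sided p-value uses the
#' large-sample normal approximation \eqn{U \sim N(nm/2,\; nm(N+1)/12)} with
#' the tie-corrected variance and, by default, a continuity correction. For
#' small samples (`exact = TRUE`, no ties) the exact Mann-Whitney
#' distribution is used instead as a cross-check.
#'
#' @param x,y numeric samples (both non-empty).
#' @param continuity apply the 0.5 continuity correction (normal mode).
#' @param exact use the exact distribution (requires no ties; intended for
#'   n*m <= 400).
#' @param n_tests Bonferroni family size applied to `p_adjusted`.
#' @return One-row test-result data.frame with `n`, `m` and the U statistic.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # complete separation: U = 0
mann_whitney_u <- function(x, y, continuity = TRUE, exact = FALSE,
                           n_tests = 1) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n <- length(x)
  m <- length(y)
  if (n * m == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n)])
  U <- R1 - n * (n + 1) / 2
  N <- n + m
  if (exact) {
    if (anyDuplicated(c(x, y))) stop("exact mode requires untied data")
    # stats::pwilcox is the exact Mann-Whitney U distribution
    p <- if (U > n * m / 2) {
      2 * stats::pwilcox(U - 1, n, m, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n, m)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * m / 2
    t <- table(c(x, y))
    tie_term <- sum(t^3 - t) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      if (continuity) z <- z - sign(z) * 0.5
      z <- z / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  out <- .test_result("mann_whitney_u", "x|y", U, n = n, m = m, p_raw = p,
                      p_adjusted = bonferroni(p, max(1, n_tests)),
                      correction = if (n_tests > 1) "bonferroni" else "none")
  out$method <- method
  out
}

# Royston (1995) AS R94 weights and p-value approximation; the computable
# form of the tabulated Shapiro-Wilk coefficients.
.sw_weights <- function(n) {
  m <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  c_ <- m / sqrt(sum(m^2))
  a <- c_
  if (n <= 3) {
    a <- c(-sqrt(0.5), 0, sqrt(0.5))[seq_len(n)]
    if (n == 3) a <- c(-sqrt(0.5), 0, sqrt(0.5))
    return(a)
  }
  u <- 1 / sqrt(n)
  a_n <- c_[n] + 0.221157 * u - 0.147981 * u^2 - 2.071190 * u^3 +
    4.434685 * u^4 - 2.706056 * u^5
  if (n > 5) {
    a_n1 <- c_[n - 1] + 0.042981 * u - 0.293762 * u^2 - 1.752461 * u^3 +
      5.682633 * u^4 - 3.582633 * u^5
    phi <- (sum(m^2) - 2 * m[n]^2 - 2 * m[n - 1]^2) /
      (1 - 2 * a_n^2 - 2 * a_n1^2)
    a <- m / sqrt(phi)
    a[n] <- a_n
    a[1] <- -a_n
    a[n - 1] <- a_n1
    a[2] <- -a_n1
  } else {
    phi <- (sum(m^2) - 2 * m[n]^2) / (1 - 2 * a_n^2)
    a <- m / sqrt(phi)
    a[n] <- a_n
    a[1] <- -a_n
  }
  a
}

#' Shapiro-Wilk normality test
#'
#' \deqn{W = \left(\sum a_i x_{(i)}\right)^2 / \sum (x_i - \bar x)^2}
#' with coefficients and p-value from the Royston (1995) approximation, the
#' computable form of the tabulated Shapiro-Wilk coefficients. W is invariant
#' under location-scale transforms and lies in (0, 1]; small W (small p)
#' rejects normality.
#'
#' @param x numeric sample, 3 <= n <= 5000, non-zero variance.
#' @return One-row test-result data.frame with the W statistic.
#' @export
shapiro_wilk <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 3 || n > 5000) stop("sample size must be in [3, 5000]")
  if (stats::var(x) == 0) stop("zero variance")
  a <- .sw_weights(n)
  W <- sum(a * x)^2 / sum((x - mean(x))^2)
  W <- min(W, 1)
  if (n == 3) {
    p <- max(0, min(1, 6 / pi * (asin(sqrt(W)) - asin(sqrt(0.75)))))
  } else if (n <= 11) {
    gamma <- -2.273 + 0.459 * n
    w <- -log(gamma - log1p(-W))
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sigma <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    p <- stats::pnorm((w - mu) / sigma, lower.tail = FALSE)
  } else {
    lg <- log(n)
    w <- log1p(-W)
    mu <- -1.5861 - 0.31082 * lg - 0.083751 * lg^2 + 0.0038915 * lg^3
    sigma <- exp(-0.4803 - 0.082676 * lg + 0.0030302 * lg^2)
    p <- stats::pnorm((w - mu) / sigma, lower.tail = FALSE)
  }
  .test_result("shapiro_wilk", "x", W, n = n, p_raw = p)
}
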