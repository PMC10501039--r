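#' @importFrom stats pnorm pf pt pchisq cor lm coef fitted var
NULL

# ---- Mann-Whitney U ---------------------------------------------------------

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, for tie-free samples of sizes `n1` and `n2`, the number of rank
#' arrangements yielding each value of U, by the standard dynamic-programming
#' recurrence `f(i, j, u) = f(i-1, j, u-j) + f(i, j-1, u)`. Counts are exact
#' in double precision for the supported sizes (`n1 + n2 <= 24`, total mass
#' `choose(n1+n2, n1) < 2^31`).
#'
#' @param n1,n2 sample sizes (>= 1).
#' @return tibble `u, count, prob` over `u = 0 .. n1*n2`.
#' @export
exact_u_null <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (n1 + n2 > 24) {
    stop("exact null supported up to n1 + n2 = 24; ",
         "use the normal approximation for larger samples")
  }
  # f[[j]][u+1] after processing i rows: arrangements of i x's, j y's with U=u
  umax <- n1 * n2
  f <- matrix(0, nrow = n2 + 1, ncol = umax + 1)
  f[, 1] <- 0
  f[1, 1] <- 1          # i = 0: any j, U = 0 (will fill below)
  f[, 1] <- 1           # i = 0 row: for all j, single arrangement with U = 0
  for (i in seq_len(n1)) {
    g <- matrix(0, nrow = n2 + 1, ncol = umax + 1)
    g[1, 1] <- 1        # j = 0: U = 0
    for (j in seq_len(n2)) {
      # g[j+1, u+1] = g_prev_i[j+1, u-j+1] + g[j, u+1]
      shifted <- c(rep(0, j), f[j + 1, seq_len(umax + 1 - j)])
      g[j + 1, ] <- shifted + g[j, ]
    }
    f <- g
  }
  counts <- f[n2 + 1, ]
  total <- choose(n1 + n2, n1)
  stopifnot(isTRUE(all.equal(sum(counts), total)))
  tibble::tibble(u = 0:umax, count = counts, prob = counts / total)
}

#' Mann-Whitney U test (exact for small tie-free samples)
#'
#' U is computed from mid-ranks as the number of (x, y) pairs with x > y,
#' counting ties as 1/2. For tie-free data with `n1 + n2 <= 20` the p-value
#' is exact, from [exact_u_null()]; otherwise a normal approximation with
#' tie correction (and no continuity correction) is used. The two-tailed
#' p-value is `min(1, 2 * one-tailed)`, matching the halving convention of
#' the reported score tables.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two_sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @return list with `u_statistic` (U of `x` over `y`), `n1`, `n2`,
#'   `p_one_tailed`, `p_two_tailed`, `method` (`"exact"` or
#'   `"normal_approx"`), `tie_correction_applied`, `degenerate`.
#' @export
mann_whitney <- function(x, y, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs x > y (+ 1/2 ties)
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  degenerate <- length(unique(pooled)) == 1

  if (degenerate) {
    p_greater <- p_less <- 0.5
    method <- "normal_approx"
  } else if (!has_ties && n1 + n2 <= 20) {
    null <- exact_u_null(n1, n2)
    p_greater <- sum(null$prob[null$u >= u])  # x stochastically larger
    p_less <- sum(null$prob[null$u <= u])
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p_greater <- p_less <- 0.5
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p_greater <- pnorm(z, lower.tail = FALSE)
      p_less <- pnorm(z)
    }
    method <- "normal_approx"
  }
  p_one <- switch(alternative,
    two_sided = min(p_greater, p_less),
    greater = p_greater,
    less = p_less
  )
  p_two <- min(1, 2 * min(p_greater, p_less))
  if (degenerate) p_two <- 1
  list(
    u_statistic = u, n1 = n1, n2 = n2,
    p_one_tailed = p_one, p_two_tailed = p_two,
    method = method, tie_correction_applied = method == "normal_approx" && has_ties,
    degenerate = degenerate
  )
}

# ---- correlations -----------------------------------------------------------

#' Verbal strength category for a correlation coefficient
#'
#' Conventional interpretation bins on `|r|`, closed on the left:
#' very weak `[0, 0.2)`, weak `[0.2, 0.4)`, moderate `[0.4, 0.6)`,
#' strong `[0.6, 0.8)`, very strong `[0.8, 1]`.
#'
#' @param r correlation coefficient in `[-1, 1]`.
#' @return character scalar.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  if (a < 0.2) "very_weak"
  else if (a < 0.4) "weak"
  else if (a < 0.6) "moderate"
  else if (a < 0.8) "strong"
  else "very_strong"
}

#' Pearson / Spearman correlation with significance and strength
#'
#' Product-moment (or rank) correlation with the two-tailed p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom (for
#' Spearman this t approximation is applied to the rank correlation).
#'
#' @param x,y numeric vectors, `n >= 3` complete pairs; neither constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return list `r, p_value, n, method, strength`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    stop("correlation undefined for a constant input")
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p_value = p, n = n, method = method,
       strength = correlation_strength(r))
}

# ---- polynomial regression --------------------------------------------------

#' Polynomial curve fit with overall F test
#'
#' Least-squares fit of `y` on `1, x, ..., x^degree`, reported the way curve
#' estimation modules print it: coefficients, multiple correlation
#' `r = sqrt(R^2)`, and the overall F statistic
#' `F = (R^2 / k) / ((1 - R^2) / (n - k - 1))` on `(k, n - k - 1)` degrees
#' of freedom.
#'
#' @param x,y numeric vectors; `n > degree + 1` and at least `degree + 1`
#'   distinct `x` values.
#' @param degree 2 (quadratic) or 3 (cubic).
#' @return list `degree, coefficients (b0..bk), r, f_statistic, df, p_value,
#'   formula` (a rendered formula string).
#' @export
polyfit_f <- function(x, y, degree = 2) {
  stopifnot(degree %in% c(2, 3))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= degree + 1) stop("need more than degree + 1 points")
  if (length(unique(x)) <= degree) {
    stop("singular fit: fewer than degree + 1 distinct x values")
  }
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  b <- unname(coef(fit))
  if (anyNA(b)) stop("singular fit: rank-deficient design")
  # noiseless inputs (exact interpolation) are legitimate; silence the
  # "essentially perfect fit" advisory summary.lm emits for them
  r2 <- suppressWarnings(summary(fit)$r.squared)
  k <- degree
  df2 <- n - k - 1
  if (r2 >= 1) {
    fstat <- Inf; p <- 0
  } else {
    fstat <- (r2 / k) / ((1 - r2) / df2)
    p <- pf(fstat, k, df2, lower.tail = FALSE)
  }
  terms <- c(sprintf("%.4g", b[1]),
             sprintf("%+.4g*X", b[2]),
             sprintf("%+.4g*X^%d", b[3:(degree + 1)], 2:degree))
  list(
    degree = degree, coefficients = b, r = sqrt(max(0, r2)),
    f_statistic = fstat, df = c(k, df2), p_value = p,
    formula = paste0("Y = ", paste(terms, collapse = " "))
  )
}

# ---- Box's M ----------------------------------------------------------------

#' Box's M test for equality of covariance matrices
#'
#' `M = (N - g) ln|S_pooled| - sum (n_i - 1) ln|S_i|` with the standard
#' chi-squared approximation: `X2 = M (1 - c)` where
#' `c = (2p^2 + 3p - 1) / (6 (p + 1)(g - 1)) * (sum 1/(n_i - 1) - 1/(N - g))`,
#' on `p (p + 1)(g - 1) / 2` degrees of freedom. M is zero iff all group
#' sample covariance matrices are identical.
#'
#' @param groups list of numeric matrices (observations x variables), one per
#'   group; each group needs more observations than variables and a
#'   nonsingular covariance.
#' @return list `m_statistic, chi2_approx, df, p_value`.
#' @export
boxs_m <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, as.matrix)
  p <- ncol(groups[[1]])
  if (any(vapply(groups, ncol, 0L) != p)) stop("groups must share variables")
  n <- vapply(groups, nrow, 0L)
  if (any(n <= p)) {
    stop("each group needs more observations than variables (n_i > p)")
  }
  g <- length(groups)
  N <- sum(n)
  covs <- lapply(groups, stats::cov)
  logdets <- vapply(seq_len(g), function(i) {
    d <- determinant(covs[[i]], logarithm = TRUE)
    if (d$sign <= 0) stop("singular covariance matrix in group ", i)
    as.numeric(d$modulus)
  }, 0)
  s_pooled <- Reduce(`+`, Map(function(S, ni) (ni - 1) * S, covs, n)) / (N - g)
  dp <- determinant(s_pooled, logarithm = TRUE)
  if (dp$sign <= 0) stop("singular pooled covariance matrix")
  m <- (N - g) * as.numeric(dp$modulus) - sum((n - 1) * logdets)
  m <- max(m, 0)  # clip tiny negative rounding
  cc <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1)) *
    (sum(1 / (n - 1)) - 1 / (N - g))
  chi2 <- m * (1 - cc)
  df <- p * (p + 1) * (g - 1) / 2
  list(m_statistic = m, chi2_approx = chi2, df = df,
       p_value = pchisq(chi2, df, lower.tail = FALSE))
}
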