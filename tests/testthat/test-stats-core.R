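test_that("exact U null distribution has the right support and mass", {
  n11 <- exact_u_null(1, 1)
  expect_equal(n11$prob, c(0.5, 0.5))
  n33 <- exact_u_null(3, 3)
  expect_equal(sum(n33$count), choose(6, 3))
  expect_equal(n33$prob[n33$u == 0], 1 / 20)
  n99 <- exact_u_null(9, 9)
  expect_equal(sum(n99$count), 48620)  # C(18, 9)
  # null symmetry about n1*n2/2
  expect_equal(n99$count, rev(n99$count))
  expect_error(exact_u_null(13, 13), "up to")
})

test_that("exact Mann-Whitney p equals brute-force enumeration (n1, n2 <= 7)", {
  set.seed(401)
  sizes <- list(c(2, 3), c(3, 3), c(4, 5), c(5, 2), c(6, 6), c(7, 7))
  for (s in sizes) {
    for (rep in 1:3) {
      x <- rnorm(s[1]); y <- rnorm(s[2])  # continuous -> tie-free
      got <- mann_whitney(x, y)
      want <- brute_force_mw_p(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$u_statistic, want$u)
      expect_equal(got$p_two_tailed, want$p_two)
      expect_equal(got$p_one_tailed, want$p_one)
    }
  }
})

test_that("exact Mann-Whitney p agrees with the standard implementation", {
  set.seed(402)
  for (rep in 1:5) {
    x <- rnorm(8); y <- rnorm(9, 0.8)
    got <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(got$u_statistic, unname(ref$statistic))
    expect_equal(got$p_two_tailed, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney honours its structural identities", {
  # complete separation at 9 vs 9: U = 0 (or 81), smallest achievable p
  mw <- mann_whitney(1:9, 101:109)
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_two_tailed, 2 / 48620)
  expect_equal(mw$p_one_tailed, 1 / 48620)
  # identical samples: U = n1*n2/2 by mid-ranks, p ~ 1
  mw_eq <- mann_whitney(1:9, 1:9)
  expect_equal(mw_eq$u_statistic, 40.5)
  expect_gt(mw_eq$p_two_tailed, 0.95)
  # U(x, y) + U(y, x) = n1 * n2, with and without ties
  set.seed(403)
  for (rep in 1:10) {
    x <- sample(1:12, 7, replace = TRUE)
    y <- sample(1:12, 5, replace = TRUE)
    expect_equal(mann_whitney(x, y)$u_statistic +
                 mann_whitney(y, x)$u_statistic, 35)
  }
  # one-tailed p is half the two-tailed p for tie-free data
  set.seed(404)
  x <- rnorm(9); y <- rnorm(9, 1)
  mw2 <- mann_whitney(x, y)
  expect_equal(mw2$p_one_tailed, mw2$p_two_tailed / 2)
  # constant pooled sample: degenerate flag and p = 1
  mw_const <- mann_whitney(rep(2, 5), rep(2, 6))
  expect_true(mw_const$degenerate)
  expect_equal(mw_const$p_two_tailed, 1)
})

test_that("correlation machinery matches cor.test and the strength bins", {
  x <- 1:10
  perf <- correlate(x, 2 * x + 1)
  expect_equal(perf$r, 1)
  expect_equal(perf$strength, "very_strong")

  set.seed(405)
  a <- rnorm(20); b <- 0.6 * a + rnorm(20)
  got <- correlate(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  got_s <- correlate(a, b, "spearman")
  ref_s <- stats::cor.test(a, b, method = "spearman")
  expect_equal(got_s$r, unname(ref_s$estimate))

  # invariance under positive affine transforms
  expect_equal(correlate(10 + 3 * a, b)$r, got$r)
  expect_equal(correlate(a, -2 * b)$r, -got$r)

  # strength bins closed on the left; 0.80 is very strong
  expect_equal(correlation_strength(0.637), "strong")
  expect_equal(correlation_strength(0.945), "very_strong")
  expect_equal(correlation_strength(0.80), "very_strong")
  expect_equal(correlation_strength(-0.45), "moderate")
  expect_equal(correlation_strength(0.199), "very_weak")

  expect_error(correlate(rep(1, 5), rnorm(5)), "constant")

  # large-sample null behaviour
  set.seed(406)
  expect_lt(abs(correlate(rnorm(10000), rnorm(10000))$r), 0.05)
})

test_that("polynomial fits match the closed-form least-squares solution", {
  # noiseless quadratic is recovered exactly
  x <- seq(-2, 2, length.out = 12)
  y <- 1.5 - 0.7 * x + 2.25 * x^2
  fit <- polyfit_f(x, y, 2)
  expect_equal(fit$coefficients, c(1.5, -0.7, 2.25), tolerance = 1e-8)
  expect_equal(fit$r, 1)

  # normal-equations oracle on noisy data
  set.seed(407)
  xn <- runif(18, 0, 3); yn <- 2 + xn - 0.5 * xn^2 + rnorm(18)
  for (deg in 2:3) {
    f <- polyfit_f(xn, yn, deg)
    X <- outer(xn, 0:deg, `^`)
    beta <- solve(crossprod(X), crossprod(X, yn))
    expect_equal(f$coefficients, drop(beta), tolerance = 1e-8)
    expect_equal(f$df, c(deg, 18 - deg - 1))
    # F statistic from R^2 definition
    r2 <- f$r^2
    expect_equal(f$f_statistic, (r2 / deg) / ((1 - r2) / (18 - deg - 1)))
  }

  # saturated cubic through 4 + 1 points interpolates when n = deg + 2?
  # exact interpolation case: 5 points, cubic through 4 distinct x with n=5
  xi <- c(0, 1, 2, 3, 4); yi <- 2 - xi + 0.5 * xi^2 - 0.1 * xi^3
  expect_equal(polyfit_f(xi, yi, 3)$r, 1)

  # quadratic multiple correlation dominates the simple |r| (nested models)
  set.seed(408)
  for (rep in 1:5) {
    xs <- rnorm(15); ys <- rnorm(15)
    expect_gte(polyfit_f(xs, ys, 2)$r + 1e-12, abs(correlate(xs, ys)$r))
  }

  expect_error(polyfit_f(c(1, 1, 1, 2, 2), c(1, 2, 3, 4, 5), 2), "singular")
})

test_that("Box's M is zero for identical groups and matches hand computation", {
  set.seed(409)
  g <- matrix(rnorm(40), 20, 2)
  same <- boxs_m(list(g, g))
  expect_equal(same$m_statistic, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-10)

  # hand-computed 2-variable, 2-group oracle, written out term by term
  g1 <- matrix(c(1, 2, 3, 4, 5, 2, 1, 3, 5, 4), ncol = 2)
  g2 <- matrix(c(2, 4, 6, 8, 10, 1, 5, 3, 2, 9), ncol = 2)
  s1 <- stats::cov(g1); s2 <- stats::cov(g2)
  det2 <- function(S) S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  sp <- (4 * s1 + 4 * s2) / 8
  m_hand <- 8 * log(det2(sp)) - 4 * log(det2(s1)) - 4 * log(det2(s2))
  c_hand <- (2 * 4 + 3 * 2 - 1) / (6 * 3 * 1) * (1 / 4 + 1 / 4 - 1 / 8)
  got <- boxs_m(list(g1, g2))
  expect_equal(got$m_statistic, m_hand, tolerance = 1e-10)
  expect_equal(got$chi2_approx, m_hand * (1 - c_hand), tolerance = 1e-10)
  expect_equal(got$df, 3)

  # invariance under a common nonsingular linear transform
  A <- matrix(c(2, 1, 0.5, -1), 2)
  got_t <- boxs_m(list(g1 %*% A, g2 %*% A))
  expect_equal(got_t$m_statistic, got$m_statistic, tolerance = 1e-8)

  expect_error(boxs_m(list(matrix(1:4, 2), matrix(1:4, 2))), "n_i > p")
})
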