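test_that("pair-counting AUC reproduces the analytic discordance identities", {
  neg <- 1:9
  one_discordant <- c(8.5, 10:17)      # a single positive below one control
  r1 <- roc_curve(c(one_discordant, neg),
                  c(rep("positive", 9), rep("control", 9)))
  expect_equal(r1$auc, 80 / 81)
  expect_equal(round(r1$auc, 4), 0.9877)

  seven_discordant <- c(2.5, 10:17)    # seven controls above one positive
  r7 <- roc_curve(c(seven_discordant, neg),
                  c(rep("positive", 9), rep("control", 9)))
  expect_equal(r7$auc, 74 / 81)
  expect_equal(round(r7$auc, 4), 0.9136)

  # complete separation: AUC 1 and a perfect Youden cutoff
  rs <- roc_curve(c(11:19, 1:9), groups_9v9)
  expect_equal(rs$auc, 1)
  expect_equal(rs$sensitivity_at_cutoff, 1)
  expect_equal(rs$specificity_at_cutoff, 1)

  expect_error(roc_curve(1:5, rep("positive", 5)), "both")
})

test_that("the ROC curve is a valid non-decreasing path from (0,0) to (1,1)", {
  set.seed(701)
  v <- c(rnorm(9, 1), rnorm(9))
  r <- roc_curve(v, groups_9v9)
  expect_equal(r$sensitivity[1], 0)
  expect_equal(r$specificity[1], 1)
  expect_equal(r$sensitivity[length(r$sensitivity)], 1)
  expect_equal(r$specificity[length(r$specificity)], 0)
  expect_true(all(diff(r$sensitivity) >= 0))
  expect_true(all(diff(r$specificity) <= 0))
})

test_that("AUC equals the Mann-Whitney identity U/(n1 n2) on random data", {
  set.seed(702)
  for (i in 1:100) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    # mix of continuous and tied integer data
    if (i %% 2 == 0) {
      pos <- rnorm(n1, 0.5); neg <- rnorm(n2)
    } else {
      pos <- sample(1:6, n1, replace = TRUE)
      neg <- sample(1:6, n2, replace = TRUE)
    }
    r <- roc_curve(c(pos, neg),
                   c(rep("positive", n1), rep("control", n2)),
                   auto_orient = FALSE)
    u <- mann_whitney(pos, neg)$u_statistic
    expect_equal(r$auc, u / (n1 * n2))
  }
})

test_that("auto-orientation reports decreasing markers on the informative scale", {
  set.seed(703)
  v <- c(rnorm(9, -2), rnorm(9))     # positives LOWER
  r <- roc_curve(v, groups_9v9)
  expect_true(r$orientation_flipped)
  expect_gt(r$auc, 0.5)
  r_neg <- roc_curve(-v, groups_9v9)
  expect_false(r_neg$orientation_flipped)
  expect_equal(r$auc, r_neg$auc)
  # the flipped curve reports its cutoff on the negated scale, so the two
  # cutoffs coincide there (i.e. mirror each other on the original scale)
  expect_equal(r$youden_cutoff, r_neg$youden_cutoff)
})

test_that("label permutation gives chance-level AUC on average", {
  set.seed(704)
  v <- rnorm(18)
  aucs <- replicate(1000, {
    roc_curve(v, sample(groups_9v9), auto_orient = FALSE)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("combined indices are OLS fitted values of the diagnosis indicator", {
  set.seed(705)
  n <- 18
  x1 <- c(rlnorm(9, 12, 0.3), rlnorm(9, 11, 0.3))
  x2 <- c(rlnorm(9, 10, 0.5), rlnorm(9, 10.4, 0.5))
  pt <- pt_from_matrix(cbind(m1 = x1, m2 = x2), groups_9v9)
  idx <- combined_index(pt, c("m1", "m2"))
  y <- as.numeric(groups_9v9 == "positive")
  ref <- lm(y ~ x1 + x2)
  expect_equal(idx$values$index, unname(fitted(ref)))
  expect_equal(idx$intercept, unname(coef(ref)[1]))

  # single perfectly separating member: index ROC is the raw-marker ROC
  sep <- c(101:109, 1:9)
  pts <- pt_from_matrix(cbind(s = sep), groups_9v9)
  idx_s <- combined_index(pts, "s")
  expect_equal(roc_curve(idx_s$values$index, groups_9v9)$auc, 1)
  expect_equal(roc_curve(idx_s$values$index, groups_9v9)$auc,
               roc_curve(sep, groups_9v9)$auc)

  # PRE-1 ranking (hence the ROC) is invariant to rescaling a member
  pt_scaled <- pt_from_matrix(cbind(m1 = x1 * 1e3 + 5, m2 = x2), groups_9v9)
  idx2 <- combined_index(pt_scaled, c("m1", "m2"))
  expect_equal(roc_curve(idx2$values$index, groups_9v9)$auc,
               roc_curve(idx$values$index, groups_9v9)$auc)

  # collinear members are rejected
  pt_col <- pt_from_matrix(cbind(m1 = x1, m2 = 2 * x1), groups_9v9)
  expect_error(combined_index(pt_col, c("m1", "m2")), "rank deficient")
})

test_that("pair-counting AUC matches the reference ROC implementation", {
  set.seed(706)
  for (i in 1:20) {
    v <- c(rnorm(9, 0.8), rnorm(9))
    r <- roc_curve(v, groups_9v9, auto_orient = FALSE)
    ref <- suppressMessages(pROC::auc(
      response = factor(groups_9v9, levels = c("control", "positive")),
      predictor = v, direction = "<"
    ))
    expect_equal(r$auc, as.numeric(ref))
  }
})

test_that("index-score correlations honour missingness and match the oracle", {
  d <- generate_dataset(default_calibration(2015))
  idx <- combined_index(d$peaks, c("texanol", "texanol_isomer"))

  # GRID-HAMD is determined only for positives: n is at most 9
  cr <- correlate_index(idx, d$cohort, "grid_hamd")
  expect_lte(cr$n, 9)
  crx <- correlate_index(idx, d$cohort, "grid_hamd",
                         exclude_agoraphobia_only = TRUE)
  expect_equal(crx$n, cr$n - 1)

  # an index equal to the score correlates perfectly, quadratic R^2 = 1
  fake <- tibble::tibble(subject_id = d$cohort$subject_id,
                         index = d$cohort$kihon_cl + 0)
  cr1 <- correlate_index(fake, d$cohort, "kihon_cl")
  expect_equal(cr1$pearson$r, 1)
  expect_equal(cr1$fit_quadratic$r, 1)

  # fits agree with the closed-form normal-equations solution
  cr2 <- correlate_index(idx, d$cohort, "sds")
  w <- dplyr::inner_join(idx$values, d$cohort, by = "subject_id")
  X <- outer(w$index, 0:2, `^`)
  beta <- solve(crossprod(X), crossprod(X, w$sds))
  expect_equal(cr2$fit_quadratic$coefficients, drop(beta), tolerance = 1e-8)

  expect_error(
    correlate_index(idx$values[1:3, ], d$cohort, "sds"),
    "insufficient"
  )
})
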