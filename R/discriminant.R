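#' Fit a two-class quadratic discriminant model
#'
#' Class-conditional Gaussian model with class-specific covariance matrices
#' (sample covariance, denominator n - 1) and, by default, equal priors:
#' the classifier behind the explicit polynomial score of
#' [expand_polynomial()]. Positive class is the MDD/agoraphobia group.
#'
#' @param table a `peak_table`, or a list with elements `x` (numeric matrix,
#'   subjects x features) and `group` (character vector).
#' @param features voc_ids to use as features (quantifier-ion areas). Each
#'   class must have more subjects than features.
#' @param priors named numeric vector `c(positive = , control = )`, summing
#'   to 1.
#' @param shrinkage optional ridge toward the diagonal, in `[0, 1]`:
#'   `(1 - lambda) * S + lambda * diag(diag(S))`. Default 0.
#' @return object of class `qda_model`: `features`, `mu_pos`, `mu_ctrl`,
#'   `sigma_pos`, `sigma_ctrl`, `priors`, `n_pos`, `n_ctrl`.
#' @export
fit_qda <- function(table, features, priors = c(positive = 0.5, control = 0.5),
                    shrinkage = 0) {
  if (inherits(table, "peak_table")) {
    qa <- quantifier_areas(table, features)
    wide <- tidyr::pivot_wider(qa[, c("subject_id", "group", "voc_id", "area")],
                               names_from = "voc_id", values_from = "area")
    x <- as.matrix(wide[, features, drop = FALSE])
    rownames(x) <- wide$subject_id
    grp <- wide$group
  } else {
    x <- as.matrix(table$x)
    grp <- table$group
    if (is.null(colnames(x))) colnames(x) <- features
    x <- x[, features, drop = FALSE]
  }
  stopifnot(abs(sum(priors) - 1) < 1e-12, all(priors > 0))
  p <- length(features)
  xp <- x[grp == "positive", , drop = FALSE]
  xc <- x[grp == "control", , drop = FALSE]
  if (nrow(xp) <= p || nrow(xc) <= p) {
    stop("each class needs more subjects than features ",
         sprintf("(positive %d, control %d, features %d)",
                 nrow(xp), nrow(xc), p))
  }
  shrink <- function(S) (1 - shrinkage) * S + shrinkage * diag(diag(S), p)
  sp_ <- shrink(stats::cov(xp))
  sc_ <- shrink(stats::cov(xc))
  for (nm in c("positive", "control")) {
    S <- if (nm == "positive") sp_ else sc_
    if (kappa(S, exact = FALSE) > 1e12) {
      stop("ill-conditioned ", nm, " covariance; ",
           "use fewer features or a nonzero shrinkage")
    }
  }
  structure(list(
    features = features,
    mu_pos = colMeans(xp), mu_ctrl = colMeans(xc),
    sigma_pos = sp_, sigma_ctrl = sc_,
    priors = priors, n_pos = nrow(xp), n_ctrl = nrow(xc)
  ), class = "qda_model")
}

#' Expand a QDA model into explicit polynomial coefficients
#'
#' The two-class quadratic score `score(x) = a0 + a'x + x'Cx` equals the
#' Gaussian log-density difference (positive minus control, plus the
#' log-prior ratio):
#' \deqn{a_0 = \tfrac12\ln\frac{|\Sigma_c|}{|\Sigma_p|}
#'   + \tfrac12(\mu_c'\Sigma_c^{-1}\mu_c - \mu_p'\Sigma_p^{-1}\mu_p)
#'   + \ln(\pi_p/\pi_c)}
#' \deqn{a = \Sigma_p^{-1}\mu_p - \Sigma_c^{-1}\mu_c, \qquad
#'   C = \tfrac12(\Sigma_c^{-1} - \Sigma_p^{-1})}
#' Positive scores indicate the MDD/agoraphobia class.
#'
#' @param model a [fit_qda()] model.
#' @return object of class `qda_coefficients`: `a0` (constant), `a` (linear
#'   coefficient vector) and `C` (symmetric quadratic coefficient matrix),
#'   plus the feature names.
#' @export
expand_polynomial <- function(model) {
  sp_inv <- solve(model$sigma_pos)
  sc_inv <- solve(model$sigma_ctrl)
  ld <- function(S) as.numeric(determinant(S, logarithm = TRUE)$modulus)
  a0 <- 0.5 * (ld(model$sigma_ctrl) - ld(model$sigma_pos)) +
    0.5 * (drop(model$mu_ctrl %*% sc_inv %*% model$mu_ctrl) -
           drop(model$mu_pos %*% sp_inv %*% model$mu_pos)) +
    log(model$priors[["positive"]] / model$priors[["control"]])
  a <- drop(sp_inv %*% model$mu_pos - sc_inv %*% model$mu_ctrl)
  C <- 0.5 * (sc_inv - sp_inv)
  C <- (C + t(C)) / 2
  structure(list(a0 = a0, a = stats::setNames(a, model$features), C = C,
                 features = model$features),
            class = "qda_coefficients")
}

#' Evaluate the polynomial discriminant score
#'
#' `score(x) = a0 + a'x + x'Cx`, in double precision. `x` must be complete;
#' for possibly-incomplete measurements use [qda_judge()].
#'
#' @param coeffs a [expand_polynomial()] object.
#' @param x numeric vector (one subject) or matrix (subjects x features).
#' @return numeric score(s).
#' @export
qda_score <- function(coeffs, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(coeffs$a)) {
    stop("feature dimension mismatch: expected ", length(coeffs$a),
         ", got ", ncol(x))
  }
  if (anyNA(x)) stop("qda_score requires complete feature vectors")
  drop(coeffs$a0 + x %*% coeffs$a + rowSums((x %*% coeffs$C) * x))
}

#' Judge a subject from a possibly-incomplete feature vector
#'
#' Missing-data policy of the published judgement rule: if any feature is
#' missing the verdict is `"unknown"`; otherwise `"positive"` iff the score
#' is at least zero (boundary inclusive), else `"negative"`. No imputation.
#'
#' @param coeffs a [expand_polynomial()] object.
#' @param x numeric feature vector, possibly containing `NA`.
#' @return `"positive"`, `"negative"` or `"unknown"`.
#' @export
qda_judge <- function(coeffs, x) {
  if (length(x) != length(coeffs$a) || anyNA(x)) return("unknown")
  if (qda_score(coeffs, x) >= 0) "positive" else "negative"
}

#' Training-set evaluation of the discriminant
#'
#' Scores every training subject with the expanded polynomial, judges each
#' one, and reports the per-class discriminant probability (percent
#' correctly judged) and error (its complement to 100), plus Box's M test
#' of covariance homogeneity between the two class samples.
#'
#' @param model a [fit_qda()] model.
#' @param table the `peak_table` the model was fitted on.
#' @return list: `coefficients`, `scores` (tibble `subject_id, group, score,
#'   judgement`), `discriminant_probability_percent` and `error_percent`
#'   (named by class), `box_m`.
#' @export
evaluate_training <- function(model, table) {
  coeffs <- expand_polynomial(model)
  qa <- quantifier_areas(table, model$features)
  wide <- tidyr::pivot_wider(qa[, c("subject_id", "group", "voc_id", "area")],
                             names_from = "voc_id", values_from = "area")
  x <- as.matrix(wide[, model$features, drop = FALSE])
  scores <- qda_score(coeffs, x)
  judgement <- ifelse(scores >= 0, "positive", "negative")
  tab <- tibble::tibble(
    subject_id = wide$subject_id, group = wide$group,
    score = scores, judgement = judgement
  )
  correct <- (tab$judgement == "positive") == (tab$group == "positive")
  prob <- c(
    positive = 100 * mean(correct[tab$group == "positive"]),
    control = 100 * mean(correct[tab$group == "control"])
  )
  bm <- boxs_m(list(x[wide$group == "positive", , drop = FALSE],
                    x[wide$group == "control", , drop = FALSE]))
  list(
    coefficients = coeffs, scores = tab,
    discriminant_probability_percent = prob,
    error_percent = 100 - prob,
    box_m = bm
  )
}
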