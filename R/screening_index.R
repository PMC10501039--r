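#' Combined-VOC screening index (unstandardized predicted values)
#'
#' Ordinary least squares of the binary diagnosis indicator (control = 0,
#' positive = 1) on the member VOCs' quantifier-ion areas; the per-subject
#' fitted values are the combined index (the "PRE-1" values fed to ROC
#' analysis). With a single member whose slope is positive this is a
#' monotone transform of the raw areas and yields an identical ROC.
#'
#' @param table a `peak_table`.
#' @param members voc_ids entering the index (combination-eligible
#'   biomarkers); the design matrix must be full rank.
#' @return object of class `combined_index`: `members`, `intercept`,
#'   `coefficients`, `values` (tibble `subject_id, group, index`),
#'   `higher_indicates_positive`.
#' @export
combined_index <- function(table, members) {
  qa <- quantifier_areas(table, members)
  wide <- tidyr::pivot_wider(qa[, c("subject_id", "group", "voc_id", "area")],
                             names_from = "voc_id", values_from = "area")
  x <- as.matrix(wide[, members, drop = FALSE])
  y <- as.numeric(wide$group == "positive")
  if (qr(cbind(1, x))$rank < ncol(x) + 1) {
    stop("collinear members: combined-index design matrix is rank deficient")
  }
  fit <- stats::lm(y ~ x)
  b <- coef(fit)
  vals <- unname(fitted(fit))
  structure(list(
    members = members,
    intercept = unname(b[1]),
    coefficients = stats::setNames(unname(b[-1]), members),
    values = tibble::tibble(subject_id = wide$subject_id,
                            group = wide$group, index = vals),
    higher_indicates_positive =
      mean(vals[y == 1]) >= mean(vals[y == 0])
  ), class = "combined_index")
}

#' Rank-based ROC curve, AUC and Youden cutoff
#'
#' AUC by pair counting: `(concordant + 0.5 * tied) / (n1 * n2)`, the
#' probability that a random positive outranks a random control (identical
#' to the trapezoidal area in the absence of ties). If the raw AUC is below
#' 0.5 and `auto_orient` is on, values are negated (decreasing markers such
#' as hexanoic acid are reported on the informative scale) and
#' `orientation_flipped` is set. The Youden cutoff maximizes
#' sensitivity + specificity - 1, ties broken toward higher sensitivity.
#'
#' @param values numeric marker values or index values, one per subject.
#' @param labels group labels, `"positive"` / `"control"` (both present).
#' @param auto_orient flip decreasing markers (default `TRUE`).
#' @return object of class `roc_result`: `thresholds` (value >= threshold
#'   predicts positive), `sensitivity`, `specificity`, `auc`,
#'   `youden_cutoff`, `sensitivity_at_cutoff`, `specificity_at_cutoff`,
#'   `orientation_flipped`; the curve runs from (0, 0) to (1, 1) with
#'   non-decreasing sensitivity.
#' @export
roc_curve <- function(values, labels, auto_orient = TRUE) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels),
            all(labels %in% c("positive", "control")))
  if (length(unique(labels)) < 2) {
    stop("ROC requires both a positive and a control label")
  }
  pos <- values[labels == "positive"]
  neg <- values[labels == "control"]
  auc_of <- function(p, n) {
    conc <- sum(outer(p, n, ">"))
    tied <- sum(outer(p, n, "=="))
    (conc + 0.5 * tied) / (length(p) * length(n))
  }
  flipped <- FALSE
  auc <- auc_of(pos, neg)
  if (auto_orient && auc < 0.5) {
    values <- -values
    pos <- -pos; neg <- -neg
    auc <- auc_of(pos, neg)
    flipped <- TRUE
  }
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(pos >= t), 0)
  spec <- vapply(thr, function(t) mean(neg < t), 0)
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[which.max(sens[best])]
  structure(list(
    thresholds = thr, sensitivity = sens, specificity = spec,
    auc = auc,
    youden_cutoff = thr[best],
    sensitivity_at_cutoff = sens[best],
    specificity_at_cutoff = spec[best],
    orientation_flipped = flipped,
    n_positive = length(pos), n_control = length(neg)
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positive vs %d control)%s\n",
              x$auc, x$n_positive, x$n_control,
              if (x$orientation_flipped) ", orientation flipped" else ""))
  invisible(x)
}

#' Correlate a combined index with a cohort score
#'
#' Pearson (and Spearman) correlation of the per-subject index against a
#' clinical score over subjects with a non-missing score (GRID-HAMD, not
#' determined for controls, restricts to the positive group), plus
#' quadratic and cubic polynomial curve fits with overall F tests.
#'
#' @param index a [combined_index()] (or any tibble with `subject_id` and
#'   `index` columns).
#' @param cohort a cohort tibble (see [read_cohort_table()]).
#' @param score_name cohort column to correlate against.
#' @param exclude_agoraphobia_only drop the subject diagnosed with
#'   agoraphobia but no depressive symptoms (used for GRID-HAMD, whose
#'   severity scale targets depression). Default `FALSE`.
#' @return list: `score_name`, `n`, `pearson`, `spearman` (both
#'   [correlate()] results), `fit_quadratic`, `fit_cubic` (both
#'   [polyfit_f()] results).
#' @export
correlate_index <- function(index, cohort, score_name,
                            exclude_agoraphobia_only = FALSE) {
  vals <- if (inherits(index, "combined_index")) index$values else index
  df <- dplyr::inner_join(vals, cohort, by = "subject_id")
  if (exclude_agoraphobia_only && "agoraphobia_only" %in% names(df)) {
    df <- df[!isTRUE_vec(df$agoraphobia_only), ]
  }
  y <- df[[score_name]]
  ok <- !is.na(y) & !is.na(df$index)
  if (sum(ok) < 4) {
    stop("insufficient data: fewer than 4 non-missing (index, ",
         score_name, ") pairs")
  }
  x <- df$index[ok]; y <- y[ok]
  list(
    score_name = score_name, n = length(x),
    pearson = correlate(x, y, "pearson"),
    spearman = correlate(x, y, "spearman"),
    fit_quadratic = polyfit_f(x, y, 2),
    fit_cubic = polyfit_f(x, y, 3)
  )
}
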