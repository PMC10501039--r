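#' Screening filter criteria for differential-VOC nomination
#'
#' The three published TIC-level rules plus the significance level used on
#' quantifier areas: (1) the raw TIC area exceeds `min_tic_area` (10,000
#' area units) in at least one diagnostic group; (2) the TIC is detected
#' (nonzero) in at least `min_detected_subjects` (3) subjects of at least
#' one group; (3) the positive/control mean TIC fold is above `up_fold`
#' (1.5) or below `down_fold` (0.7).
#'
#' @param min_tic_area minimum TIC area (rule 1).
#' @param min_detected_subjects minimum detections (rule 2).
#' @param up_fold,down_fold fold thresholds (rule 3).
#' @param significance_alpha one-tailed alpha for calling a tested candidate
#'   significant.
#' @param area_mode rule 1 applied to the `"group_mean"` TIC (default) or to
#'   `"any_sample"`.
#' @param detect_scope rule 2 counted within `"either_group"` (default) or
#'   `"pooled"` across all subjects.
#' @return list of criteria.
#' @export
filter_criteria <- function(min_tic_area = 10000, min_detected_subjects = 3,
                            up_fold = 1.5, down_fold = 0.7,
                            significance_alpha = 0.05,
                            area_mode = c("group_mean", "any_sample"),
                            detect_scope = c("either_group", "pooled")) {
  stopifnot(min_tic_area > 0, up_fold > 1, down_fold < 1, down_fold > 0,
            significance_alpha > 0, significance_alpha < 1)
  list(
    min_tic_area = min_tic_area,
    min_detected_subjects = min_detected_subjects,
    up_fold = up_fold, down_fold = down_fold,
    significance_alpha = significance_alpha,
    area_mode = match.arg(area_mode),
    detect_scope = match.arg(detect_scope)
  )
}

#' Apply the TIC-level screening filters
#'
#' Evaluates the three rules of [filter_criteria()] for every species of a
#' peak table and flags candidates passing all three. Fold is the positive
#' over control mean TIC (subjects with no detection contribute zero to the
#' mean); a zero control mean with positive signal counts as an increase.
#'
#' @param table a `peak_table`.
#' @param criteria a [filter_criteria()] list.
#' @return tibble, one row per species: group mean TICs, detection counts,
#'   `fold_tic`, per-rule flags `pass_area`, `pass_detection`, `pass_fold`,
#'   and `candidate` (all three).
#' @export
apply_tic_filters <- function(table, criteria = filter_criteria()) {
  df <- dplyr::left_join(table$tic, table$subjects, by = "subject_id")
  by_voc <- df |>
    dplyr::group_by(.data$voc_id) |>
    dplyr::summarise(
      mean_tic_control = mean(.data$tic_area[.data$group == "control"]),
      mean_tic_positive = mean(.data$tic_area[.data$group == "positive"]),
      max_tic = max(.data$tic_area),
      n_detected_control = sum(.data$tic_area[.data$group == "control"] > 0),
      n_detected_positive = sum(.data$tic_area[.data$group == "positive"] > 0),
      .groups = "drop"
    )
  by_voc <- by_voc[match(table$species$voc_id, by_voc$voc_id), ]
  pass_area <- if (criteria$area_mode == "group_mean") {
    pmax(by_voc$mean_tic_control, by_voc$mean_tic_positive) >
      criteria$min_tic_area
  } else {
    by_voc$max_tic > criteria$min_tic_area
  }
  pass_detection <- if (criteria$detect_scope == "either_group") {
    pmax(by_voc$n_detected_control, by_voc$n_detected_positive) >=
      criteria$min_detected_subjects
  } else {
    (by_voc$n_detected_control + by_voc$n_detected_positive) >=
      criteria$min_detected_subjects
  }
  fold <- ifelse(by_voc$mean_tic_control > 0,
                 by_voc$mean_tic_positive / by_voc$mean_tic_control,
                 ifelse(by_voc$mean_tic_positive > 0, Inf, NA_real_))
  pass_fold <- !is.na(fold) &
    (fold > criteria$up_fold | fold < criteria$down_fold)
  dplyr::mutate(by_voc,
    fold_tic = fold,
    pass_area = pass_area,
    pass_detection = pass_detection,
    pass_fold = pass_fold,
    candidate = pass_area & pass_detection & pass_fold
  )
}

#' Test candidate species on quantifier-ion areas
#'
#' For each candidate: selects the quantifier ion, summarises the per-group
#' quantifier areas (mean, SEM, fold) and runs the Mann-Whitney test,
#' reporting both the two- and one-tailed p-values. A candidate is called
#' significant when its one-tailed p is at or below the criteria's alpha
#' (the nomination convention; both p-values are always reported).
#'
#' @param table a `peak_table`.
#' @param candidates character vector of voc_ids (subset of the table's
#'   species).
#' @param criteria a [filter_criteria()] list.
#' @return tibble, one row per candidate: species metadata, quantifier m/z,
#'   group summary, `p_two_tailed`, `p_one_tailed`, `significant`.
#' @export
test_candidates <- function(table, candidates, criteria = filter_criteria()) {
  stopifnot(all(candidates %in% table$species$voc_id))
  if (length(candidates) == 0) {
    return(tibble::tibble(
      voc_id = character(), name = character(),
      retention_time_min = double(), quantifier_mz = integer(),
      confirmed_standard = logical(),
      mean_control = double(), sem_control = double(),
      mean_positive = double(), sem_positive = double(), fold = double(),
      p_two_tailed = double(), p_one_tailed = double(),
      significant = logical()
    ))
  }
  qa <- quantifier_areas(table, candidates)
  sp <- table$species
  rows <- lapply(candidates, function(v) {
    sub <- qa[qa$voc_id == v, ]
    gs <- group_summary(sub$area[sub$group == "control"],
                        sub$area[sub$group == "positive"],
                        variable = v)
    i <- match(v, sp$voc_id)
    tibble::tibble(
      voc_id = v, name = sp$name[i],
      retention_time_min = sp$retention_time_min[i],
      quantifier_mz = sub$quantifier_mz[1],
      confirmed_standard = sp$confirmed_standard[i],
      mean_control = gs$mean_control, sem_control = gs$sem_control,
      mean_positive = gs$mean_positive, sem_positive = gs$sem_positive,
      fold = gs$fold,
      p_two_tailed = gs$p_two_tailed, p_one_tailed = gs$p_one_tailed,
      significant = gs$p_one_tailed <= criteria$significance_alpha
    )
  })
  dplyr::bind_rows(rows)
}

#' Nominate biomarkers from tested differential VOCs
#'
#' @param diffs output of [test_candidates()].
#' @return list (`biomarker_set`): `nominated` (all tested candidates),
#'   `significant` (one-tailed p at or below alpha) and
#'   `combination_eligible` (significant AND identification confirmed with a
#'   commercial standard — only these may enter combined indices).
#' @export
nominate_biomarkers <- function(diffs) {
  if (is.null(diffs) || nrow(diffs) == 0) {
    return(structure(list(nominated = diffs,
                          significant = diffs,
                          combination_eligible = diffs),
                     class = "biomarker_set"))
  }
  sig <- diffs[diffs$significant, ]
  structure(list(
    nominated = diffs,
    significant = sig,
    combination_eligible = sig[isTRUE_vec(sig$confirmed_standard), ]
  ), class = "biomarker_set")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Run the full differential-VOC extraction cascade
#'
#' Convenience wrapper: [apply_tic_filters()], then [test_candidates()] on
#' the passing species, then [nominate_biomarkers()].
#'
#' @inheritParams apply_tic_filters
#' @return list with `filters` (per-species filter table), `diffs` (tested
#'   candidates) and `biomarkers` (the biomarker set).
#' @export
extract_differential_vocs <- function(table, criteria = filter_criteria()) {
  filters <- apply_tic_filters(table, criteria)
  cand <- filters$voc_id[filters$candidate]
  diffs <- test_candidates(table, cand, criteria)
  list(filters = filters, diffs = diffs,
       biomarkers = nominate_biomarkers(diffs))
}
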