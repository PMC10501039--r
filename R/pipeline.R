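#' @importFrom utils packageVersion
NULL

# report-style number formatting: areas as thousands-separated integers,
# p-values to 4 decimals with a floor
fmt_area <- function(x) formatC(round(x), format = "d", big.mark = ",")
fmt_p <- function(p) ifelse(is.na(p), "n.d.",
                     ifelse(p < 1e-4, "< 0.0001", sprintf("%.4f", p)))
fmt_fold <- function(f) ifelse(is.na(f), "n.d.", sprintf("%.2f", f))

config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x",
          sum(as.numeric(raw) * (seq_along(raw) %% 251 + 1)) %% 4294967291)
}

#' Cohort summary table
#'
#' Group means, SEMs, folds and Mann-Whitney p-values for every numeric
#' cohort variable, in the layout of the study's cohort-comparison table.
#' GRID-HAMD, not determined for controls, is summarised for positives only
#' (no fold or test).
#'
#' @param cohort a cohort tibble.
#' @return tibble, one row per variable.
#' @export
summarise_cohort <- function(cohort) {
  vars <- setdiff(cohort_cols, c("subject_id", "group", "sex", "age"))
  rows <- lapply(vars, function(v) {
    ctl <- cohort[[v]][cohort$group == "control"]
    pos <- cohort[[v]][cohort$group == "positive"]
    if (all(is.na(ctl))) {
      tibble::tibble(
        variable = v, mean_control = NA_real_, sem_control = NA_real_,
        mean_positive = mean(pos, na.rm = TRUE),
        sem_positive = sd(pos, na.rm = TRUE) / sqrt(sum(!is.na(pos))),
        fold = NA_real_, p_two_tailed = NA_real_, p_one_tailed = NA_real_
      )
    } else {
      group_summary(ctl, pos, variable = v)
    }
  })
  dplyr::bind_rows(rows)
}

default_index_members <- function() {
  list(
    two_voc = c("texanol", "texanol_isomer"),
    three_voc = c("dms", "phenethyl_itc", "hexanoic_acid")
  )
}

# the discriminant panel: all significant VOCs, capped at the six smallest
# one-tailed p-values (the study's panel size) so each 9-subject class keeps
# more observations than features
discriminant_panel <- function(biomarkers, max_features = 6) {
  sig <- biomarkers$significant
  if (is.null(sig) || nrow(sig) == 0) return(character(0))
  sig <- sig[order(sig$p_one_tailed, sig$voc_id), ]
  utils::head(sig$voc_id, max_features)
}

#' Run the full screening pipeline
#'
#' Orchestrates simulate -> extract -> discriminate -> ROC -> correlate:
#' generates (or accepts) a peak table plus cohort table, summarises the
#' cohort, runs the differential-VOC extraction cascade, fits the quadratic
#' discriminant on the significant panel, computes single-marker and
#' combined-index ROC curves, and correlates the combined indices with the
#' clinical scores. All randomness flows from `config$seed` through named
#' substreams, so a rerun with the same config is byte-identical.
#'
#' @param config generator configuration ([default_calibration()]); ignored
#'   when `data` is supplied.
#' @param data optional list `(peaks, cohort)` to analyse instead of
#'   simulating.
#' @param criteria [filter_criteria()] overrides.
#' @param index_members named list of voc_id vectors for the combined
#'   indices (default: the two-VOC texanol pair and the three-VOC panel).
#'   An empty list skips the index/correlation stages with a warning.
#' @param correlate_scores cohort variables to correlate each index with.
#' @param out_dir optional directory; when given, all stage artifacts are
#'   written there (TSV/CSV/JSON plus a human-readable `run_report.txt`).
#' @return A `run_report` list with elements `config_hash`, `seed`,
#'   `versions`, `data`, `cohort_summary`, `extraction`, `discriminant`,
#'   `roc`, `correlations`, `log`.
#' @export
run_pipeline <- function(config = default_calibration(), data = NULL,
                         criteria = filter_criteria(),
                         index_members = default_index_members(),
                         correlate_scores = c("kihon_cl", "dskc_self", "sds",
                                              "grid_hamd"),
                         out_dir = NULL) {
  log <- list()
  note <- function(stage, ...) {
    entry <- list(stage = stage, detail = sprintf(...))
    log[[length(log) + 1]] <<- entry
    message("[", stage, "] ", entry$detail)
  }

  if (is.null(data)) {
    data <- generate_dataset(config)
    note("simulate", "generated %d species x %d subjects (seed %s)",
         nrow(data$peaks$species), nrow(data$peaks$subjects),
         format(config$seed))
  } else {
    note("input", "analysing supplied tables: %d species x %d subjects",
         nrow(data$peaks$species), nrow(data$peaks$subjects))
  }
  peaks <- data$peaks; cohort <- data$cohort

  cohort_summary <- summarise_cohort(cohort)
  note("cohort", "summarised %d cohort variables", nrow(cohort_summary))

  extraction <- extract_differential_vocs(peaks, criteria)
  note("extract", "cascade passed %d of %d species; %d significant",
       nrow(extraction$diffs), nrow(extraction$filters),
       nrow(extraction$biomarkers$significant))

  panel <- discriminant_panel(extraction$biomarkers)
  discr <- NULL
  if (length(panel) >= 1) {
    model <- fit_qda(peaks, panel)
    discr <- evaluate_training(model, peaks)
    discr$features <- panel
    note("discriminate",
         "panel {%s}: discriminant probability %.3f%% / %.3f%% (pos/ctrl), Box's M p = %.3g",
         paste(panel, collapse = ", "),
         discr$discriminant_probability_percent[["positive"]],
         discr$discriminant_probability_percent[["control"]],
         discr$box_m$p_value)
  } else {
    note("discriminate", "no significant biomarkers; stage skipped")
  }

  qa <- quantifier_areas(peaks, panel)
  roc_single <- lapply(stats::setNames(panel, panel), function(v) {
    sub <- qa[qa$voc_id == v, ]
    roc_curve(sub$area, sub$group)
  })
  indices <- list()
  roc_combined <- list()
  if (length(index_members) == 0) {
    warning("empty combined-index member list; index stages skipped")
    note("roc", "single-marker ROC only (no combined indices requested)")
  } else {
    eligible <- extraction$biomarkers$combination_eligible$voc_id
    for (nm in names(index_members)) {
      mem <- index_members[[nm]]
      if (!all(mem %in% peaks$species$voc_id)) {
        stop("roc stage: unknown voc_id in index '", nm, "'")
      }
      if (length(eligible) > 0 && !all(mem %in% eligible)) {
        note("roc", "index '%s' uses members outside the combination-eligible set (%s)",
             nm, paste(setdiff(mem, eligible), collapse = ", "))
      }
      idx <- combined_index(peaks, mem)
      indices[[nm]] <- idx
      roc_combined[[nm]] <- roc_curve(idx$values$index, idx$values$group)
    }
    note("roc", "AUCs: %s",
         paste(c(
           sprintf("%s %.4f", panel, vapply(roc_single, `[[`, 0, "auc")),
           sprintf("%s %.4f", names(roc_combined),
                   vapply(roc_combined, `[[`, 0, "auc"))
         ), collapse = "; "))
  }

  correlations <- list()
  for (nm in names(indices)) {
    for (sc in correlate_scores) {
      key <- paste(nm, sc, sep = ".")
      res <- try(correlate_index(indices[[nm]], cohort, sc), silent = TRUE)
      if (!inherits(res, "try-error")) correlations[[key]] <- res
    }
  }
  if (length(correlations) > 0) {
    note("correlate", "%d index-score correlations computed",
         length(correlations))
  }

  report <- list(
    package_version = as.character(packageVersion("vocscreen")),
    seed = config$seed,
    config_hash = config_hash(list(config, criteria, index_members)),
    data = data,
    cohort_summary = cohort_summary,
    extraction = extraction,
    discriminant = discr,
    indices = indices,
    roc = list(single = roc_single, combined = roc_combined),
    correlations = correlations,
    log = log
  )
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Write all pipeline artifacts to a directory
#'
#' @param report a [run_pipeline()] report.
#' @param out_dir target directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_peak_table(report$data$peaks, fp("peak_table.tsv"))
  write_cohort_table(report$data$cohort, fp("cohort_table.csv"))
  readr::write_tsv(report$cohort_summary, fp("cohort_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$extraction$filters, fp("tic_filters.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$extraction$diffs, fp("differential_vocs.tsv"),
                   progress = FALSE)
  if (!is.null(report$discriminant)) {
    co <- report$discriminant$coefficients
    jsonlite::write_json(
      list(features = co$features, a0 = co$a0, a = as.list(co$a),
           C = unname(apply(co$C, 1, as.list))),
      fp("discriminant_coefficients.json"),
      auto_unbox = TRUE, digits = NA
    )
    readr::write_tsv(report$discriminant$scores, fp("discriminant_scores.tsv"),
                     progress = FALSE)
  }
  aucs <- c(
    lapply(report$roc$single, function(r) r$auc),
    lapply(report$roc$combined, function(r) r$auc)
  )
  jsonlite::write_json(aucs, fp("auc.json"), auto_unbox = TRUE, digits = NA)
  roc_points <- dplyr::bind_rows(lapply(
    c(report$roc$single, report$roc$combined), function(r) {
      tibble::tibble(threshold = r$thresholds, sensitivity = r$sensitivity,
                     specificity = r$specificity)
    }), .id = "marker")
  readr::write_tsv(roc_points, fp("roc_points.tsv"), progress = FALSE)
  if (length(report$correlations) > 0) {
    jsonlite::write_json(
      lapply(report$correlations, function(cr) list(
        score = cr$score_name, n = cr$n,
        pearson_r = cr$pearson$r, pearson_p = cr$pearson$p_value,
        strength = cr$pearson$strength,
        spearman_r = cr$spearman$r, spearman_p = cr$spearman$p_value,
        quadratic = list(formula = cr$fit_quadratic$formula,
                         r = cr$fit_quadratic$r,
                         f = cr$fit_quadratic$f_statistic,
                         df = cr$fit_quadratic$df,
                         p = cr$fit_quadratic$p_value),
        cubic = list(formula = cr$fit_cubic$formula,
                     r = cr$fit_cubic$r,
                     f = cr$fit_cubic$f_statistic,
                     df = cr$fit_cubic$df,
                     p = cr$fit_cubic$p_value)
      )),
      fp("correlations.json"), auto_unbox = TRUE, digits = NA
    )
  }
  writeLines(render_text_report(report), fp("run_report.txt"))
  invisible(out_dir)
}

render_text_report <- function(report) {
  out <- c(
    sprintf("vocscreen %s run report (seed %s, config %s)",
            report$package_version, format(report$seed), report$config_hash),
    "",
    "== Cohort summary (control vs positive) =="
  )
  cs <- report$cohort_summary
  out <- c(out, sprintf(
    " %-20s %8.3f (%.3f)  %8.3f (%.3f)  fold %s  p %s / %s",
    cs$variable,
    ifelse(is.na(cs$mean_control), NaN, cs$mean_control),
    ifelse(is.na(cs$sem_control), NaN, cs$sem_control),
    cs$mean_positive, cs$sem_positive,
    fmt_fold(cs$fold), fmt_p(cs$p_two_tailed), fmt_p(cs$p_one_tailed)
  ))
  d <- report$extraction$diffs
  out <- c(out, "", "== Differential VOCs (quantifier-ion areas) ==")
  if (nrow(d) > 0) {
    out <- c(out, sprintf(
      " %-20s m/z %-3d  %12s (%s)  %12s (%s)  fold %s  p %s / %s%s",
      d$voc_id, d$quantifier_mz,
      fmt_area(d$mean_control), fmt_area(d$sem_control),
      fmt_area(d$mean_positive), fmt_area(d$sem_positive),
      fmt_fold(d$fold), fmt_p(d$p_two_tailed), fmt_p(d$p_one_tailed),
      ifelse(d$significant, "  *", "")
    ))
  }
  if (!is.null(report$discriminant)) {
    dp <- report$discriminant$discriminant_probability_percent
    out <- c(out, "", "== Quadratic discriminant (training set) ==",
      sprintf(" features: %s",
              paste(report$discriminant$features, collapse = ", ")),
      sprintf(" discriminant probability: positive %.3f%%, control %.3f%%",
              dp[["positive"]], dp[["control"]]),
      sprintf(" error: positive %.3f%%, control %.3f%%",
              100 - dp[["positive"]], 100 - dp[["control"]]),
      sprintf(" Box's M = %.3f, chi2(%d) = %.3f, p = %s",
              report$discriminant$box_m$m_statistic,
              report$discriminant$box_m$df,
              report$discriminant$box_m$chi2_approx,
              fmt_p(report$discriminant$box_m$p_value)))
  }
  aucs <- c(
    vapply(report$roc$single, `[[`, 0, "auc"),
    vapply(report$roc$combined, `[[`, 0, "auc")
  )
  if (length(aucs) > 0) {
    out <- c(out, "", "== ROC / AUC ==",
             sprintf(" %-24s AUC %.4f", names(aucs), aucs))
  }
  if (length(report$correlations) > 0) {
    out <- c(out, "", "== Index-score correlations ==")
    for (nm in names(report$correlations)) {
      cr <- report$correlations[[nm]]
      out <- c(out, sprintf(
        " %-28s n=%2d  Pearson r = %.3f (%s, p %s); quadratic %s; cubic %s",
        nm, cr$n, cr$pearson$r, cr$pearson$strength,
        fmt_p(cr$pearson$p_value),
        cr$fit_quadratic$formula, cr$fit_cubic$formula
      ))
    }
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_text_report(x), sep = "\n")
  invisible(x)
}
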