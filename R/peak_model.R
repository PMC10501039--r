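#' @importFrom rlang .data
#' @importFrom stats sd
NULL

# ---- peak_table class -------------------------------------------------------

#' Construct a peak table
#'
#' A `peak_table` is the central container of the pipeline: a dense grid of
#' GC-MS peak measurements (per-fragment m/z areas plus an independently
#' integrated total-ion-current area) for every subject x VOC pair, together
#' with species metadata and subject group labels.
#'
#' @param species tibble with columns `voc_id`, `name`, `cas`,
#'   `chemical_class`, `retention_time_min`, `fragment_mzs` (list column of
#'   integer vectors), `quantifier_mz` (integer or `NA`), and
#'   `confirmed_standard` (logical).
#' @param subjects tibble with columns `subject_id` and `group`
#'   (`"positive"` or `"control"`).
#' @param fragments long tibble `subject_id, voc_id, mz, area` covering every
#'   declared fragment of every (subject, voc) pair; missing cells are
#'   zero-filled by [as_peak_table()].
#' @param tic tibble `subject_id, voc_id, tic_area` covering every
#'   (subject, voc) pair.
#'
#' @details "Not detected" is encoded as all-zero areas (fragments and TIC),
#'   never as `NA`; the detection filter of the extraction cascade relies on
#'   this crisp zero/nonzero predicate. Fragment m/z values must lie in the
#'   instrument scan range 35--300.
#'
#' @return An object of class `peak_table`.
#' @export
as_peak_table <- function(species, subjects, fragments, tic) {
  species <- tibble::as_tibble(species)
  subjects <- tibble::as_tibble(subjects)
  fragments <- tibble::as_tibble(fragments)
  tic <- tibble::as_tibble(tic)

  grid <- tidyr::expand_grid(
    subject_id = subjects$subject_id,
    voc_id = species$voc_id
  )
  frag_grid <- dplyr::inner_join(
    grid,
    tidyr::unnest(
      dplyr::transmute(species, voc_id = .data$voc_id, mz = .data$fragment_mzs),
      "mz"
    ),
    by = "voc_id",
    relationship = "many-to-many"   # subjects x fragments, intended
  )
  fragments <- dplyr::left_join(frag_grid, fragments,
    by = c("subject_id", "voc_id", "mz")
  )
  fragments$area[is.na(fragments$area)] <- 0
  tic <- dplyr::left_join(grid, tic, by = c("subject_id", "voc_id"))
  tic$tic_area[is.na(tic$tic_area)] <- 0

  out <- structure(
    list(species = species, subjects = subjects,
         fragments = fragments, tic = tic),
    class = "peak_table"
  )
  validate_peak_table(out)
  out
}

validate_peak_table <- function(x) {
  sp <- x$species
  stopifnot(is.list(sp$fragment_mzs))
  if (anyDuplicated(sp$voc_id) > 0) stop("duplicate voc_id in species table")
  if (anyDuplicated(x$subjects$subject_id) > 0) {
    stop("duplicate subject_id in subject table")
  }
  bad_rt <- !is.na(sp$retention_time_min) & sp$retention_time_min <= 0
  if (any(bad_rt)) stop("retention_time_min must be positive")
  mzs <- unlist(sp$fragment_mzs)
  if (length(mzs) == 0 || any(lengths(sp$fragment_mzs) == 0)) {
    stop("every species needs at least one fragment m/z")
  }
  if (any(mzs < 35 | mzs > 300)) {
    stop("fragment m/z outside the 35-300 scan range")
  }
  qmz <- sp$quantifier_mz
  has_q <- !is.na(qmz)
  if (any(has_q & !mapply(function(q, f) q %in% f, qmz, sp$fragment_mzs))) {
    stop("quantifier_mz must be one of the species' fragment m/z values")
  }
  grp <- unique(as.character(x$subjects$group))
  if (!setequal(grp, c("positive", "control"))) {
    stop("subjects must form exactly two non-empty groups: positive, control")
  }
  if (any(x$fragments$area < 0) || any(x$tic$tic_area < 0)) {
    stop("areas must be non-negative")
  }
  if (nrow(x$tic) != nrow(x$subjects) * nrow(sp)) {
    stop("TIC grid is not dense")
  }
  invisible(x)
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf(
    "<peak_table> %d species x %d subjects (%d positive, %d control)\n",
    nrow(x$species), nrow(x$subjects),
    sum(x$subjects$group == "positive"), sum(x$subjects$group == "control")
  ))
  invisible(x)
}

# ---- readers / writers ------------------------------------------------------

long_peak_cols <- c("subject_id", "group", "voc_id", "name", "cas",
                    "retention_time_min", "mz", "fragment_area", "tic_area")

#' Read a peak table from disk
#'
#' The canonical interchange format is long TSV, one row per
#' subject x VOC x fragment with columns
#' `subject_id, group, voc_id, name, cas, retention_time_min, mz,
#' fragment_area, tic_area` (the TIC area is repeated on each fragment row of
#' a pair). A lossy wide view (one `voc|mz` column per fragment plus a
#' `voc|tic` column, written by [write_peak_table()]) can be read back, but
#' species metadata other than fragment m/z values is not recoverable from it.
#'
#' @param path file to read.
#' @param format `"long"` (canonical) or `"wide"`.
#' @return A [as_peak_table()] object. Missing (subject, voc) cells become
#'   all-zero (not-detected) measurements; subject order follows first
#'   appearance in the file.
#' @export
read_peak_table <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "long") read_peak_table_long(path) else read_peak_table_wide(path)
}

read_peak_table_long <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(long_peak_cols, header)
  if (length(missing_cols) > 0) {
    stop("malformed peak table header; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), group = readr::col_character(),
    voc_id = readr::col_character(), name = readr::col_character(),
    cas = readr::col_character(), retention_time_min = readr::col_double(),
    mz = readr::col_integer(), fragment_area = readr::col_double(),
    tic_area = readr::col_double()
  ), progress = FALSE, lazy = FALSE)
  missing_cols <- setdiff(long_peak_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed peak table header; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("peak table has a header but no data rows")
  dup <- duplicated(df[, c("subject_id", "voc_id", "mz")])
  if (any(dup)) {
    stop("duplicate (subject_id, voc_id, mz) record(s), first at data row ",
         which(dup)[1])
  }
  df$cas[is.na(df$cas)] <- ""

  species <- df |>
    dplyr::group_by(.data$voc_id) |>
    dplyr::summarise(
      name = .data$name[1], cas = .data$cas[1],
      retention_time_min = .data$retention_time_min[1],
      fragment_mzs = list(sort(unique(.data$mz))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      chemical_class = NA_character_,
      quantifier_mz = NA_integer_,
      confirmed_standard = NA
    )
  # preserve first-appearance order of species and subjects
  species <- species[match(unique(df$voc_id), species$voc_id), ]
  subjects <- df |>
    dplyr::distinct(.data$subject_id, .data$group)
  if (anyDuplicated(subjects$subject_id) > 0) {
    stop("subject assigned to more than one group")
  }
  fragments <- df[, c("subject_id", "voc_id", "mz", "fragment_area")]
  names(fragments)[4] <- "area"
  tic <- df |>
    dplyr::distinct(.data$subject_id, .data$voc_id, .data$tic_area)
  as_peak_table(species, subjects, fragments, tic)
}

read_peak_table_wide <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), group = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, lazy = FALSE)
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop("malformed peak table header; missing column(s): subject_id/group")
  }
  if (nrow(df) == 0) stop("peak table has a header but no data rows")
  val_cols <- setdiff(names(df), c("subject_id", "group"))
  parts <- strsplit(val_cols, "|", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("wide columns must be named '<voc_id>|mz<int>' or '<voc_id>|tic'")
  }
  voc <- vapply(parts, `[`, "", 1)
  kind <- vapply(parts, `[`, "", 2)
  long <- tidyr::pivot_longer(df, dplyr::all_of(val_cols),
                              names_to = "key", values_to = "value")
  long$voc_id <- voc[match(long$key, val_cols)]
  long$kind <- kind[match(long$key, val_cols)]
  frag <- long[grepl("^mz", long$kind), ]
  frag$mz <- as.integer(sub("^mz", "", frag$kind))
  tic <- long[long$kind == "tic", ]
  species <- tibble::tibble(
    voc_id = unique(voc),
    name = unique(voc), cas = "", chemical_class = NA_character_,
    retention_time_min = NA_real_,
    fragment_mzs = lapply(unique(voc), function(v) {
      sort(unique(frag$mz[frag$voc_id == v]))
    }),
    quantifier_mz = NA_integer_, confirmed_standard = NA
  )
  as_peak_table(
    species,
    df[, c("subject_id", "group")],
    tibble::tibble(subject_id = frag$subject_id, voc_id = frag$voc_id,
                   mz = frag$mz, area = frag$value),
    tibble::tibble(subject_id = tic$subject_id, voc_id = tic$voc_id,
                   tic_area = tic$value)
  )
}

#' Write a peak table to disk
#'
#' @param table a `peak_table`.
#' @param path output file.
#' @param format `"long"` (canonical, round-trips through
#'   [read_peak_table()]) or `"wide"` (convenience view; species metadata is
#'   dropped).
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    df <- table$fragments |>
      dplyr::left_join(table$subjects, by = "subject_id") |>
      dplyr::left_join(
        dplyr::select(table$species, "voc_id", "name", "cas",
                      "retention_time_min"),
        by = "voc_id"
      ) |>
      dplyr::left_join(table$tic, by = c("subject_id", "voc_id")) |>
      dplyr::transmute(
        subject_id = .data$subject_id, group = as.character(.data$group),
        voc_id = .data$voc_id, name = .data$name, cas = .data$cas,
        retention_time_min = .data$retention_time_min, mz = .data$mz,
        fragment_area = .data$area, tic_area = .data$tic_area
      )
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    frag <- table$fragments |>
      dplyr::mutate(key = paste0(.data$voc_id, "|mz", .data$mz)) |>
      dplyr::select("subject_id", "key", "area") |>
      tidyr::pivot_wider(names_from = "key", values_from = "area")
    ticw <- table$tic |>
      dplyr::mutate(key = paste0(.data$voc_id, "|tic")) |>
      dplyr::select("subject_id", "key", "tic_area") |>
      tidyr::pivot_wider(names_from = "key", values_from = "tic_area")
    df <- table$subjects |>
      dplyr::mutate(group = as.character(.data$group)) |>
      dplyr::left_join(frag, by = "subject_id") |>
      dplyr::left_join(ticw, by = "subject_id")
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

# ---- cohort table -----------------------------------------------------------

cohort_cols <- c("subject_id", "group", "sex", "age", "kihon_cl", "tmig_ic",
                 "jst_ic", "dskc", "dskc_self", "sds", "grid_hamd",
                 "serum_creatinine", "urinary_creatinine", "ucreat_per_weight",
                 "specific_gravity")

#' Read / write a cohort score table (CSV)
#'
#' Per-subject clinical and frailty variables: group label, sex, age, Kihon
#' checklist (kihon_cl, 0--20), TMIG index of competence (0--13), JST index
#' of competence (0--16), the depression section of the Kihon checklist
#' scored by others (dskc) and by self report (dskc_self, both 0--5), Zung
#' SDS (20--80), GRID-HAMD (missing for controls, for whom it is not
#' determined), serum and urinary creatinine (mg/dL), urinary creatinine per
#' body weight (mg/kg) and urinary specific gravity. Empty cells are missing.
#'
#' @param path CSV file.
#' @return A tibble with the columns above.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), group = readr::col_character(),
    sex = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, lazy = FALSE)
  missing_cols <- setdiff(cohort_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed cohort table header; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_cohort_table(df)
  df
}

validate_cohort_table <- function(df) {
  chk <- function(v, lo, hi) {
    x <- df[[v]]
    if (any(!is.na(x) & (x < lo | x > hi))) {
      stop(sprintf("%s outside its documented range [%g, %g]", v, lo, hi))
    }
  }
  chk("kihon_cl", 0, 20); chk("tmig_ic", 0, 13); chk("jst_ic", 0, 16)
  chk("dskc", 0, 5); chk("dskc_self", 0, 5); chk("sds", 20, 80)
  if (any(!is.na(df$grid_hamd) & df$group == "control")) {
    stop("grid_hamd must be missing (not determined) for controls")
  }
  invisible(df)
}

#' @rdname read_cohort_table
#' @param cohort a cohort tibble.
#' @export
write_cohort_table <- function(cohort, path) {
  readr::write_csv(cohort[, cohort_cols], path, progress = FALSE, na = "")
  invisible(path)
}

# ---- quantifier ion ---------------------------------------------------------

#' Select the quantifier ion of a VOC species
#'
#' Among a species' fragment m/z values, the quantifier ion is the fragment
#' whose area summed over all subjects is largest; its per-subject area is
#' the quantity used for between-group testing. Ties break deterministically
#' toward the smallest m/z.
#'
#' @param table a `peak_table`.
#' @param voc_id species identifier.
#' @return The quantifier m/z (integer).
#' @export
select_quantifier_ion <- function(table, voc_id) {
  fr <- table$fragments[table$fragments$voc_id == voc_id, ]
  if (nrow(fr) == 0) stop("unknown voc_id: ", voc_id)
  tot <- tapply(fr$area, fr$mz, sum)
  if (all(tot == 0)) {
    stop("no signal: all fragment areas of ", voc_id, " are zero")
  }
  mzs <- as.integer(names(tot))
  best <- mzs[tot == max(tot)]
  min(best)
}

#' Per-subject quantifier-ion areas
#'
#' Returns the matrix-ready long table of quantifier areas used by the
#' statistical stages. Species without a preset `quantifier_mz` get one via
#' [select_quantifier_ion()].
#'
#' @param table a `peak_table`.
#' @param voc_ids species to extract (default: all).
#' @return tibble `subject_id, group, voc_id, quantifier_mz, area`.
#' @export
quantifier_areas <- function(table, voc_ids = table$species$voc_id) {
  sp <- table$species[match(voc_ids, table$species$voc_id), ]
  if (anyNA(sp$voc_id)) stop("unknown voc_id requested")
  qmz <- sp$quantifier_mz
  for (i in seq_along(voc_ids)) {
    if (is.na(qmz[i])) qmz[i] <- select_quantifier_ion(table, voc_ids[i])
  }
  key <- tibble::tibble(voc_id = voc_ids, quantifier_mz = as.integer(qmz))
  table$fragments |>
    dplyr::inner_join(key, by = "voc_id") |>
    dplyr::filter(.data$mz == .data$quantifier_mz) |>
    dplyr::left_join(table$subjects, by = "subject_id") |>
    dplyr::select("subject_id", "group", "voc_id", "quantifier_mz", "area")
}

# ---- retention index --------------------------------------------------------

#' Kovats-style retention index
#'
#' Linear interpolation of a retention time between the bracketing n-alkane
#' retention times: `RI = 100 * (n + (rt - t_n) / (t_{n+1} - t_n))`.
#'
#' @param rt retention time (minutes).
#' @param alkane_rts named numeric vector, names are alkane carbon numbers,
#'   values their retention times in minutes; must be strictly increasing.
#' @return The retention index (exactly `100 * n` at an alkane anchor).
#' @export
compute_retention_index <- function(rt, alkane_rts) {
  n <- as.integer(names(alkane_rts))
  o <- order(n)
  n <- n[o]; t_n <- unname(alkane_rts[o])
  if (any(diff(t_n) <= 0)) stop("alkane retention times must be increasing")
  if (rt < t_n[1] || rt > t_n[length(t_n)]) {
    stop("retention time outside the alkane calibration range")
  }
  i <- findInterval(rt, t_n, rightmost.closed = TRUE)
  100 * (n[i] + (rt - t_n[i]) / (t_n[i + 1] - t_n[i]))
}

# ---- group summary ----------------------------------------------------------

#' Two-group summary of a variable
#'
#' Mean, standard error of the mean (sample SD over sqrt(n)), fold change
#' (positive mean / control mean) and, optionally, exact Mann-Whitney
#' p-values for a variable measured in the two diagnostic groups.
#'
#' @param control,positive numeric vectors (non-empty; `NA` dropped).
#' @param variable variable name carried through to the output.
#' @param test if `TRUE` (default) attach [mann_whitney()] p-values.
#' @return One-row tibble with `variable, mean_control, sem_control,
#'   mean_positive, sem_positive, fold, p_two_tailed, p_one_tailed`. `fold`
#'   is `NA` (flagged, not an error) when the control mean is zero.
#' @export
group_summary <- function(control, positive, variable = "value", test = TRUE) {
  control <- control[!is.na(control)]
  positive <- positive[!is.na(positive)]
  stopifnot(length(control) > 0, length(positive) > 0)
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  mc <- mean(control); mp <- mean(positive)
  fold <- if (mc > 0) mp / mc else NA_real_
  p2 <- p1 <- NA_real_
  if (test) {
    mw <- mann_whitney(positive, control)
    p2 <- mw$p_two_tailed; p1 <- mw$p_one_tailed
  }
  tibble::tibble(
    variable = variable,
    mean_control = mc, sem_control = sem(control),
    mean_positive = mp, sem_positive = sem(positive),
    fold = fold, p_two_tailed = p2, p_one_tailed = p1
  )
}
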