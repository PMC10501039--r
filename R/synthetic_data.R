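#' @importFrom stats rnorm runif qlnorm pnorm rbinom
NULL

# ---- calibration constants --------------------------------------------------

# Published per-group quantifier-area summaries for the 20 named urinary VOCs
# (control vs MDD/agoraphobia-positive, n = 9 each): arithmetic mean and SEM
# of the quantifier-ion area, fragment m/z triplets, retention times and
# whether the identification was confirmed against a commercial standard.
# n_outlier > 0 marks compounds whose published rank test was NOT significant
# despite a large mean fold: their excess mean is carried by a couple of
# extreme subjects rather than a distributional shift (see the methods
# vignette).
effect_calibration <- function() {
  e <- function(voc_id, name, cas, class, rt, mzs, used, mc, sc, mp, sp,
                confirmed, n_outlier = 0, force_separation = FALSE) {
    tibble::tibble(
      voc_id = voc_id, name = name, cas = cas, chemical_class = class,
      retention_time_min = rt, fragment_mzs = list(as.integer(mzs)),
      quantifier_mz = as.integer(used), confirmed_standard = confirmed,
      mean_control = mc, sem_control = sc,
      mean_positive = mp, sem_positive = sp,
      detect_prob_control = 1, detect_prob_positive = 1,
      force_separation = force_separation, n_outlier = n_outlier,
      tic_scale = 3.0
    )
  }
  out <- dplyr::bind_rows(
    e("acetyl_tetrazole", "2-acetyl-2H-tetrazole", "51410-11-8",
      "Diarylethers", 15.97, c(42, 43), 43,
      896619, 108935, 1188273, 137696, FALSE),
    e("octanedione", "2,3-Octanedione", "585-25-1",
      "Alpha-diketone", 19.46, c(43, 57, 71), 43,
      17480, 2462, 31273, 8861, FALSE, n_outlier = 2),
    e("allyl_itc", "Allyl isothiocyanate", "57-06-7",
      "Organosulfur/isothiocyanate", 20.50, c(41, 72, 99), 99,
      667199, 554308, 171145, 54542, FALSE, n_outlier = 2),
    e("ditb_benzene", "Benzene, 1,3-bis(1,1-dimethylethyl)-", "1014-60-4",
      "Benzenoids", 22.53, c(41, 57, 175), 175,
      32371, 15202, 16238, 2147, FALSE, n_outlier = 2),
    e("acetic_acid", "Acetic acid", "64-19-7",
      "Carboxylic acids and derivatives", 23.26, c(43, 45, 60), 43,
      343894, 85633, 385236, 207645, FALSE),
    e("butene_itc", "1-Butene 4-isothiocyanate", "3386-97-8",
      "Organosulfur/isothiocyanate", 23.39, c(55, 72, 113), 113,
      29243, 14845, 1306697, 1191445, TRUE, n_outlier = 2),
    e("dmso", "Dimethyl sulfoxide", "67-68-5",
      "Sulfoxides", 25.99, c(45, 63, 78), 63,
      32197, 6114, 73214, 21273, TRUE, n_outlier = 2),
    e("menthol", "Menthol", "15356-70-4",
      "Prenol lipids", 28.17, c(71, 81, 95), 71,
      151744, 59924, 64621, 23668, FALSE, n_outlier = 2),
    e("carvone", "(-)-Carvone", "6485-40-1",
      "Prenol lipids", 30.28, c(54, 82, 93), 82,
      45357, 30608, 53152, 23399, FALSE),
    e("dms", "Dimethyl sulfone", "67-71-0",
      "Sulfones", 33.89, c(79, 94), 79,
      660288, 140962, 1328412, 290284, TRUE),
    e("benzothiazole", "Benzothiazole", "95-16-9",
      "Benzenoids", 35.05, c(82, 108, 135), 135,
      19864, 3788, 17627, 2854, FALSE),
    e("phenol", "Phenol", "108-95-2",
      "Benzenoids", 36.12, c(65, 66, 94), 94,
      43106, 19370, 39801, 14563, FALSE),
    e("p_cresol", "p-Cresol", "106-44-5",
      "Benzenoids", 37.62, c(77, 107, 108), 107,
      31128, 11066, 65472, 36074, FALSE, n_outlier = 2),
    e("methoxy_vinylphenol", "2-Methoxy-4-vinylphenol", "7786-61-0",
      "Benzenoids", 39.79, c(107, 135, 150), 150,
      81457, 29571, 35448, 10739, FALSE, n_outlier = 2),
    e("dichlorophenol", "2,5-Dichlorophenol", "583-78-8",
      "Benzenoids", 39.86, c(63, 162, 164), 162,
      168307, 57814, 1041674, 587894, TRUE, n_outlier = 2),
    e("phenethyl_itc", "Phenethyl isothiocyanate", "2257-09-2",
      "Benzenoids/isothiocyanate", 40.30, c(91, 163), 91,
      31162, 8863, 350507, 179957, TRUE),
    e("hexanoic_acid", "Hexanoic acid", "142-62-1",
      "Medium-chain fatty acids", 32.89, c(60, 73, 87), 60,
      429620, 32655, 301160, 30979, TRUE),
    e("texanol", "2,2,4-Trimethyl-1,3-pentanediol 1-monoisobutyrate (texanol)",
      "25265-77-4", "Hydrocarbon", 33.41, c(56, 71, 89), 71,
      293552, 7765, 355679, 9990, TRUE, force_separation = TRUE),
    e("texanol_isomer",
      "2,2,4-Trimethyl-1,3-pentanediol 3-monoisobutyrate (texanol isomer)",
      "", "Hydrocarbon", 33.70, c(43, 71, 83), 71,
      345878, 10438, 409732, 12109, TRUE),
    e("piperidinone", "2-Piperidinone", "675-20-7",
      "Piperidine", 38.21, c(55, 70, 99), 99,
      107248, 47157, 93972, 43154, FALSE)
  )
  # Planted TIC-level group fold. All 20 compounds were nominated as showing
  # differential TIC (or feature-extracted) signal, so the TIC fold is the
  # quantifier fold pushed clear of the screening thresholds: at least 2.0
  # for compounds with a positive-direction excess, at most 0.5 for
  # negative-direction ones.
  fold <- out$mean_positive / out$mean_control
  out$tic_fold <- ifelse(fold >= 1, pmax(fold, 2.0), pmin(fold, 0.5))
  out
}

# Published cohort-variable summaries (mean, SEM per group) with documented
# ranges; integer-valued questionnaire scores are rounded after drawing.
cohort_calibration <- function() {
  tibble::tribble(
    ~variable,            ~mean_control, ~sem_control, ~mean_positive, ~sem_positive, ~lo,  ~hi, ~integer, ~positive_only,
    "kihon_cl",            3.667,         0.943,        7.222,          1.164,         0,    20,  TRUE,     FALSE,
    "tmig_ic",             12.00,         0.527,        11.22,          0.572,         0,    13,  TRUE,     FALSE,
    "jst_ic",              11.33,         1.225,        9.222,          1.331,         0,    16,  TRUE,     FALSE,
    "dskc",                1.000,         0.441,        2.667,          0.289,         0,    5,   TRUE,     FALSE,
    "dskc_self",           0.667,         0.373,        3.556,          0.176,         0,    5,   TRUE,     FALSE,
    "sds",                 33.56,         2.615,        40.44,          2.652,         20,   80,  TRUE,     FALSE,
    "grid_hamd",           NA,            NA,           12.22,          1.526,         7,    52,  TRUE,     TRUE,
    "serum_creatinine",    0.720,         0.049,        0.769,          0.056,         0.01, Inf, FALSE,    FALSE,
    "urinary_creatinine",  76.82,         13.65,        79.44,          11.76,         0.1,  Inf, FALSE,    FALSE,
    "ucreat_per_weight",   1.344,         0.199,        1.564,          0.300,         0.01, Inf, FALSE,    FALSE,
    "specific_gravity",    1.014,         0.002,        1.014,          0.001,         1.00, 1.06, FALSE,   FALSE
  )
}

# Matched design of the study cohort: six men and three women per group,
# ages as enrolled.
cohort_ages <- function() {
  list(
    positive = tibble::tibble(
      sex = c(rep("M", 6), rep("F", 3)),
      age = c(67, 73, 77, 78, 79, 84, 74, 77, 87)
    ),
    control = tibble::tibble(
      sex = c(rep("M", 6), rep("F", 3)),
      age = c(70, 73, 75, 78, 79, 85, 73, 77, 87)
    )
  )
}

# Deterministic background-species metadata: 137 compounds with no group
# effect, population quantifier means log-spaced across 1e3..1e6 area units
# and fragment m/z triplets derived arithmetically from the species index.
# The species list never depends on the generator seed.
background_species <- function(n_background) {
  idx <- seq_len(n_background)
  base <- 35L + as.integer((idx * 37L) %% 230L)
  tibble::tibble(
    voc_id = sprintf("bg_%03d", idx),
    name = sprintf("background compound %03d", idx),
    cas = "", chemical_class = "Unassigned",
    retention_time_min = round(5 + 45 * (idx - 1) / max(1, n_background - 1), 3),
    fragment_mzs = lapply(base, function(b) pmin(b + c(0L, 7L, 15L), 300L)),
    quantifier_mz = base,
    confirmed_standard = FALSE,
    mean_area = 10^(3 + 3 * (idx - 1) / max(1, n_background - 1))
  )
}

#' Default generator configuration
#'
#' The packaged calibration: 9 positive and 9 control subjects, 157 VOC
#' species of which 20 carry the published group effects (with texanol's
#' complete group separation enforced and the texanol / texanol-isomer
#' correlation of 0.8094 planted in the positive group), 137 background
#' species with no group effect (log-normal, CV 0.25, population means
#' log-spaced over 1e3--1e6 area units), three background species subjected
#' to detection dropout (zeroed in all but two subjects), TIC areas at 3x
#' the quantifier area, and cohort scores drawn from the published
#' per-group means and SEMs. Default seed: 2015.
#'
#' @param seed integer seed driving all randomness (required downstream).
#' @return A list config consumed by [generate_dataset()].
#' @export
default_calibration <- function(seed = 2015) {
  list(
    seed = seed,
    n_positive = 9,
    n_control = 9,
    n_species = 157,
    effects = effect_calibration(),
    background_cv = 0.25,
    background_tic_scale = 3.0,
    n_dropout_species = 3,
    dropout_keep_subjects = 2,
    copula_rho = 0.8094,
    copula_members = c("texanol", "texanol_isomer"),
    force_separation_enabled = TRUE,
    cohort = cohort_calibration()
  )
}

# deterministic substream seed per module/stage name
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

# log-normal parameterized by arithmetic mean and SD on the natural scale
lnorm_pars <- function(m, s) {
  cv2 <- (s / m)^2
  list(mu = log(m) - 0.5 * log1p(cv2), sigma = sqrt(log1p(cv2)))
}

rlnorm_ms <- function(n, m, s) {
  p <- lnorm_pars(m, s)
  exp(p$mu + p$sigma * rnorm(n))
}

rtrunc_norm <- function(n, m, s, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, m, s)
      if (v >= lo && v <= hi) { out[i] <- v; break }
    }
  }
  out
}

#' Generate a synthetic peak table and cohort table
#'
#' Draws a complete subject x VOC peak table plus matched cohort scores with
#' the statistical structure the downstream analysis assumes: log-normal
#' quantifier areas matching the calibrated per-group means/SEMs (SD =
#' SEM * sqrt(9), the study-scale sampling error), contaminated draws for
#' compounds whose published rank test was non-significant despite a large
#' mean fold, a Gaussian copula planting the texanol / texanol-isomer
#' correlation in the positive group, enforced complete texanol separation,
#' detection dropout for a few background species, TIC areas proportional to
#' quantifier areas with the planted TIC-level group folds, and cohort
#' scores as rounded truncated normals clamped to their documented ranges.
#' Deterministic for a fixed seed; the species list, subject ids and group
#' sizes do not depend on the seed.
#'
#' @param config a configuration list, see [default_calibration()].
#' @return list with elements `peaks` (a [as_peak_table()] object) and
#'   `cohort` (a cohort tibble with an extra logical `agoraphobia_only`
#'   column marking the one positive subject diagnosed with agoraphobia but
#'   not depression).
#' @export
generate_dataset <- function(config = default_calibration()) {
  if (is.null(config$seed)) {
    stop("config$seed is required: the generator refuses to run unseeded")
  }
  np <- config$n_positive; nc <- config$n_control
  eff <- config$effects
  n_bg <- config$n_species - nrow(eff)
  if (n_bg < 0) stop("n_species smaller than the number of named effects")
  bg <- background_species(n_bg)

  width <- max(2, nchar(as.character(np + nc)))
  subjects <- tibble::tibble(
    subject_id = c(sprintf(paste0("P%0", width, "d"), seq_len(np)),
                   sprintf(paste0("C%0", width, "d"), np + seq_len(nc))),
    group = c(rep("positive", np), rep("control", nc))
  )
  pos_ids <- subjects$subject_id[subjects$group == "positive"]
  ctl_ids <- subjects$subject_id[subjects$group == "control"]

  species <- dplyr::bind_rows(
    dplyr::select(eff, "voc_id", "name", "cas", "chemical_class",
                  "retention_time_min", "fragment_mzs", "quantifier_mz",
                  "confirmed_standard"),
    dplyr::select(bg, "voc_id", "name", "cas", "chemical_class",
                  "retention_time_min", "fragment_mzs", "quantifier_mz",
                  "confirmed_standard")
  )

  q_areas <- with_substream(config$seed, "areas", {
    draw_all_quantifier_areas(eff, bg, np, nc, config)
  })

  # detection dropout: a few background species visible in only two subjects
  dropout <- with_substream(config$seed, "dropout", {
    if (config$n_dropout_species > 0 && n_bg >= config$n_dropout_species) {
      ids <- sample(bg$voc_id, config$n_dropout_species)
      lapply(stats::setNames(ids, ids), function(v) {
        sample(subjects$subject_id, config$dropout_keep_subjects)
      })
    } else list()
  })
  for (v in names(dropout)) {
    zero <- !(subjects$subject_id %in% dropout[[v]])
    q_areas[[v]][zero] <- 0
  }

  # per-subject fragment areas: deterministic relative abundances with the
  # quantifier ion carrying the largest fraction
  frag_ratios <- c(1, 0.55, 0.25, 0.12)
  frag_list <- vector("list", nrow(species))
  for (i in seq_len(nrow(species))) {
    v <- species$voc_id[i]
    mzs <- species$fragment_mzs[[i]]
    qmz <- species$quantifier_mz[i]
    others <- setdiff(mzs, qmz)
    ratio <- stats::setNames(
      c(1, frag_ratios[seq_along(others) + 1]), c(qmz, others)
    )
    frag_list[[i]] <- tidyr::expand_grid(
      subject_id = subjects$subject_id, mz = as.integer(names(ratio))
    ) |>
      dplyr::mutate(
        voc_id = v,
        area = q_areas[[v]][match(.data$subject_id, subjects$subject_id)] *
          unname(ratio[as.character(.data$mz)])
      ) |>
      dplyr::select("subject_id", "voc_id", "mz", "area")
  }
  fragments <- dplyr::bind_rows(frag_list)

  # TIC areas: proportional to the quantifier area; for the named effects the
  # positive group is rescaled so the realized group-mean TIC fold equals the
  # planted TIC-level fold
  tic_scale <- stats::setNames(
    c(eff$tic_scale, rep(config$background_tic_scale, n_bg)),
    c(eff$voc_id, bg$voc_id)
  )
  tic_rows <- vector("list", nrow(species))
  is_pos <- subjects$group == "positive"
  for (i in seq_len(nrow(species))) {
    v <- species$voc_id[i]
    tic <- q_areas[[v]] * tic_scale[[v]]
    j <- match(v, eff$voc_id)
    if (!is.na(j) && !is.na(eff$tic_fold[j])) {
      mc <- mean(tic[!is_pos]); mp <- mean(tic[is_pos])
      if (mc > 0 && mp > 0) tic[is_pos] <- tic[is_pos] * eff$tic_fold[j] * mc / mp
    }
    tic_rows[[i]] <- tibble::tibble(
      subject_id = subjects$subject_id, voc_id = v, tic_area = tic
    )
  }
  tic <- dplyr::bind_rows(tic_rows)

  peaks <- as_peak_table(species, subjects, fragments, tic)

  cohort <- with_substream(config$seed, "cohort", {
    draw_cohort(config, subjects, pos_ids, ctl_ids)
  })

  list(peaks = peaks, cohort = cohort)
}

# Draw quantifier areas for every species; returns a named list of numeric
# vectors in subject order (positives first, then controls).
draw_all_quantifier_areas <- function(eff, bg, np, nc, config) {
  out <- list()
  copula <- config$copula_members
  do_copula <- length(copula) == 2 && all(copula %in% eff$voc_id)

  draw_group <- function(row, n, side) {
    m_this <- if (side == "positive") row$mean_positive else row$mean_control
    s_this <- if (side == "positive") row$sem_positive else row$sem_control
    m_other <- if (side == "positive") row$mean_control else row$mean_positive
    s_other <- if (side == "positive") row$sem_control else row$sem_positive
    # SD is calibrated at the study scale (n = 9 per group)
    sd_this <- s_this * 3; sd_other <- s_other * 3
    if (row$n_outlier > 0 && m_this > m_other) {
      # contaminated group: mostly baseline (other group's distribution)
      # plus outlier subjects carrying the published excess mean
      k <- max(1L, round(n * row$n_outlier / 9))
      m_out <- (n * m_this - (n - k) * m_other) / k
      vals <- rlnorm_ms(n, m_other, sd_other)
      pos <- sample(n, k)
      vals[pos] <- rlnorm_ms(k, m_out, 0.5 * m_out)
      vals
    } else {
      rlnorm_ms(n, m_this, sd_this)
    }
  }

  for (i in seq_len(nrow(eff))) {
    row <- eff[i, ]
    v <- row$voc_id
    if (do_copula && v == copula[2]) next  # drawn jointly with the first
    if (do_copula && v == copula[1]) {
      j <- match(copula[2], eff$voc_id)
      row2 <- eff[j, ]
      rho <- config$copula_rho
      z1 <- rnorm(np)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(np)
      p1 <- lnorm_pars(row$mean_positive, row$sem_positive * 3)
      p2 <- lnorm_pars(row2$mean_positive, row2$sem_positive * 3)
      pos1 <- exp(p1$mu + p1$sigma * z1)
      pos2 <- exp(p2$mu + p2$sigma * z2)
      ctl1 <- rlnorm_ms(nc, row$mean_control, row$sem_control * 3)
      ctl2 <- rlnorm_ms(nc, row2$mean_control, row2$sem_control * 3)
      if (isTRUE(config$force_separation_enabled) &&
          (row$force_separation || row2$force_separation)) {
        sep_on_1 <- row$force_separation
        tries <- 0
        while (tries < 500) {
          bad1 <- sep_on_1 && min(pos1) <= max(ctl1)
          bad2 <- !sep_on_1 && min(pos2) <= max(ctl2)
          if (!bad1 && !bad2) break
          z1 <- rnorm(np)
          z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(np)
          pos1 <- exp(p1$mu + p1$sigma * z1)
          pos2 <- exp(p2$mu + p2$sigma * z2)
          tries <- tries + 1
        }
        # fallback: minimal multiplicative lift of the offending values
        lift <- function(pos, ctl) {
          mx <- max(ctl)
          off <- pos <= mx
          if (any(off)) pos[off] <- mx * (1 + 1e-3 * rank(pos[off]))
          pos
        }
        if (sep_on_1 && min(pos1) <= max(ctl1)) pos1 <- lift(pos1, ctl1)
        if (!sep_on_1 && min(pos2) <= max(ctl2)) pos2 <- lift(pos2, ctl2)
      }
      out[[copula[1]]] <- c(pos1, ctl1)
      out[[copula[2]]] <- c(pos2, ctl2)
      next
    }
    pos <- draw_group(row, np, "positive")
    ctl <- draw_group(row, nc, "control")
    if (isTRUE(config$force_separation_enabled) && row$force_separation) {
      tries <- 0
      while (min(pos) <= max(ctl) && tries < 500) {
        pos <- draw_group(row, np, "positive")
        tries <- tries + 1
      }
      if (min(pos) <= max(ctl)) {
        mx <- max(ctl)
        off <- pos <= mx
        pos[off] <- mx * (1 + 1e-3 * rank(pos[off]))
      }
    }
    # detection dropout by configured probability
    if (row$detect_prob_positive < 1) {
      pos[runif(np) > row$detect_prob_positive] <- 0
    }
    if (row$detect_prob_control < 1) {
      ctl[runif(nc) > row$detect_prob_control] <- 0
    }
    out[[v]] <- c(pos, ctl)
  }

  cv <- config$background_cv
  for (i in seq_len(nrow(bg))) {
    m <- bg$mean_area[i]
    out[[bg$voc_id[i]]] <- rlnorm_ms(np + nc, m, cv * m)
  }
  out
}

draw_cohort <- function(config, subjects, pos_ids, ctl_ids) {
  np <- length(pos_ids); nc <- length(ctl_ids)
  cal <- config$cohort
  ages <- cohort_ages()
  demo <- if (np == 9 && nc == 9) {
    dplyr::bind_rows(
      dplyr::mutate(ages$positive, subject_id = pos_ids, group = "positive"),
      dplyr::mutate(ages$control, subject_id = ctl_ids, group = "control")
    )
  } else {
    tibble::tibble(
      subject_id = subjects$subject_id, group = subjects$group,
      sex = rep_len(c("M", "F"), np + nc),
      age = sample(66:88, np + nc, replace = TRUE)
    )
  }
  out <- demo[, c("subject_id", "group", "sex", "age")]
  for (i in seq_len(nrow(cal))) {
    row <- cal[i, ]
    draw <- function(n, m, s) {
      if (is.na(m)) return(rep(NA_real_, n))
      v <- rtrunc_norm(n, m, s * 3, row$lo, row$hi)
      if (row$integer) v <- pmin(row$hi, pmax(row$lo, round(v)))
      v
    }
    pos_vals <- draw(np, row$mean_positive, row$sem_positive)
    ctl_vals <- if (row$positive_only) rep(NA_real_, nc) else {
      draw(nc, row$mean_control, row$sem_control)
    }
    vals <- c(pos_vals, ctl_vals)[match(out$subject_id,
                                        c(pos_ids, ctl_ids))]
    out[[row$variable]] <- vals
  }
  # one positive subject carries agoraphobia without depressive symptoms;
  # index-score correlations can exclude this subject
  out$agoraphobia_only <- out$subject_id == pos_ids[length(pos_ids)]
  out[, c(cohort_cols, "agoraphobia_only")]
}
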