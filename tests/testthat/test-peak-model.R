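test_that("long peak-table files round-trip and zero-fill missing cells", {
  # hand-written 2-subject, 2-VOC long file with one absent (subject, voc)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("subject_id", "group", "voc_id", "name", "cas",
          "retention_time_min", "mz", "fragment_area", "tic_area", sep = "\t"),
    "s1\tpositive\tva\tcompound A\t1-2-3\t10.5\t57\t100.25\t400",
    "s1\tpositive\tvb\tcompound B\t\t12.0\t71\t200\t650",
    "s2\tcontrol\tva\tcompound A\t1-2-3\t10.5\t57\t50\t180"
    # (s2, vb) intentionally absent -> all-zero measurement
  ), tmp)
  pt <- read_peak_table(tmp, "long")
  expect_equal(nrow(pt$species), 2)
  expect_equal(nrow(pt$tic), 4)  # dense grid
  missing_cell <- pt$fragments[pt$fragments$subject_id == "s2" &
                               pt$fragments$voc_id == "vb", ]
  expect_equal(missing_cell$area, 0)
  expect_equal(pt$tic$tic_area[pt$tic$subject_id == "s2" &
                               pt$tic$voc_id == "vb"], 0)
  expect_equal(pt$subjects$subject_id, c("s1", "s2"))  # file order kept

  # round-trip: write back and re-read; data grid identical
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(pt, tmp2, "long")
  pt2 <- read_peak_table(tmp2, "long")
  ord <- function(d) d[order(d$subject_id, d$voc_id, d$mz), ]
  expect_equal(ord(pt2$fragments), ord(pt$fragments))
  expect_equal(pt2$tic[order(pt2$tic$subject_id, pt2$tic$voc_id), ],
               pt$tic[order(pt$tic$subject_id, pt$tic$voc_id), ])

  # area values survive as decimal text, bit-exact
  expect_identical(
    pt2$fragments$area[pt2$fragments$subject_id == "s1" &
                       pt2$fragments$voc_id == "va"],
    100.25
  )
})

test_that("malformed peak-table input is rejected with a precise error", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tgroup\tvoc_id", "s1\tpositive\tva"), tmp)
  expect_error(read_peak_table(tmp), "missing column")

  # valid header, no data
  tmp_empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("subject_id", "group", "voc_id", "name", "cas",
                   "retention_time_min", "mz", "fragment_area", "tic_area",
                   sep = "\t"), tmp_empty)
  expect_error(read_peak_table(tmp_empty), "no data rows")

  # duplicate (subject, voc, mz) record
  tmp_dup <- withr::local_tempfile(fileext = ".tsv")
  row <- "s1\tpositive\tva\tA\t\t10\t57\t100\t300"
  writeLines(c(paste("subject_id", "group", "voc_id", "name", "cas",
                     "retention_time_min", "mz", "fragment_area", "tic_area",
                     sep = "\t"), row, row), tmp_dup)
  expect_error(read_peak_table(tmp_dup), "duplicate")
})

test_that("wide format writes a readable (lossy) view of the same grid", {
  set.seed(11)
  pt <- pt_from_matrix(matrix(rlnorm(12, 8), 4), c("positive", "positive",
                                                   "control", "control"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(pt, tmp, "wide")
  pt2 <- read_peak_table(tmp, "wide")
  expect_equal(sort(pt2$species$voc_id), sort(pt$species$voc_id))
  ord <- function(d) d[order(d$subject_id, d$voc_id, d$mz), ]
  expect_equal(ord(pt2$fragments)$area, ord(pt$fragments)$area)
})

test_that("quantifier-ion selection takes the largest summed area with a
           smallest-m/z tie-break", {
  species <- tibble::tibble(
    voc_id = c("dms_like", "single", "tied"),
    name = c("dms_like", "single", "tied"), cas = "",
    chemical_class = "t", retention_time_min = c(33.9, 10, 20),
    fragment_mzs = list(c(79L, 94L), 101L, c(55L, 70L)),
    quantifier_mz = NA_integer_, confirmed_standard = FALSE
  )
  subjects <- tibble::tibble(subject_id = c("a", "b"),
                             group = c("positive", "control"))
  frag <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 5),
    voc_id = rep(c("dms_like", "dms_like", "single", "tied", "tied"), 2),
    mz = rep(c(79L, 94L, 101L, 55L, 70L), 2),
    area = c(300, 200, 40, 60, 70, 200, 100, 10, 40, 30)
  )
  tic <- tidyr::expand_grid(subject_id = c("a", "b"),
                            voc_id = species$voc_id)
  tic$tic_area <- 1000
  pt <- as_peak_table(species, subjects, frag, tic)

  # 79: 500 vs 94: 300 -> 79
  expect_identical(select_quantifier_ion(pt, "dms_like"), 79L)
  # single-fragment species -> that fragment
  expect_identical(select_quantifier_ion(pt, "single"), 101L)
  # 55: 100 vs 70: 100 -> smallest m/z wins
  expect_identical(select_quantifier_ion(pt, "tied"), 55L)

  # permutation invariance in subject order
  pt_rev <- as_peak_table(species, subjects[2:1, ], frag, tic)
  for (v in species$voc_id) {
    expect_identical(select_quantifier_ion(pt_rev, v),
                     select_quantifier_ion(pt, v))
  }

  # all-zero species -> no-signal error
  frag0 <- frag; frag0$area[frag0$voc_id == "single"] <- 0
  pt0 <- as_peak_table(species, subjects, frag0, tic)
  expect_error(select_quantifier_ion(pt0, "single"), "no signal")
})

test_that("retention index interpolates linearly between alkane anchors", {
  alk <- c("10" = 12.0, "11" = 14.0, "12" = 16.5)
  expect_equal(compute_retention_index(12.0, alk), 1000)   # anchor
  expect_equal(compute_retention_index(13.0, alk), 1050)   # midpoint
  expect_equal(compute_retention_index(12.5, alk), 1025)   # quarter point
  expect_equal(compute_retention_index(16.5, alk), 1200)   # last anchor
  expect_error(compute_retention_index(11.0, alk), "outside")
  expect_error(compute_retention_index(17.0, alk), "outside")
  # monotone increasing in rt
  rts <- seq(12.0, 16.5, length.out = 40)
  ris <- vapply(rts, compute_retention_index, 0, alkane_rts = alk)
  expect_true(all(diff(ris) > 0))
})

test_that("group summaries report mean, SEM (n-1 sd), and fold", {
  ctl <- c(1, 2, 3, 4)
  pos <- c(2, 4, 6, 8)
  gs <- group_summary(ctl, pos, "toy")
  expect_equal(gs$mean_control, 2.5)
  expect_equal(gs$sem_control, sd(ctl) / 2)
  expect_equal(gs$fold, 2)
  # fold = 1 for identical groups
  expect_equal(group_summary(pos, pos, test = FALSE)$fold, 1)
  # fold invariant under common positive scaling
  gs_scaled <- group_summary(ctl * 1e4, pos * 1e4, test = FALSE)
  expect_equal(gs_scaled$fold, gs$fold)
  # zero control mean: flagged as NA, not an error
  expect_true(is.na(group_summary(c(0, 0), c(1, 2), test = FALSE)$fold))
})

test_that("cohort tables round-trip and enforce documented score ranges", {
  cohort <- generate_dataset(default_calibration(42))$cohort
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(cohort, tmp)
  back <- read_cohort_table(tmp)
  expect_equal(back$kihon_cl, cohort$kihon_cl)
  expect_true(all(is.na(back$grid_hamd[back$group == "control"])))

  bad <- cohort
  bad$sds[1] <- 99
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(bad, tmp2)
  expect_error(read_cohort_table(tmp2), "sds outside")
})
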