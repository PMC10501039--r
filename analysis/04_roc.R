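#!/usr/bin/env Rscript
# Stage 4: ROC evaluation. Single-marker AUCs for the significant panel and
# combined-VOC screening indices (PRE-1 values from regressing the diagnosis
# indicator on member areas): the texanol + texanol-isomer pair and the
# dimethyl sulfone + phenethyl isothiocyanate + hexanoic acid triple.
suppressPackageStartupMessages(library(vocscreen))

peaks <- read_peak_table("results/data/peak_table.tsv")
diffs <- readr::read_tsv("results/differential_vocs.tsv",
                         show_col_types = FALSE)
sig <- diffs$voc_id[diffs$significant]

aucs <- list()
points <- list()
qa <- quantifier_areas(peaks, sig)
for (v in sig) {
  sub <- qa[qa$voc_id == v, ]
  r <- roc_curve(sub$area, sub$group)
  aucs[[v]] <- list(auc = r$auc, youden_cutoff = r$youden_cutoff,
                    sensitivity = r$sensitivity_at_cutoff,
                    specificity = r$specificity_at_cutoff,
                    orientation_flipped = r$orientation_flipped)
  points[[v]] <- tibble::tibble(marker = v, threshold = r$thresholds,
                                sensitivity = r$sensitivity,
                                specificity = r$specificity)
}

members <- list(
  two_voc = c("texanol", "texanol_isomer"),
  three_voc = c("dms", "phenethyl_itc", "hexanoic_acid")
)
indices <- list()
for (nm in names(members)) {
  idx <- combined_index(peaks, members[[nm]])
  indices[[nm]] <- idx
  r <- roc_curve(idx$values$index, idx$values$group)
  aucs[[nm]] <- list(auc = r$auc, youden_cutoff = r$youden_cutoff,
                     sensitivity = r$sensitivity_at_cutoff,
                     specificity = r$specificity_at_cutoff,
                     orientation_flipped = r$orientation_flipped)
  points[[nm]] <- tibble::tibble(marker = nm, threshold = r$thresholds,
                                 sensitivity = r$sensitivity,
                                 specificity = r$specificity)
  readr::write_tsv(idx$values, sprintf("results/index_%s.tsv", nm),
                   progress = FALSE)
}

jsonlite::write_json(aucs, "results/auc.json", auto_unbox = TRUE, digits = NA)
readr::write_tsv(dplyr::bind_rows(points), "results/roc_points.tsv",
                 progress = FALSE)

message("AUCs:")
for (nm in names(aucs)) {
  message(sprintf("  %-16s %.4f%s", nm, aucs[[nm]]$auc,
                  if (aucs[[nm]]$orientation_flipped) " (flipped)" else ""))
}
message("Wrote results/auc.json, results/roc_points.tsv, results/index_*.tsv")
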