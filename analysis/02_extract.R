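#!/usr/bin/env Rscript
# Stage 2: differential-VOC extraction. Applies the three TIC screening
# rules (mean TIC > 10,000 in a group; detected in >= 3 subjects of a
# group; fold > 1.5 or < 0.7), then tests each candidate's quantifier-ion
# areas with the exact Mann-Whitney test.
suppressPackageStartupMessages(library(vocscreen))

peaks <- read_peak_table("results/data/peak_table.tsv")
# standard-confirmation status is experiment metadata, not part of the peak
# table format: re-annotate from the packaged calibration
cal <- default_calibration()$effects
peaks$species$confirmed_standard <-
  peaks$species$voc_id %in% cal$voc_id[cal$confirmed_standard]

extraction <- extract_differential_vocs(peaks)
readr::write_tsv(extraction$filters, "results/tic_filters.tsv",
                 progress = FALSE)
readr::write_tsv(extraction$diffs, "results/differential_vocs.tsv",
                 progress = FALSE)

bs <- extraction$biomarkers
message(sprintf(
  "Cascade: %d of %d species nominated; %d significant (one-tailed p <= 0.05); %d combination-eligible.",
  nrow(bs$nominated), nrow(extraction$filters),
  nrow(bs$significant), nrow(bs$combination_eligible)
))
message("Significant: ", paste(bs$significant$voc_id, collapse = ", "))
message("Wrote results/tic_filters.tsv, results/differential_vocs.tsv")
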