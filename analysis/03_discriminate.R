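#!/usr/bin/env Rscript
# Stage 3: quadratic discriminant on the significant panel (capped at six
# markers): explicit polynomial coefficients, per-subject scores and
# judgements, per-class discriminant probability, and Box's M.
suppressPackageStartupMessages(library(vocscreen))

peaks <- read_peak_table("results/data/peak_table.tsv")
diffs <- readr::read_tsv("results/differential_vocs.tsv",
                         show_col_types = FALSE)
sig <- diffs[diffs$significant, ]
sig <- sig[order(sig$p_one_tailed, sig$voc_id), ]
panel <- head(sig$voc_id, 6)

model <- fit_qda(peaks, panel)
evaluation <- evaluate_training(model, peaks)

co <- evaluation$coefficients
jsonlite::write_json(
  list(features = co$features, a0 = co$a0, a = as.list(co$a),
       C = unname(apply(co$C, 1, as.list))),
  "results/discriminant_coefficients.json", auto_unbox = TRUE, digits = NA
)
readr::write_tsv(evaluation$scores, "results/discriminant_scores.tsv",
                 progress = FALSE)

dp <- evaluation$discriminant_probability_percent
message("Panel: ", paste(panel, collapse = ", "))
message(sprintf(
  "Discriminant probability: positive %.3f%%, control %.3f%% (errors %.3f%% / %.3f%%).",
  dp[["positive"]], dp[["control"]],
  100 - dp[["positive"]], 100 - dp[["control"]]
))
message(sprintf("Box's M = %.2f, chi2(%d) = %.2f, p = %.3g (class covariances differ).",
                evaluation$box_m$m_statistic, evaluation$box_m$df,
                evaluation$box_m$chi2_approx, evaluation$box_m$p_value))
message("Wrote results/discriminant_coefficients.json, results/discriminant_scores.tsv")
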