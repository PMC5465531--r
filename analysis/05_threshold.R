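#!/usr/bin/env Rscript
# ROC analysis: percentage test-method change as a detector of a reference
# change above 10%, with the 8% operating point.

suppressPackageStartupMessages(library(hemotrend))
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

derived <- read_measurements("results/derived_co.csv")
pairs <- paired_co(derived$patient_id, derived$timepoint,
                   co_ref = derived$co_pac, co_test = derived$co_tte)
t1 <- pairs[pairs$timepoint == 1, ]
t2 <- pairs[pairs$timepoint == 2, ]
deltas <- compute_deltas(t1[t1$patient_id %in% t2$patient_id, ], t2)

roc <- roc_analysis(deltas, positive_pct = 10)
print(roc)
op <- operating_point(roc, threshold = 8)
cat(sprintf(
  "at test change > 8%%: sensitivity %.0f%%, specificity %.0f%% (tp %d, fp %d, tn %d, fn %d)\n",
  op$sensitivity_pct, op$specificity_pct, op$tp, op$fp, op$tn, op$fn
))
yj <- youden_point(roc)
cat(sprintf("Youden-optimal threshold (for reference): %.1f%%\n", yj$threshold))

out <- unclass(roc)
out$operating_point <- op
out$youden <- yj
jsonlite::write_json(out, "results/roc.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
ggplot2::ggsave("results/figures/roc.png", plot_roc(roc, 8),
                width = 5, height = 5, dpi = 150)
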