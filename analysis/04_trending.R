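#!/usr/bin/env Rscript
# Trending ability: 24-h CO changes for re-measured patients, four-quadrant
# concordance (15% exclusion zone) and half-circle polar statistics
# (0.5 L/min exclusion zone, +/-30 degree band).

suppressPackageStartupMessages(library(hemotrend))
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

derived <- read_measurements("results/derived_co.csv")
pairs <- paired_co(derived$patient_id, derived$timepoint,
                   co_ref = derived$co_pac, co_test = derived$co_tte)
t1 <- pairs[pairs$timepoint == 1, ]
t2 <- pairs[pairs$timepoint == 2, ]
deltas <- compute_deltas(t1[t1$patient_id %in% t2$patient_id, ], t2)
cat(sprintf("%d change pairs\n", nrow(deltas)))

tr <- trending_analysis(deltas)
print(tr)
cat(if (tr$good_trending_fq) {
  "four-quadrant concordance exceeds the 90% good-trending cutoff\n"
} else {
  "four-quadrant concordance is below the 90% good-trending cutoff\n"
})

jsonlite::write_json(unclass(tr), "results/trending.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
ggplot2::ggsave("results/figures/four_quadrant.png", plot_four_quadrant(deltas),
                width = 5, height = 5, dpi = 150)
ggplot2::ggsave("results/figures/polar.png", plot_polar(deltas),
                width = 6, height = 4, dpi = 150)
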