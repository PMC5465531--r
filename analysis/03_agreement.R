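#!/usr/bin/env Rscript
# Agreement between the two CO methods over all measurement pairs:
# correlation, Bland-Altman bias and limits of agreement, percentage error.

suppressPackageStartupMessages(library(hemotrend))
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

derived <- read_measurements("results/derived_co.csv")
pairs <- paired_co(derived$patient_id, derived$timepoint,
                   co_ref = derived$co_pac, co_test = derived$co_tte)
ag <- agreement_analysis(pairs)
print(ag)
if (ag$pe_pct <= 30) {
  cat("percentage error within the 30% interchangeability criterion\n")
} else {
  cat("percentage error exceeds the 30% interchangeability criterion\n")
}

jsonlite::write_json(unclass(ag), "results/agreement.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
ggplot2::ggsave("results/figures/bland_altman.png",
                plot_bland_altman(pairs, ag), width = 5, height = 4, dpi = 150)
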