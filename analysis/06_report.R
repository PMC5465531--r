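#!/usr/bin/env Rscript
# End-to-end report: the whole pipeline in one call from the raw CSV, with
# the default configuration echoed into the provenance block.

suppressPackageStartupMessages(library(hemotrend))

report <- run_full_analysis("results/raw_measurements.csv", analysis_config())
print(report)
write_report(report, "results/report.json")
cat("wrote results/report.json\n")
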