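#!/usr/bin/env Rscript
# Derive per-pair CO values from the raw measurements (echo: LVOT area x
# mean VTI x HR; reference: mean of 5 thermodilution boluses) and compute
# replicate-based precision and least significant change for both methods.

suppressPackageStartupMessages(library(hemotrend))

raw <- read_measurements("results/raw_measurements.csv")
derived <- derive_co(raw)
write_derived_co(derived, "results/derived_co.csv")
cat(sprintf("derived CO for %d patient-timepoints -> results/derived_co.csv\n",
            nrow(derived)))

prec_ref <- precision_stats(replicate_sets(raw, "ref"),
                            "reference (thermodilution)")
prec_test <- precision_stats(replicate_sets(raw, "test"), "test (echo VTI)")
print(prec_ref)
print(prec_test)

jsonlite::write_json(
  list(reference = unclass(prec_ref), test = unclass(prec_test)),
  "results/precision.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)
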