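#!/usr/bin/env Rscript

# Generate the synthetic study data used by the downstream analyses:
# a two-genotype feature table with planted 8-fold differential features,
# blank contamination and an internal reference, plus a labeled/control
# tracer table with planted D3 and D11 isotopologue partners.

suppressPackageStartupMessages(library(deutrace))
dir.create("results", showWarnings = FALSE)

sim <- generate_differential_table(
  n_features = 200, n_differential = 10, fold_change = 8,
  n_per_group = 6, noise_sigma = 0.2, seed = 101
)
write_feature_table(sim$table, "results/differential_features.csv",
                    "results/differential_manifest.csv")
readr::write_csv(sim$truth, "results/differential_truth.csv")
cat("differential table:", nrow(sim$table$features), "features;",
    sum(sim$truth$class == "differential"), "planted at 8-fold\n")

tr <- generate_tracer_table(
  labeled_fraction = 0.2, n_d_values = c(3L, 11L), ppm_jitter = 0,
  n_features = 100, seed = 102
)
write_feature_table(tr$table, "results/tracer_features.csv",
                    "results/tracer_manifest.csv")
readr::write_csv(tr$truth, "results/tracer_truth.csv")
cat("tracer table:", nrow(tr$table$features), "features;",
    sum(tr$truth$class == "labeled_partner"), "planted labeled partners\n")
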