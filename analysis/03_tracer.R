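#!/usr/bin/env Rscript

# Match deuterium-labeled isotopologue partners in the simulated tracer
# table (labeled vs control condition), score label enrichment, and
# annotate the pairs with tracer-fate model predictions for the
# D13-labeled C11 metabolite family.

suppressPackageStartupMessages(library(deutrace))

tab <- read_feature_table("results/tracer_features.csv",
                          "results/tracer_manifest.csv")
truth <- readr::read_csv("results/tracer_truth.csv", show_col_types = FALSE)

des <- tracer_design("labeled", "control", n_range = 1:13)
pairs <- find_label_pairs(tab, des)
pairs <- score_enrichment(pairs, tab, des)
preds <- predict_c11_family("d13_cis")
pairs <- annotate_predictions(pairs, tab, preds[c("name", "n_d", "mz")])
readr::write_csv(pairs, "results/tracer_pairs.csv")

planted <- truth[truth$class == "labeled_partner", ]
hit <- merge(pairs, planted, by.x = "labeled_id", by.y = "feature_id")
cat(sprintf("pairs found: %d (planted: %d); correct parent and D count: %d\n",
            nrow(pairs), nrow(planted),
            sum(hit$unlabeled_id == hit$partner_of & hit$n_d.x == hit$n_d.y)))
cat("verdicts:\n")
print(table(pairs$verdict))
cat("pair table written to results/tracer_pairs.csv\n")
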