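#!/usr/bin/env Rscript
# One-command reproduction: the full pipeline (tabulation, three growth
# fits with DIC deltas, logistic comparison, thresholds) on each fixture,
# serialised to JSON under results/.

suppressPackageStartupMessages(library(alpacatestis))
dir.create("results", showWarnings = FALSE)
seed <- 20160205

rep1 <- run_full_analysis(table_fixture("experiment1"), seed = seed)
report_json(rep1, "results/report_experiment1.json")
print(rep1)

rep2 <- run_full_analysis(table_fixture("experiment2"), seed = seed + 1)
report_json(rep2, "results/report_experiment2.json")
print(rep2)
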