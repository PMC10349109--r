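#!/usr/bin/env Rscript
# Step 4 — expression gating of candidate genes.
#
# RPKM credibility binning of the candidate genes from step 2 in the
# normal-atrium controls, and the tumor-vs-normal percent change. A gene is
# kept only when credibly expressed above background in the control tissue
# (the criterion that retained the moderately expressed, decreased
# candidate and rejected the not-credibly expressed one).

library(myxotriage)

manifest <- read_manifest("results/cohort/manifest.tsv")
expr <- readr::read_tsv("results/cohort/expression.tsv", show_col_types = FALSE)
candidates <- readr::read_tsv("results/triage/candidates.tsv",
                              show_col_types = FALSE, na = ".")

gate <- expression_gate(unique(candidates$gene), expr, manifest)
readr::write_tsv(gate, "results/expression_gate.tsv", na = ".")
print(as.data.frame(gate))
cat("\nkept", sum(gate$keep), "of", nrow(gate), "candidate genes;",
    "mean percent change of kept genes:",
    round(mean(gate$percent_change[gate$keep]), 1), "%\n")
cat("wrote results/expression_gate.tsv\n")
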