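#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates the synthetic stand-in for the study's post-annotation data:
# two discovery tumor patients (D1, D2) with a PBMC sample for D2, three
# normal atrial tissues, 26 sporadic validation patients and two
# lab-control exomes; 1000 background variants, 100 common variants, 10
# recurrent artifacts and 2 planted hereditary causal variants, plus an
# RPKM expression table in which the planted genes are credibly expressed
# in normal tissue and decreased ~66% in tumors.

library(myxotriage)

cfg <- sim_config(seed = 1L)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cat("samples:", nrow(cohort$manifest), "\n")
print(table(cohort$manifest$arm))
cat("call rows:", nrow(cohort$calls), "over",
    length(unique(variant_id_of(cohort$calls))), "distinct variants\n")
cat("planted hereditary:", length(cohort$truth$hereditary),
    "| artifacts:", length(cohort$truth$artifacts),
    "| common:", length(cohort$truth$common), "\n")
cat("lab control database:", length(cohort$control_db), "variants\n")
cat("wrote results/cohort/{manifest,calls,control_db,expression}.tsv + truth.json\n")
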