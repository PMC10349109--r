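---
title: "Variant triage for left atrial myxoma: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant triage for left atrial myxoma: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myxotriage)
```

## The procedure and its assumptions

`myxotriage` implements a filter-cascade prioritization for a small
tumor/blood/normal exome design: two discovery tumor patients, a
germline-representative PBMC sample for one of them, normal atrial tissue
controls, a sporadic validation arm, and lab-control exomes. The cascade
assumes:

- **Annotation is upstream.** Variant calling, gene/region annotation and
  per-database frequencies arrive precomputed; the package consumes a
  normalized table and never queries live databases.
- **A causal hereditary variant is fully penetrant in the discovery
  design**: present in every discovery tumor and PBMC, absent from normal
  atrium. A causal somatic variant is clonal enough to be called in every
  tumor and absent from blood. Presence/absence is binary; allele fraction
  and zygosity play no role in the set logic (zygosity is carried to
  reports only).
- **Recurrence across unrelated sporadic patients indicates a platform
  artifact, not causality** — reasonable for a rare disease where unrelated
  patients are not expected to share the same rare allele, and the basis of
  the systematic-error stage.
- **Rarity matters jointly**: a variant at or above the frequency threshold
  in *any* configured database is excluded; a missing frequency is treated
  as "rare until observed" (the "or NA" clause), which is deliberate —
  coercing missing to 0 would be indistinguishable from "observed absent"
  and silently change the rule.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `maf_threshold` | 0.001 | strict per-database frequency bound (fraction) |
| `maf_databases` | 1000g EAS, ESP6500, ExAC | databases that must each pass |
| `allowed_regions` | exonic, splicing | annotation categories admitted |
| `allowed_func` | nonsyn., frameshift, splicing, stopgain, stoploss, unknown | damaging-compatible classes |
| `min_votes` | 4 | consensus threshold over the six predictors |
| `min_patients` | 2 | distinct sporadic patients that brand an artifact |
| `min_bin` | middle | weakest control-tissue RPKM bin the gate accepts |

Predictor cutoffs (SIFT < 0.1, PolyPhen-2 ∈ {D, P}, PhyloP > 0.95,
GERP++ > 4, MutationTaster ∈ {A, D}, LRT = D) are the published criteria;
all inequalities are strict, so boundary values (SIFT = 0.1, GERP++ = 4)
do not vote. A missing predictor abstains rather than voting damaging,
because the consensus counts positive damaging predictions only.

## Decisions where the design was open

- **Locus identity.** Coordinates are 1-based (VCF convention); alleles are
  uppercased and trimmed to a minimal left-anchored representation
  (`normalize_variant()`), making "same variation at the same locus"
  well-defined for the artifact and control-database stages. Exact
  normalized-key matching is used for the lab-database subtraction.
- **Which patients count as "different patients" for artifacts.** The
  artifact definition is recurrence across unrelated *sporadic* patients,
  so recurrence is counted over distinct `patient_id`s of the validation
  arm (a patient's tumor + blood pair counts once). Counting discovery
  patients would be self-defeating: any hereditary candidate is present in
  both discovery patients by definition. An `arms` argument widens the
  counted arms for users who want the stricter behavior.
- **"Present in both myxoma tissues"** generalizes to *every* discovery
  tumor (`tumor_presence = "all"`), with `"any"` available.
- **Genotype-to-zygosity.** GT allele counts map 1 copy → Het, 2 copies →
  Hom; genotypes that are not diploid or reference undeclared alleles are
  rejected loudly. Multiallelic records split into one record per alternate
  allele on ingest.
- **RPKM bin boundaries.** The published bin description leaves exactly 1
  and exactly 10 unassigned; half-open intervals closed on the left
  ([1, 10), [10, 100)) are adopted, plus a fourth bin (≥ 100, "high") so
  the binning is total on [0, ∞).
- **The 66% average decrease statistic.** Whether it is a percent change of
  mean RPKM or a mean of per-sample percent changes is ambiguous;
  `expression_gate()` defaults to percent change of the case/control means
  (`change = "percent_of_aggregates"`) and offers `"mean_of_percents"`.
  Aggregation defaults to the arithmetic mean (an "average" decrease),
  with median available.
- **ACMG conflict handling.** The combining table is encoded as data
  (`acmg_rule_table`), not branching code. The default `intervar_default`
  profile lets a firing benign tier win when pathogenic evidence reaches no
  combination — the only behavior consistent with a published
  {PM2, BP4, BP7} → likely benign call — and returns uncertain significance
  when a firing pathogenic tier co-occurs with any benign evidence. A
  `strict_acmg` profile (any firing conflict → uncertain) is selectable.
  Evidence-code *assignment* is out of scope; codes are inputs.
- **Fail-closed configuration.** Unknown config keys error with a
  nearest-key suggestion instead of being ignored, because a silently
  misspelled `maf_threshold` would invalidate the whole triage.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` reproduces the *statistical structure the triage
assumes*, with planted truth labels:

- the study's sample design (2 discovery tumors, 1 discovery PBMC, 3
  normal atria, 26 sporadic validation patients, 2 lab-control exomes);
- planted hereditary variants that pass every screening condition, carry
  ≥ 4 damaging votes, and whose genes are credibly expressed in control
  tissue (RPKM drawn in [20, 80]) with a planted case decrease of 66%
  (lognormal per-sample noise, CV 0.05 — so realized changes land near,
  not exactly at, −66);
- recurrent artifacts that mimic the hereditary presence pattern but recur
  in 2–5 validation patients;
- common variants with frequencies ≥ 0.001 (Beta-tailed spectrum) spread
  across samples including the lab controls, so the control database is
  derived the way the real one was — from variants observed in lab-control
  exomes;
- background variants, each violating at least one screening condition at
  configured rates, with per-database frequency missingness (point mass
  0.3).

Each artifact class draws from its own RNG stream derived from the master
seed, so outputs are byte-identical per seed and adding classes does not
perturb existing fixtures. Positions live on a synthetic contig (`chrS`)
to avoid implying real genomic coordinates.

**Limits.** The generator plants *separable* truth: planted positives pass
all filters and nothing else survives them, so recall 1.0 / zero false
positives on synthetic cohorts demonstrates the *logic* is implemented
correctly — not that the filters have those operating characteristics on
real exomes, where causal variants can fail a filter (a true 3'UTR variant
fails the region screen by design) and artifacts can evade recurrence. The
real study's intermediate counts ("five genes and twenty loci") depend on
undeposited raw data and an in-house control database and are not
reproduction targets; the published five-variant worked example
(`generate_worked_example()`) is the in-paper regression fixture instead.
There is no read-level simulation, no sequencing-error model and no
linkage structure. Background scale defaults to 10³ variants (desk scale)
against ~10⁴–10⁵ in a real exome; the config scales up.

## Numerical choices and degenerate inputs

- MAF comparison is strict `<`; equality at the threshold excludes.
- `"."`, `""` and `"NA"` all parse to missing in annotation columns.
- RPKM uses the exact closed form; the generator converts target RPKM to
  integer read counts and back, so emitted tables are self-consistent to
  rounding.
- Degenerate inputs error early and by name: empty manifests, duplicate
  sample ids, unknown tissue/arm/zygosity values, frequencies outside
  [0, 1], zero gene length or library size, short > long diameters,
  candidates without annotations, missing required sample roles.
- Set operations return sorted keys, making outputs order-deterministic.

## Problem sizes used in the checks

The test suite exercises oracle equivalence on 100+ random cohorts of up
to 50 variants × 10 samples against brute-force evaluation of the set
expressions, exhaustive enumeration of all 3⁶ coarse predictor states and
all ACMG code sets of size ≤ 3 against an independently coded rule table,
and full-pipeline recovery over 20 seeds at 10³ background variants. The
acceptance script re-runs the pipeline over 10 seeded cohorts at the same
scale. These sizes were chosen as the smallest at which every code path
and every planted artifact class is exercised; all results above them are
properties of the algebra (set logic, counting), not of scale.
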