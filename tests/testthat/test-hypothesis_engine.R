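study_manifest <- function() {
  dplyr::bind_rows(
    tibble::tibble(sample_id = c("D1_T", "D2_T", "D2_B"),
                   patient_id = c("D1", "D2", "D2"),
                   tissue = c("tumor", "tumor", "pbmc"), arm = "discovery"),
    tibble::tibble(sample_id = c("N1", "N2", "N3"),
                   patient_id = c("PN1", "PN2", "PN3"),
                   tissue = "normal_atrium", arm = "normal_control"),
    tibble::tibble(sample_id = paste0("V", 1:6), patient_id = paste0("PV", 1:6),
                   tissue = "tumor", arm = "validation"))
}

call_rows <- function(pos, samples, gene = "G1") {
  tibble::tibble(sample_id = samples, chrom = "chrS", pos = pos, ref = "A",
                 alt = "G", zygosity = "Het", gene = gene,
                 region = "exonic", func_class = "nonsynonymous")
}

test_that("hereditary and somatic set logic follow the presence/absence definitions", {
  m <- study_manifest()
  calls <- dplyr::bind_rows(
    call_rows(100, c("D1_T", "D2_T", "D2_B")),            # hereditary pattern
    call_rows(200, c("D1_T", "D2_T")),                    # somatic pattern
    call_rows(300, c("D1_T", "D2_T", "D2_B", "N1")),      # in a normal -> excluded
    call_rows(400, c("D1_T", "D2_B")),                    # missing one tumor
    call_rows(500, c("D1_T", "D2_T", "N2")))              # somatic-like but in normal
  h <- hereditary_candidates(calls, m)
  s <- somatic_candidates(calls, m)
  expect_equal(h, "chrS:100:A>G")
  expect_equal(s, "chrS:200:A>G")
  # presence in any normal atrium excludes regardless of tumor status
  expect_false("chrS:300:A>G" %in% c(h, s))
  expect_false("chrS:500:A>G" %in% c(h, s))
  # pbmc presence separates the hypotheses: they are disjoint
  expect_length(intersect(h, s), 0L)
  # tumor_presence = "any" relaxes the all-tumors requirement
  expect_true("chrS:400:A>G" %in% hereditary_candidates(calls, m, tumor_presence = "any"))
})

test_that("missing required sample roles are reported by name", {
  m <- study_manifest()
  calls <- call_rows(100, "D1_T")
  no_pbmc <- m[!(m$tissue == "pbmc" & m$arm == "discovery"), ]
  expect_error(hereditary_candidates(calls, no_pbmc), "discovery pbmc")
  no_normal <- m[m$tissue != "normal_atrium", ]
  expect_error(somatic_candidates(calls, no_normal), "normal_atrium")
})

test_that("staged triage equals brute-force set-expression evaluation on random cohorts", {
  set.seed(41)
  for (i in 1:25) {
    co <- random_small_cohort(n_variants = sample(10:50, 1),
                              n_extra_samples = sample(0:6, 1))
    for (hyp in c("hereditary", "somatic")) {
      fn <- if (hyp == "hereditary") hereditary_candidates else somatic_candidates
      expect_equal(fn(co$calls, co$manifest),
                   oracle_hypothesis(co$calls, co$manifest, hyp),
                   info = sprintf("cohort %d, %s", i, hyp))
    }
  }
})

test_that("systematic-error elimination counts distinct sporadic patients", {
  m <- study_manifest()
  calls <- dplyr::bind_rows(
    call_rows(100, c("D1_T", "D2_T", "D2_B")),                  # true hereditary
    call_rows(200, c("D1_T", "D2_T", "D2_B", "V1", "V2", "V3")),# artifact: 3 patients
    call_rows(300, c("D1_T", "D2_T", "D2_B", "V4")))            # 1 sporadic patient
  cands <- hereditary_candidates(calls, m)
  expect_setequal(cands, c("chrS:100:A>G", "chrS:200:A>G", "chrS:300:A>G"))
  kept <- remove_systematic_errors(cands, calls, m, min_patients = 2)
  # the recurrent artifact is removed; singleton observations are retained
  expect_setequal(kept, c("chrS:100:A>G", "chrS:300:A>G"))
  # discovery patients sharing a variant do not make it an artifact
  expect_true("chrS:100:A>G" %in% kept)
  # counting is per patient, not per sample: duplicate samples of one
  # patient count once
  m2 <- dplyr::bind_rows(m, tibble::tibble(sample_id = "V1b", patient_id = "PV1",
                                           tissue = "tumor", arm = "validation"))
  calls2 <- dplyr::bind_rows(call_rows(600, c("D1_T", "D2_T", "D2_B", "V1", "V1b")))
  expect_equal(remove_systematic_errors("chrS:600:A>G", calls2, m2), "chrS:600:A>G")
  # sweeping min_patients upward only shrinks the removal set
  removed_at <- vapply(2:5, function(k) {
    length(cands) - length(remove_systematic_errors(cands, calls, m, min_patients = k))
  }, numeric(1))
  expect_true(all(diff(removed_at) <= 0))
  expect_error(remove_systematic_errors(cands, calls, m, min_patients = 1), ">= 2")
})

test_that("control-database subtraction is exact-key set difference", {
  cands <- c("chrS:1:A>G", "chrS:2:C>T", "chrS:3:G>A")
  expect_equal(subtract_control_db(cands, character()), sort(cands))
  out <- subtract_control_db(cands, c("chrS:2:C>T", "chrS:9:T>A"))
  expect_setequal(out, c("chrS:1:A>G", "chrS:3:G>A"))
  expect_equal(length(out), length(cands) - length(intersect(cands, "chrS:2:C>T")))
})

test_that("summaries report genes and loci with a consistent provenance ledger", {
  ann <- dplyr::bind_rows(
    call_rows(100, "D1_T", gene = "KIF1C"),
    call_rows(200, "D1_T", gene = "KIF1C"),
    call_rows(300, "D1_T", gene = "CYP1A2"),
    call_rows(400, "D1_T", gene = "CYP1A2"))
  cands <- variant_id_of(ann)
  cs <- summarize_candidates(cands, ann, "hereditary")
  # the published outcome shape: two candidate genes and four loci
  expect_equal(cs$n_genes, 2L)
  expect_equal(cs$n_loci, 4L)
  expect_lte(cs$n_genes, cs$n_loci)
  empty <- summarize_candidates(character(), ann, "somatic")
  expect_equal(c(empty$n_genes, empty$n_loci), c(0L, 0L))
  expect_error(summarize_candidates("chrS:999:A>G", ann, "hereditary"),
               "unannotated")
})

test_that("each triage stage is monotone and idempotent, and the final set is order-independent", {
  set.seed(42)
  m <- study_manifest()
  co <- random_small_cohort(n_variants = 40, n_extra_samples = 6)
  cands <- hereditary_candidates(co$calls, co$manifest)
  s1 <- remove_systematic_errors(cands, co$calls, co$manifest)
  expect_true(all(s1 %in% cands))
  expect_equal(remove_systematic_errors(s1, co$calls, co$manifest), s1)
  db <- sample(variant_id_of(co$calls), 5)
  s2 <- subtract_control_db(s1, db)
  expect_true(all(s2 %in% s1))
  expect_equal(subtract_control_db(s2, db), s2)
  # control-db first, systematic second gives the same final set
  alt_order <- remove_systematic_errors(subtract_control_db(cands, db),
                                        co$calls, co$manifest)
  expect_equal(alt_order, s2)
})
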