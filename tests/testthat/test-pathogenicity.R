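scores_row <- function(sift = NA_real_, polyphen2 = NA_character_,
                       phylop = NA_real_, gerp = NA_real_,
                       mutationtaster = NA_character_, lrt = NA_character_) {
  tibble::tibble(sift = sift, polyphen2 = polyphen2, phylop = phylop,
                 gerp = gerp, mutationtaster = mutationtaster, lrt = lrt)
}

test_that("damaging votes follow the six published criteria with strict bounds", {
  th <- predictor_thresholds()
  all_damaging <- scores_row(0.01, "D", 2.0, 5.1, "D", "D")
  expect_equal(damaging_votes(all_damaging, th), 6L)
  # strict inequalities: boundary values do not vote
  expect_equal(damaging_votes(scores_row(sift = 0.1), th), 0L)
  expect_equal(damaging_votes(scores_row(sift = 0.0999), th), 1L)
  expect_equal(damaging_votes(scores_row(phylop = 0.95), th), 0L)
  expect_equal(damaging_votes(scores_row(gerp = 4), th), 0L)
  # category predictors: P counts for PolyPhen-2, A for MutationTaster,
  # only D for LRT
  expect_equal(damaging_votes(scores_row(polyphen2 = "P"), th), 1L)
  expect_equal(damaging_votes(scores_row(polyphen2 = "B"), th), 0L)
  expect_equal(damaging_votes(scores_row(mutationtaster = "A"), th), 1L)
  expect_equal(damaging_votes(scores_row(mutationtaster = "N"), th), 0L)
  expect_equal(damaging_votes(scores_row(lrt = "U"), th), 0L)
  # missing predictors abstain
  expect_equal(damaging_votes(scores_row(), th), 0L)
})

test_that("consensus is 'at least four of six' and matches exhaustive enumeration", {
  th <- predictor_thresholds()
  # exactly 4 votes -> damaging; 3 -> not
  four <- scores_row(0.01, "D", 2.0, 5.1, NA_character_, NA_character_)
  three <- scores_row(0.01, "D", 2.0, NA_real_, NA_character_, NA_character_)
  expect_true(consensus_damaging(four, th))
  expect_false(consensus_damaging(three, th))
  # exhaustive: every damaging/benign/missing combination of the six
  # predictors agrees with an independent per-predicate count
  states <- expand.grid(rep(list(c("dmg", "ben", "mis")), 6),
                        stringsAsFactors = FALSE)
  val <- list(
    sift = c(dmg = 0.05, ben = 0.5, mis = NA),
    polyphen2 = c(dmg = "D", ben = "B", mis = NA),
    phylop = c(dmg = 1.2, ben = 0.1, mis = NA),
    gerp = c(dmg = 5, ben = 1, mis = NA),
    mutationtaster = c(dmg = "A", ben = "N", mis = NA),
    lrt = c(dmg = "D", ben = "N", mis = NA))
  tbl <- tibble::tibble(
    sift = as.numeric(val$sift[states[[1]]]),
    polyphen2 = as.character(val$polyphen2[states[[2]]]),
    phylop = as.numeric(val$phylop[states[[3]]]),
    gerp = as.numeric(val$gerp[states[[4]]]),
    mutationtaster = as.character(val$mutationtaster[states[[5]]]),
    lrt = as.character(val$lrt[states[[6]]]))
  got <- damaging_votes(tbl, th)
  manual <- rowSums(states == "dmg")
  expect_equal(got, as.integer(manual))
  expect_equal(consensus_damaging(tbl, th), manual >= 4)
  # and on random continuous scores against the loop oracle
  set.seed(51)
  rnd <- random_scores(200)
  expect_equal(damaging_votes(rnd, th),
               vapply(seq_len(200), function(i) oracle_votes(rnd[i, ], th), integer(1)))
})

test_that("vote count is monotone as any single predictor becomes more extreme", {
  th <- predictor_thresholds()
  base <- scores_row(0.5, "B", 0.0, 0.0, "N", "N")
  stronger <- list(
    scores_row(0.01, "B", 0.0, 0.0, "N", "N"),
    scores_row(0.5, "P", 0.0, 0.0, "N", "N"),
    scores_row(0.5, "D", 0.0, 0.0, "N", "N"),
    scores_row(0.5, "B", 2.0, 0.0, "N", "N"),
    scores_row(0.5, "B", 0.0, 5.0, "N", "N"),
    scores_row(0.5, "B", 0.0, 0.0, "D", "N"),
    scores_row(0.5, "B", 0.0, 0.0, "N", "D"))
  v0 <- damaging_votes(base, th)
  for (s in stronger) expect_gte(damaging_votes(s, th), v0)
})

test_that("the published evidence-code sets classify exactly as printed", {
  expect_equal(acmg_classify(c("PM1", "PM2")), "uncertain_significance")
  expect_equal(acmg_classify(c("PM1", "PM2", "PP3")), "uncertain_significance")
  expect_equal(acmg_classify(c("PM2", "BP4", "BP7")), "likely_benign")
  expect_equal(acmg_classify(c("BS1", "BP4")), "likely_benign")
  expect_equal(acmg_classify(character()), "uncertain_significance")
  expect_error(acmg_classify("PM9"), "unknown")
})

test_that("classification agrees with an independent rule-table oracle on all small code sets", {
  sets <- c(list(character()),
            lapply(ACMG_CODES, identity),
            combn(ACMG_CODES, 2, simplify = FALSE),
            combn(ACMG_CODES, 3, simplify = FALSE))
  got <- acmg_classify_all(sets)
  want <- vapply(sets, oracle_acmg, character(1))
  expect_equal(got, want)
  # plus a few larger spot checks across the rule table
  expect_equal(acmg_classify(c("PVS1", "PS1")), "pathogenic")
  expect_equal(acmg_classify(c("PVS1", "PM2")), "likely_pathogenic")
  expect_equal(acmg_classify(c("PM1", "PM2", "PM4")), "likely_pathogenic")
  expect_equal(acmg_classify(c("PS1", "PM1", "PM2", "PM4")), "pathogenic")
  expect_equal(acmg_classify("BA1"), "benign")
  expect_equal(acmg_classify(c("BS1", "BS2")), "benign")
})

test_that("benign-only evidence never classifies pathogenic and vice versa; codes move one way", {
  ranks <- c(benign = 1, likely_benign = 2, uncertain_significance = 3,
             likely_pathogenic = 4, pathogenic = 5)
  benign_codes <- grep("^B", ACMG_CODES, value = TRUE)
  path_codes <- grep("^P", ACMG_CODES, value = TRUE)
  set.seed(52)
  for (i in 1:50) {
    b <- sample(benign_codes, sample(1:4, 1))
    expect_lte(ranks[acmg_classify(b)], ranks["uncertain_significance"])
    p <- sample(path_codes, sample(1:4, 1))
    expect_gte(ranks[acmg_classify(p)], ranks["uncertain_significance"])
    # adding PP never moves toward benign; adding BP never toward pathogenic
    mixed <- sample(ACMG_CODES, sample(1:3, 1))
    base_rank <- ranks[acmg_classify(mixed)]
    expect_gte(ranks[acmg_classify(unique(c(mixed, "PP1")))], base_rank)
    expect_lte(ranks[acmg_classify(unique(c(mixed, "BP1")))], base_rank)
  }
  # strict profile sends any firing pathogenic+benign conflict to uncertain
  expect_equal(acmg_classify(c("PM1", "PM2", "PM3", "BP1", "BP2"),
                             profile = "strict_acmg"),
               "uncertain_significance")
})

test_that("evidence-code strings parse to sets", {
  expect_equal(parse_evidence_codes(c("PM1, PM2", "", NA))[[1]], c("PM1", "PM2"))
  expect_equal(parse_evidence_codes("BS1,BP4")[[1]], c("BS1", "BP4"))
  expect_length(parse_evidence_codes(NA_character_)[[1]], 0L)
})
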