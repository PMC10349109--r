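# Consensus in-silico damage voting over six predictors, and ACMG/AMP
# evidence-code combination into the five-tier classification.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Predictor damage thresholds
#'
#' Defaults are the six published criteria: SIFT < 0.1, PolyPhen-2 in
#' \{D, P\}, PhyloP > 0.95, GERP++ > 4, MutationTaster in \{A, D\},
#' LRT = D; a variant is called damaging by consensus when at least
#' `min_votes` (default 4) of the six predictors vote damaging.
#' Inequalities are strict exactly as published — boundary values fail —
#' and a missing predictor abstains (contributes no vote) rather than
#' counting as damaging.
#'
#' @param sift_lt SIFT strict upper bound for a damaging vote.
#' @param polyphen2_damaging PolyPhen-2 categories voting damaging.
#' @param phylop_gt PhyloP strict lower bound.
#' @param gerp_gt GERP++ strict lower bound.
#' @param mutationtaster_damaging MutationTaster categories voting damaging.
#' @param lrt_damaging LRT categories voting damaging.
#' @param min_votes Consensus threshold ("at least" semantics), in 1..6.
#' @return A `predictor_thresholds` list.
#' @export
predictor_thresholds <- function(sift_lt = 0.1,
                                 polyphen2_damaging = c("D", "P"),
                                 phylop_gt = 0.95,
                                 gerp_gt = 4,
                                 mutationtaster_damaging = c("A", "D"),
                                 lrt_damaging = "D",
                                 min_votes = 4L) {
  min_votes <- as.integer(min_votes)
  if (min_votes < 1L || min_votes > 6L) stop("min_votes must be in 1..6", call. = FALSE)
  structure(list(sift_lt = sift_lt,
                 polyphen2_damaging = polyphen2_damaging,
                 phylop_gt = phylop_gt,
                 gerp_gt = gerp_gt,
                 mutationtaster_damaging = mutationtaster_damaging,
                 lrt_damaging = lrt_damaging,
                 min_votes = min_votes),
            class = "predictor_thresholds")
}

#' Count damaging predictor votes
#'
#' Counts, per row, how many of the six predictors' present values satisfy
#' their damaging criterion (0..6). Missing predictors contribute 0 votes.
#'
#' @param scores A tibble with columns `sift`, `polyphen2`, `phylop`,
#'   `gerp`, `mutationtaster`, `lrt` (any may be missing / NA).
#' @param th A [predictor_thresholds()].
#' @return Integer vector of vote counts.
#' @export
damaging_votes <- function(scores, th = predictor_thresholds()) {
  n <- nrow(scores)
  col <- function(name, default) {
    if (name %in% names(scores)) scores[[name]] else rep(default, n)
  }
  vote <- function(x, pred) !is.na(x) & pred(x)
  v <- vote(col("sift", NA_real_), function(x) x < th$sift_lt) +
    vote(col("polyphen2", NA_character_), function(x) x %in% th$polyphen2_damaging) +
    vote(col("phylop", NA_real_), function(x) x > th$phylop_gt) +
    vote(col("gerp", NA_real_), function(x) x > th$gerp_gt) +
    vote(col("mutationtaster", NA_character_), function(x) x %in% th$mutationtaster_damaging) +
    vote(col("lrt", NA_character_), function(x) x %in% th$lrt_damaging)
  as.integer(v)
}

#' Consensus damaging call
#'
#' `TRUE` when [damaging_votes()] reaches at least `th$min_votes`
#' (default: damaging by at least four of the six predictors).
#'
#' @inheritParams damaging_votes
#' @return Logical vector.
#' @export
consensus_damaging <- function(scores, th = predictor_thresholds()) {
  damaging_votes(scores, th) >= th$min_votes
}

#' The 28 ACMG/AMP evidence codes
#' @export
ACMG_CODES <- c("PVS1",
                paste0("PS", 1:4),
                paste0("PM", 1:6),
                paste0("PP", 1:5),
                "BA1",
                paste0("BS", 1:4),
                paste0("BP", 1:7))

CLASSIFICATION_LEVELS <- c("benign", "likely_benign", "uncertain_significance",
                           "likely_pathogenic", "pathogenic")

# ACMG/AMP 2015 combining rules as data: a rule fires when the evidence-set
# category counts meet every minimum; the strongest firing tier wins.
acmg_rule_table <- function() {
  rule <- function(tier, pvs = 0, ps = 0, pm = 0, pp = 0, ba = 0, bs = 0, bp = 0) {
    tibble::tibble(tier = tier, pvs = pvs, ps = ps, pm = pm, pp = pp,
                   ba = ba, bs = bs, bp = bp)
  }
  dplyr::bind_rows(
    rule("pathogenic", pvs = 1, ps = 1),
    rule("pathogenic", pvs = 1, pm = 2),
    rule("pathogenic", pvs = 1, pm = 1, pp = 1),
    rule("pathogenic", pvs = 1, pp = 2),
    rule("pathogenic", ps = 2),
    rule("pathogenic", ps = 1, pm = 3),
    rule("pathogenic", ps = 1, pm = 2, pp = 2),
    rule("pathogenic", ps = 1, pm = 1, pp = 4),
    rule("likely_pathogenic", pvs = 1, pm = 1),
    rule("likely_pathogenic", ps = 1, pm = 1),
    rule("likely_pathogenic", ps = 1, pp = 2),
    rule("likely_pathogenic", pm = 3),
    rule("likely_pathogenic", pm = 2, pp = 2),
    rule("likely_pathogenic", pm = 1, pp = 4),
    rule("benign", ba = 1),
    rule("benign", bs = 2),
    rule("likely_benign", bs = 1, bp = 1),
    rule("likely_benign", bp = 2)
  )
}

code_category_counts <- function(codes) {
  codes <- unique(codes)
  bad <- setdiff(codes, ACMG_CODES)
  if (length(bad)) {
    stop("unknown ACMG/AMP evidence code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  c(pvs = sum(codes == "PVS1"),
    ps = sum(grepl("^PS", codes)),
    pm = sum(grepl("^PM", codes)),
    pp = sum(grepl("^PP", codes)),
    ba = sum(codes == "BA1"),
    bs = sum(grepl("^BS", codes)),
    bp = sum(grepl("^BP", codes)))
}

#' Combine ACMG/AMP evidence codes into a classification
#'
#' Applies the ACMG/AMP 2015 combining-rule table (encoded as data in
#' `acmg_rule_table`): the pathogenic tier is the strongest pathogenic /
#' likely-pathogenic combination that fires, the benign tier the strongest
#' benign / likely-benign combination. The two tiers are then resolved by
#' the selected profile:
#' \describe{
#'   \item{`intervar_default`}{If only one tier fires, return it. If the
#'     benign tier fires while the pathogenic evidence reached no
#'     combination, the benign call wins (this is the behavior required by
#'     the published likely-benign calls such as \{PM2, BP4, BP7\}). A
#'     pathogenic-tier call of likely_pathogenic or stronger in the presence
#'     of any benign evidence returns uncertain_significance.}
#'   \item{`strict_acmg`}{Any co-occurrence of a firing pathogenic tier and
#'     a firing benign tier returns uncertain_significance.}
#' }
#' With no firing tier the classification is uncertain_significance.
#'
#' @param codes Character vector: one evidence-code set (e.g.
#'   `c("PM1", "PM2")`).
#' @param profile Conflict-resolution profile.
#' @return One of `"pathogenic"`, `"likely_pathogenic"`,
#'   `"uncertain_significance"`, `"likely_benign"`, `"benign"`.
#' @examples
#' acmg_classify(c("PM1", "PM2"))        # uncertain_significance
#' acmg_classify(c("PM2", "BP4", "BP7")) # likely_benign
#' @export
acmg_classify <- function(codes, profile = c("intervar_default", "strict_acmg")) {
  profile <- match.arg(profile)
  counts <- code_category_counts(codes)
  rules <- acmg_rule_table()
  fires <- vapply(seq_len(nrow(rules)), function(i) {
    all(counts >= unlist(rules[i, c("pvs", "ps", "pm", "pp", "ba", "bs", "bp")]))
  }, logical(1))
  tiers <- rules$tier[fires]
  path_tier <- if ("pathogenic" %in% tiers) "pathogenic"
               else if ("likely_pathogenic" %in% tiers) "likely_pathogenic"
               else NA_character_
  benign_tier <- if ("benign" %in% tiers) "benign"
                 else if ("likely_benign" %in% tiers) "likely_benign"
                 else NA_character_
  any_benign_evidence <- sum(counts[c("ba", "bs", "bp")]) > 0
  if (is.na(path_tier) && is.na(benign_tier)) return("uncertain_significance")
  if (profile == "strict_acmg") {
    if (!is.na(path_tier) && !is.na(benign_tier)) return("uncertain_significance")
    return(if (!is.na(path_tier)) path_tier else benign_tier)
  }
  # intervar_default
  if (!is.na(path_tier)) {
    if (any_benign_evidence) return("uncertain_significance")
    return(path_tier)
  }
  benign_tier
}

#' @rdname acmg_classify
#' @param code_sets A list of evidence-code character vectors.
#' @return For `acmg_classify_all`, a character vector of classifications.
#' @export
acmg_classify_all <- function(code_sets, profile = c("intervar_default", "strict_acmg")) {
  profile <- match.arg(profile)
  vapply(code_sets, acmg_classify, character(1), profile = profile)
}

#' Parse a comma-separated evidence-code string
#'
#' `"PM1, PM2"` -> `c("PM1", "PM2")`; empty / missing strings give an empty
#' set (which classifies as uncertain_significance).
#'
#' @param x Character vector of comma-separated code strings.
#' @return A list of code character vectors.
#' @export
parse_evidence_codes <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character())
    trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}
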