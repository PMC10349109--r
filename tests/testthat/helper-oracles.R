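# Independent brute-force oracles. These re-derive expected results by
# direct enumeration, in a style deliberately different from the package
# implementation (per-record loops and explicit booleans, no shared code).

oracle_screen <- function(tbl, cfg = screen_config()) {
  keep <- logical(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    ok_region <- !is.na(tbl$region[i]) && tbl$region[i] %in% cfg$allowed_regions
    ok_func <- !is.na(tbl$func_class[i]) && tbl$func_class[i] %in% cfg$allowed_func
    ok_maf <- TRUE
    for (db in cfg$maf_databases) {
      v <- tbl[[paste0("maf_", db)]][i]
      ok_db <- if (is.na(v)) cfg$missing_passes else v < cfg$maf_threshold
      if (!ok_db) ok_maf <- FALSE
    }
    keep[i] <- ok_region && ok_func && ok_maf
  }
  tbl[keep, , drop = FALSE]
}

# direct evaluation of the full boolean set expression, one variant at a time
oracle_hypothesis <- function(calls, manifest, hypothesis) {
  tumors <- manifest$sample_id[manifest$arm == "discovery" & manifest$tissue == "tumor"]
  pbmcs <- manifest$sample_id[manifest$arm == "discovery" & manifest$tissue == "pbmc"]
  normals <- manifest$sample_id[manifest$tissue == "normal_atrium"]
  ids <- variant_id_of(calls)
  out <- character()
  for (v in unique(ids)) {
    samples <- calls$sample_id[ids == v]
    in_all_tumors <- all(tumors %in% samples)
    in_all_pbmcs <- all(pbmcs %in% samples)
    in_any_pbmc <- any(pbmcs %in% samples)
    in_any_normal <- any(normals %in% samples)
    hit <- if (hypothesis == "hereditary") {
      in_all_tumors && in_all_pbmcs && !in_any_normal
    } else {
      in_all_tumors && !in_any_pbmc && !in_any_normal
    }
    if (hit) out <- c(out, v)
  }
  sort(out)
}

oracle_votes <- function(row, th = predictor_thresholds()) {
  n <- 0L
  if (!is.na(row$sift) && row$sift < th$sift_lt) n <- n + 1L
  if (!is.na(row$polyphen2) && row$polyphen2 %in% th$polyphen2_damaging) n <- n + 1L
  if (!is.na(row$phylop) && row$phylop > th$phylop_gt) n <- n + 1L
  if (!is.na(row$gerp) && row$gerp > th$gerp_gt) n <- n + 1L
  if (!is.na(row$mutationtaster) && row$mutationtaster %in% th$mutationtaster_damaging) n <- n + 1L
  if (!is.na(row$lrt) && row$lrt %in% th$lrt_damaging) n <- n + 1L
  n
}

# independent hand-coded ACMG/AMP 2015 combining table (intervar_default
# conflict handling), written as explicit conditions rather than a rule list
oracle_acmg <- function(codes) {
  codes <- unique(codes)
  pvs <- sum(codes == "PVS1")
  ps <- length(grep("^PS", codes))
  pm <- length(grep("^PM", codes))
  pp <- length(grep("^PP", codes))
  ba <- sum(codes == "BA1")
  bs <- length(grep("^BS", codes))
  bp <- length(grep("^BP", codes))

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm >= 1) ||
    (ps >= 1 && pm >= 1) ||
    (ps >= 1 && pp >= 2) ||
    pm >= 3 ||
    (pm >= 2 && pp >= 2) ||
    (pm >= 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs >= 1 && bp >= 1) || bp >= 2

  path_tier <- if (pathogenic) "pathogenic" else if (likely_pathogenic) "likely_pathogenic" else NA
  ben_tier <- if (benign) "benign" else if (likely_benign) "likely_benign" else NA
  if (is.na(path_tier) && is.na(ben_tier)) return("uncertain_significance")
  if (!is.na(path_tier)) {
    if (ba + bs + bp > 0) return("uncertain_significance")
    return(path_tier)
  }
  ben_tier
}

# small random cohorts for oracle-equivalence checks (independent of the
# package's own generator)
random_small_cohort <- function(n_variants = 30, n_extra_samples = 4) {
  manifest <- dplyr::bind_rows(
    tibble::tibble(sample_id = c("T1", "T2", "B1"),
                   patient_id = c("P1", "P2", "P2"),
                   tissue = c("tumor", "tumor", "pbmc"),
                   arm = "discovery"),
    tibble::tibble(sample_id = "NA1", patient_id = "PN1",
                   tissue = "normal_atrium", arm = "normal_control"),
    if (n_extra_samples > 0) {
      tibble::tibble(sample_id = paste0("V", seq_len(n_extra_samples)),
                     patient_id = paste0("PV", seq_len(n_extra_samples)),
                     tissue = "tumor", arm = "validation")
    })
  keys <- tibble::tibble(
    chrom = "chrS", pos = sample.int(1e6, n_variants),
    ref = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE))
  keys$alt <- vapply(keys$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                     character(1))
  rows <- list()
  for (i in seq_len(n_variants)) {
    samples <- manifest$sample_id[runif(nrow(manifest)) < 0.5]
    for (s in samples) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = s, chrom = keys$chrom[i], pos = keys$pos[i],
        ref = keys$ref[i], alt = keys$alt[i], zygosity = "Het",
        gene = paste0("G", i), region = "exonic", func_class = "nonsynonymous")
    }
  }
  calls <- dplyr::bind_rows(rows)
  list(manifest = manifest, calls = calls)
}

random_scores <- function(n) {
  tibble::tibble(
    sift = ifelse(runif(n) < 0.2, NA_real_, runif(n)),
    polyphen2 = ifelse(runif(n) < 0.2, NA_character_,
                       sample(c("D", "P", "B"), n, replace = TRUE)),
    phylop = ifelse(runif(n) < 0.2, NA_real_, runif(n, -3, 3)),
    gerp = ifelse(runif(n) < 0.2, NA_real_, runif(n, -5, 7)),
    mutationtaster = ifelse(runif(n) < 0.2, NA_character_,
                            sample(c("A", "D", "N", "P"), n, replace = TRUE)),
    lrt = ifelse(runif(n) < 0.2, NA_character_,
                 sample(c("D", "N", "U"), n, replace = TRUE)))
}

# minimal valid variant table for I/O tests
make_variant_table <- function(n = 10) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  tibble::tibble(
    sample_id = sample(c("S1", "S2", "S3"), n, replace = TRUE),
    chrom = sample(c("1", "17", "chrS"), n, replace = TRUE),
    pos = sample.int(1e7, n),
    ref = ref, alt = unname(alt),
    zygosity = sample(c("Het", "Hom"), n, replace = TRUE),
    gene = paste0("GENE", seq_len(n)),
    region = sample(c("exonic", "splicing", "intronic"), n, replace = TRUE),
    func_class = sample(c("nonsynonymous", "synonymous", "stopgain"), n, replace = TRUE),
    maf_1000g2015Aug_eas = ifelse(runif(n) < 0.5, NA, round(runif(n, 0, 0.01), 6)),
    maf_esp6500siv2_all = ifelse(runif(n) < 0.5, NA, round(runif(n, 0, 0.01), 6)),
    maf_exac03 = ifelse(runif(n) < 0.5, NA, round(runif(n, 0, 0.01), 6)),
    sift = ifelse(runif(n) < 0.3, NA, round(runif(n), 4)),
    polyphen2 = ifelse(runif(n) < 0.3, NA, sample(c("D", "P", "B"), n, replace = TRUE)),
    phylop = ifelse(runif(n) < 0.3, NA, round(runif(n, -3, 3), 3)),
    gerp = ifelse(runif(n) < 0.3, NA, round(runif(n, -5, 7), 3)),
    mutationtaster = ifelse(runif(n) < 0.3, NA, sample(c("A", "D", "N", "P"), n, replace = TRUE)),
    lrt = ifelse(runif(n) < 0.3, NA, sample(c("D", "N", "U"), n, replace = TRUE)),
    hgvs_c = ifelse(runif(n) < 0.5, NA, paste0("c.", seq_len(n), "A>G")),
    hgvs_p = NA_character_)
}
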