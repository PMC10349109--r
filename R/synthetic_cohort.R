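# Seed-deterministic synthetic cohort generator with planted ground truth.
#
# Emulates the post-annotation data the triage consumes: a discovery arm of
# two tumor patients (one with a germline-representative PBMC sample), three
# normal atrial tissues, a sporadic validation arm, and two lab-control
# exomes; planted hereditary and somatic causal variants, recurrent
# cross-patient artifacts, a common-variant background with a realistic MAF
# spectrum and missingness, predictor scores straddling the damaging
# thresholds, and an RPKM expression table in which planted genes are
# credibly expressed in normal tissue and decreased in tumors.
#
# Each artifact class draws from its own RNG stream derived from the master
# seed, so adding classes does not perturb existing output.

#' Simulation configuration
#'
#' Defaults mirror the study design: 2 discovery tumor patients (D1, D2)
#' with a PBMC sample for D2, 3 normal atrial tissues, 26 sporadic
#' validation patients and 2 lab-control exomes, with a desk-scale
#' background of 1000 variants.
#'
#' @param seed Master seed; identical configuration implies byte-identical
#'   output files.
#' @param n_background_variants Variants violating at least one screening
#'   condition (region, function or MAF) at the configured rates.
#' @param n_common_variants Variants with MAF >= 0.001 in at least one
#'   database, widespread across samples (and hence in the lab controls).
#' @param n_systematic_artifacts Screen-passing variants that mimic the
#'   hereditary presence pattern but recur in >= 2 validation patients.
#' @param n_planted_hereditary Causal germline variants: present in all
#'   discovery tumors and PBMCs, absent elsewhere, screen-passing, >= 4
#'   damaging votes, credibly expressed gene with a case decrease.
#' @param n_planted_somatic Causal tumor-only variants.
#' @param n_validation_patients Sporadic validation patients (one tumor each).
#' @param n_normal_atrium Normal atrial tissue samples (>= 1 required).
#' @param n_lab_controls Lab-control PBMC exomes.
#' @param maf_spectrum List: `p_missing` (per-database point mass of
#'   missingness for rare variants), `common_shape1`, `common_shape2`
#'   (Beta parameters of the common-variant frequency spectrum above the
#'   screening threshold).
#' @param predictor_noise List: `p_missing` (per-predictor missingness),
#'   `p_stray_damaging` (chance a non-causal variant's predictor takes a
#'   damaging value, so scores straddle the thresholds).
#' @param expression_params List: `middle_range` (control-side RPKM range
#'   for planted genes), `planted_percent_change` (case change for planted
#'   genes; -66 is the study's average decrease), `noise_cv` (lognormal
#'   coefficient of variation per sample), `n_background_genes`.
#' @param background_rates List of violation probabilities `p_region_fail`,
#'   `p_func_fail`, `p_maf_fail` (at least one violation is enforced).
#' @param multi_variant_genes If TRUE, planted hereditary variants share one
#'   gene (the two-variants-in-one-gene pattern); default gives each
#'   planted variant its own gene.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_background_variants = 1000L,
                       n_common_variants = 100L,
                       n_systematic_artifacts = 10L,
                       n_planted_hereditary = 2L,
                       n_planted_somatic = 0L,
                       n_validation_patients = 26L,
                       n_normal_atrium = 3L,
                       n_lab_controls = 2L,
                       maf_spectrum = list(p_missing = 0.3,
                                           common_shape1 = 0.5,
                                           common_shape2 = 20),
                       predictor_noise = list(p_missing = 0.1,
                                              p_stray_damaging = 0.15),
                       expression_params = list(middle_range = c(20, 80),
                                                planted_percent_change = -66,
                                                noise_cv = 0.05,
                                                n_background_genes = 50L),
                       background_rates = list(p_region_fail = 0.35,
                                               p_func_fail = 0.35,
                                               p_maf_fail = 0.5),
                       multi_variant_genes = FALSE) {
  counts <- c(n_background_variants, n_common_variants, n_systematic_artifacts,
              n_planted_hereditary, n_planted_somatic, n_validation_patients,
              n_lab_controls)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (n_normal_atrium < 1) {
    stop("infeasible config: at least one normal atrial sample is required",
         call. = FALSE)
  }
  if (n_systematic_artifacts > 0 && n_validation_patients < 2) {
    stop("infeasible config: systematic artifacts need >= 2 validation patients",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  structure(as.list(environment()), class = "sim_config")
}

# independent stream per artifact class
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 7919) %% 2147483399
}

default_manifest <- function(cfg) {
  dplyr::bind_rows(
    tibble::tibble(sample_id = c("D1_T", "D2_T", "D2_B"),
                   patient_id = c("D1", "D2", "D2"),
                   tissue = c("tumor", "tumor", "pbmc"),
                   arm = "discovery"),
    tibble::tibble(sample_id = paste0("N", seq_len(cfg$n_normal_atrium)),
                   patient_id = paste0("PN", seq_len(cfg$n_normal_atrium)),
                   tissue = "normal_atrium",
                   arm = "normal_control"),
    if (cfg$n_validation_patients > 0) {
      tibble::tibble(sample_id = paste0("V", seq_len(cfg$n_validation_patients), "_T"),
                     patient_id = paste0("V", seq_len(cfg$n_validation_patients)),
                     tissue = "tumor",
                     arm = "validation")
    },
    if (cfg$n_lab_controls > 0) {
      tibble::tibble(sample_id = paste0("LC", seq_len(cfg$n_lab_controls)),
                     patient_id = paste0("LC", seq_len(cfg$n_lab_controls)),
                     tissue = "pbmc",
                     arm = "lab_control")
    }
  )
}

rare_maf_draw <- function(n, p_missing) {
  # heavy concentration near zero, always below the 0.001 screen threshold,
  # with a point mass of missingness per database
  v <- 10^stats::runif(n, -6, log10(9.9e-4))
  v[stats::runif(n) < p_missing] <- NA_real_
  v
}

common_maf_draw <- function(n, spec) {
  0.001 + stats::rbeta(n, spec$common_shape1, spec$common_shape2) * 0.5
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  tibble::tibble(ref = ref, alt = unname(alt))
}

damaging_scores <- function(n, p_missing, max_missing = 2L) {
  out <- tibble::tibble(
    sift = stats::runif(n, 0, 0.099),
    polyphen2 = sample(c("D", "P"), n, replace = TRUE, prob = c(0.8, 0.2)),
    phylop = stats::runif(n, 1, 3),
    gerp = stats::runif(n, 4.05, 6),
    mutationtaster = sample(c("A", "D"), n, replace = TRUE),
    lrt = rep("D", n))
  # predictor dropout, capped so the consensus (>= 4 of 6) always holds
  for (i in seq_len(n)) {
    miss <- which(stats::runif(6) < p_missing)
    if (length(miss) > max_missing) miss <- miss[seq_len(max_missing)]
    for (j in miss) out[i, j] <- if (j %in% c(1, 3, 4)) NA_real_ else NA_character_
  }
  out
}

noise_scores <- function(n, noise) {
  damaging <- function(k) stats::runif(n) < noise$p_stray_damaging
  miss <- function() stats::runif(n) < noise$p_missing
  sift <- ifelse(damaging(), stats::runif(n, 0, 0.099), stats::runif(n, 0.15, 1))
  pp2 <- ifelse(damaging(), sample(c("D", "P"), n, replace = TRUE), "B")
  phylop <- ifelse(damaging(), stats::runif(n, 0.96, 3), stats::runif(n, -2, 0.94))
  gerp <- ifelse(damaging(), stats::runif(n, 4.05, 6), stats::runif(n, -3, 3.9))
  mt <- ifelse(damaging(), sample(c("A", "D"), n, replace = TRUE),
               sample(c("N", "P"), n, replace = TRUE))
  lrt <- ifelse(damaging(), "D", sample(c("N", "U"), n, replace = TRUE))
  sift[miss()] <- NA_real_; pp2[miss()] <- NA_character_
  phylop[miss()] <- NA_real_; gerp[miss()] <- NA_real_
  mt[miss()] <- NA_character_; lrt[miss()] <- NA_character_
  tibble::tibble(sift = sift, polyphen2 = pp2, phylop = phylop, gerp = gerp,
                 mutationtaster = mt, lrt = lrt)
}

screen_passing_annotation <- function(n, p_missing) {
  tibble::tibble(
    region = sample(c("exonic", "splicing"), n, replace = TRUE, prob = c(0.9, 0.1)),
    func_class = sample(c("nonsynonymous", "frameshift", "stopgain", "unknown"),
                        n, replace = TRUE, prob = c(0.8, 0.08, 0.07, 0.05)),
    maf_1 = rare_maf_draw(n, p_missing),
    maf_2 = rare_maf_draw(n, p_missing),
    maf_3 = rare_maf_draw(n, p_missing))
}

#' Generate a synthetic annotated cohort with planted truth
#'
#' Produces everything the triage pipeline consumes plus the ground-truth
#' labels it should recover: a manifest, per-sample annotated calls, a lab
#' control-variant database (the variants observed in the lab-control
#' samples), a gene-level expression table, and `truth` (pairwise-disjoint
#' sets of hereditary, somatic, artifact and common variant keys). By
#' construction, planted hereditary variants pass every screening condition
#' and survive triage, artifacts are removed at the systematic-error stage,
#' and common/background variants never reach the candidate set.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `manifest`, `calls`, `control_db`,
#'   `expression`, `truth`, `config`.
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  manifest <- default_manifest(cfg)
  n_total <- cfg$n_background_variants + cfg$n_common_variants +
    cfg$n_systematic_artifacts + cfg$n_planted_hereditary + cfg$n_planted_somatic

  set.seed(derive_seed(cfg$seed, 1))  # stream 1: variant keys and classes
  pos <- sort(sample.int(5e7, n_total))
  alleles <- random_alleles(n_total)
  class_vec <- rep(c("hereditary", "somatic", "artifact", "common", "background"),
                   times = c(cfg$n_planted_hereditary, cfg$n_planted_somatic,
                             cfg$n_systematic_artifacts, cfg$n_common_variants,
                             cfg$n_background_variants))
  variants <- tibble::tibble(chrom = "chrS", pos = pos,
                             ref = alleles$ref, alt = alleles$alt,
                             class = sample(class_vec))
  variants$vid <- variant_id_of(variants)
  idx <- split(seq_len(n_total), variants$class)
  gene <- character(n_total)
  gene[idx$hereditary %||% integer()] <-
    if (isTRUE(cfg$multi_variant_genes)) "GENE_H1" else
      paste0("GENE_H", seq_along(idx$hereditary %||% integer()))
  gene[idx$somatic %||% integer()] <- paste0("GENE_S", seq_along(idx$somatic %||% integer()))
  gene[idx$artifact %||% integer()] <- paste0("GENE_A", seq_along(idx$artifact %||% integer()))
  gene[idx$common %||% integer()] <- paste0("GENE_C", seq_along(idx$common %||% integer()))
  nb <- length(idx$background %||% integer())
  if (nb) gene[idx$background] <- sprintf("GENE_B%04d", sample.int(max(1L, nb %/% 3L), nb, replace = TRUE))
  variants$gene <- gene

  set.seed(derive_seed(cfg$seed, 2))  # stream 2: annotations and MAFs
  ann <- screen_passing_annotation(n_total, cfg$maf_spectrum$p_missing)
  bg <- idx$background %||% integer()
  if (length(bg)) {
    r <- cfg$background_rates
    fail_region <- stats::runif(length(bg)) < r$p_region_fail
    fail_func <- stats::runif(length(bg)) < r$p_func_fail
    fail_maf <- stats::runif(length(bg)) < r$p_maf_fail
    none <- !(fail_region | fail_func | fail_maf)
    fail_maf[none] <- TRUE  # every background variant violates >= 1 condition
    ann$region[bg[fail_region]] <- sample(c("intronic", "UTR3", "UTR5", "intergenic"),
                                          sum(fail_region), replace = TRUE)
    ann$func_class[bg[fail_func]] <- "synonymous"
    if (any(fail_maf)) {
      db_pick <- sample.int(3, sum(fail_maf), replace = TRUE)
      high <- common_maf_draw(sum(fail_maf), cfg$maf_spectrum)
      for (d in 1:3) {
        sel <- bg[fail_maf][db_pick == d]
        ann[[paste0("maf_", d)]][sel] <- high[db_pick == d]
      }
    }
  }
  cm <- idx$common %||% integer()
  if (length(cm)) {
    db_pick <- sample.int(3, length(cm), replace = TRUE)
    high <- common_maf_draw(length(cm), cfg$maf_spectrum)
    for (d in 1:3) {
      sel <- cm[db_pick == d]
      ann[[paste0("maf_", d)]][sel] <- high[db_pick == d]
    }
  }
  names(ann)[match(paste0("maf_", 1:3), names(ann))] <- maf_col(DEFAULT_MAF_DATABASES)
  variants <- dplyr::bind_cols(variants, ann)

  set.seed(derive_seed(cfg$seed, 3))  # stream 3: predictor scores
  planted <- c(idx$hereditary %||% integer(), idx$somatic %||% integer())
  scores <- noise_scores(n_total, cfg$predictor_noise)
  if (length(planted)) {
    scores[planted, ] <- damaging_scores(length(planted),
                                         cfg$predictor_noise$p_missing)
  }
  variants <- dplyr::bind_cols(variants, scores)
  variants$hgvs_c <- NA_character_
  variants$hgvs_p <- NA_character_

  set.seed(derive_seed(cfg$seed, 4))  # stream 4: presence patterns
  tumors <- sample_ids_for(manifest, arm = "discovery", tissue = "tumor")
  pbmcs <- sample_ids_for(manifest, arm = "discovery", tissue = "pbmc")
  normals <- sample_ids_for(manifest, tissue = "normal_atrium")
  validation <- sample_ids_for(manifest, arm = "validation")
  labs <- sample_ids_for(manifest, arm = "lab_control")
  all_samples <- manifest$sample_id
  presence <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    presence[[i]] <- switch(variants$class[i],
      hereditary = c(tumors, pbmcs),
      somatic = tumors,
      artifact = c(tumors, pbmcs,
                   sample(validation, min(length(validation),
                                          sample(2:5, 1L)))),
      common = {
        s <- all_samples[stats::runif(length(all_samples)) < 0.7]
        unique(c(s, labs[1]))  # common variants are seen in the lab controls
      },
      background = all_samples[stats::runif(length(all_samples)) < 0.15])
  }
  zyg <- sample(c("Het", "Hom"), n_total, replace = TRUE, prob = c(0.9, 0.1))
  reps <- lengths(presence)
  calls <- variants[rep(seq_len(n_total), reps), ]
  calls$sample_id <- unlist(presence)
  calls$zygosity <- rep(zyg, reps)
  calls <- calls[, c("sample_id", setdiff(canonical_columns(), "sample_id"),
                     "vid", "class")]
  calls <- calls[order(calls$sample_id, calls$chrom, calls$pos,
                       calls$ref, calls$alt), ]
  truth <- list(hereditary = sort(variants$vid[idx$hereditary %||% integer()]),
                somatic = sort(variants$vid[idx$somatic %||% integer()]),
                artifacts = sort(variants$vid[idx$artifact %||% integer()]),
                common = sort(variants$vid[idx$common %||% integer()]))
  control_db <- sort(unique(calls$vid[calls$sample_id %in% labs]))

  set.seed(derive_seed(cfg$seed, 5))  # stream 5: expression
  expression <- generate_expression(cfg, variants, manifest)

  out_calls <- calls[, c("sample_id", setdiff(canonical_columns(), "sample_id"))]
  list(manifest = manifest,
       calls = validate_variant_table(tibble::as_tibble(out_calls)),
       control_db = control_db,
       expression = expression,
       truth = truth,
       config = cfg)
}

generate_expression <- function(cfg, variants, manifest) {
  ep <- cfg$expression_params
  planted_genes <- unique(variants$gene[variants$class %in% c("hereditary", "somatic")])
  bg_pool <- unique(variants$gene[variants$class == "background"])
  bg_genes <- utils::head(bg_pool, ep$n_background_genes)
  genes <- c(planted_genes, bg_genes)
  cases <- sample_ids_for(manifest, arm = "discovery", tissue = "tumor")
  controls <- sample_ids_for(manifest, tissue = "normal_atrium")
  samples <- c(cases, controls)
  total_mapped <- stats::setNames(round(stats::runif(length(samples), 1.8e7, 2.2e7)),
                                  samples)
  base <- ifelse(genes %in% planted_genes,
                 stats::runif(length(genes), ep$middle_range[1], ep$middle_range[2]),
                 10^stats::runif(length(genes), -1, 2.7))
  lengths_bp <- sample(500:5000, length(genes), replace = TRUE)
  fold <- 1 + ep$planted_percent_change / 100
  rows <- list()
  for (gi in seq_along(genes)) {
    for (s in samples) {
      mu <- base[gi] * (if (s %in% cases && genes[gi] %in% planted_genes) fold else 1)
      rpkm_target <- mu * exp(stats::rnorm(1, 0, ep$noise_cv))
      count <- round(rpkm_target * lengths_bp[gi] * total_mapped[[s]] / 1e9)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = genes[gi], sample_id = s, read_count = count,
        gene_length_bp = lengths_bp[gi], total_mapped_reads = total_mapped[[s]])
    }
  }
  expr <- dplyr::bind_rows(rows)
  expr$rpkm <- compute_rpkm(expr$read_count, expr$gene_length_bp,
                            expr$total_mapped_reads)
  expr
}

#' Write a generated cohort to plain-text files
#'
#' Emits `manifest.tsv`, `calls.tsv` (annovar_tsv dialect),
#' `control_db.tsv`, `expression.tsv` and `truth.json` under `dir`. All
#' writers are deterministic, so identical configurations give
#' byte-identical trees.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  write_variant_table(cohort$calls, file.path(dir, "calls.tsv"), "annovar_tsv")
  con <- file(file.path(dir, "control_db.tsv"), open = "wb")
  writeLines(c("variant_id", cohort$control_db), con, sep = "\n")
  close(con)
  con <- file(file.path(dir, "expression.tsv"), open = "wb")
  writeLines(c(paste(names(cohort$expression), collapse = "\t"),
               do.call(paste, c(lapply(cohort$expression, function(v)
                 vapply(v, function(x) if (is.numeric(x)) format(x, digits = 17, scientific = NA)
                        else as.character(x), character(1))), sep = "\t"))),
             con, sep = "\n")
  close(con)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Worked-example fixture: the five published coding variants
#'
#' Builds, in code, the regression fixture mirroring the published table of
#' rare variants in the candidate gene's consensus coding sequence: HGVS
#' labels, zygosity, the printed ExAC frequencies (3.4e-5, 4.9e-5,
#' 1.265e-3, and absent for two variants), the printed evidence-code sets,
#' and the printed five-tier classifications. Genomic coordinates are
#' synthetic placeholders (position = cDNA coordinate); identity is carried
#' by `hgvs_c`.
#'
#' @return A tibble with one row per variant: variant key fields, `gene`,
#'   `region`, `func_class`, MAF columns, `zygosity`, `hgvs_c`, `hgvs_p`,
#'   `evidence` (comma-separated codes) and `reported_classification`.
#' @export
generate_worked_example <- function() {
  tbl <- tibble::tibble(
    sample_id = c("D2_T", "D1_T", "V16_T", "V7_T", "V7_T"),
    chrom = "17",
    pos = c(772L, 899L, 352L, 2895L, 3049L),
    ref = c("T", "A", "A", "C", "G"),
    alt = c("G", "T", "T", "T", "A"),
    zygosity = c("Het", "Het", "Het", "Het", "Hom"),
    gene = "KIF1C",
    region = "exonic",
    func_class = c("nonsynonymous", "nonsynonymous", "nonsynonymous",
                   "synonymous", "nonsynonymous"),
    maf_1000g2015Aug_eas = NA_real_,
    maf_esp6500siv2_all = NA_real_,
    maf_exac03 = c(3.4e-5, 4.9e-5, NA, NA, 1.265e-3),
    sift = NA_real_, polyphen2 = NA_character_, phylop = NA_real_,
    gerp = NA_real_, mutationtaster = NA_character_, lrt = NA_character_,
    hgvs_c = c("c.772T>G", "c.899A>T", "c.352A>T", "c.2895C>T", "c.3049G>A"),
    hgvs_p = c("p.Ser258Ala", "p.Tyr300Phe", "p.Ile118Phe", "p.Pro965Pro",
               "p.Ala1017Thr"),
    evidence = c("PM1,PM2", "PM1,PM2,PP3", "PM1,PM2,PP3", "PM2,BP4,BP7",
                 "BS1,BP4"),
    reported_classification = c("uncertain_significance",
                                "uncertain_significance",
                                "uncertain_significance",
                                "likely_benign", "likely_benign"))
  tbl
}
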