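# Cross-sample set logic: hereditary / somatic candidate derivation,
# recurrent-artifact ("systematic error") elimination, control-database
# subtraction, and gene/locus summarization.
#
# Variant identity throughout is the normalized key from variant_id();
# zygosity is deliberately ignored by presence/absence logic and carried
# through to reports only.

sample_ids_for <- function(manifest, arm = NULL, tissue = NULL) {
  keep <- rep(TRUE, nrow(manifest))
  if (!is.null(arm)) keep <- keep & manifest$arm %in% arm
  if (!is.null(tissue)) keep <- keep & manifest$tissue %in% tissue
  manifest$sample_id[keep]
}

require_roles <- function(manifest) {
  missing <- character()
  if (!length(sample_ids_for(manifest, arm = "discovery", tissue = "tumor"))) {
    missing <- c(missing, "discovery tumor")
  }
  if (!length(sample_ids_for(manifest, arm = "discovery", tissue = "pbmc"))) {
    missing <- c(missing, "discovery pbmc")
  }
  if (!length(sample_ids_for(manifest, tissue = "normal_atrium"))) {
    missing <- c(missing, "normal_atrium")
  }
  if (length(missing)) {
    stop("manifest is missing required sample role(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(manifest)
}

# variant_id -> set of sample_ids carrying it
presence_sets <- function(calls) {
  ids <- variant_id_of(calls)
  split(calls$sample_id, ids)
}

hypothesis_candidates <- function(calls, manifest, pbmc_required,
                                  tumor_presence = c("all", "any")) {
  tumor_presence <- match.arg(tumor_presence)
  manifest <- validate_manifest(manifest)
  require_roles(manifest)
  tumors <- sample_ids_for(manifest, arm = "discovery", tissue = "tumor")
  pbmcs <- sample_ids_for(manifest, arm = "discovery", tissue = "pbmc")
  normals <- sample_ids_for(manifest, tissue = "normal_atrium")
  pres <- presence_sets(calls)
  keep <- vapply(pres, function(samples) {
    in_tumor <- if (tumor_presence == "all") all(tumors %in% samples) else any(tumors %in% samples)
    in_pbmc <- all(pbmcs %in% samples)
    no_pbmc <- !any(pbmcs %in% samples)
    no_normal <- !any(normals %in% samples)
    in_tumor && no_normal && (if (pbmc_required) in_pbmc else no_pbmc)
  }, logical(1))
  sort(names(pres)[keep])
}

#' Hereditary-hypothesis candidates
#'
#' Variants present in every discovery tumor sample AND in every discovery
#' PBMC sample (germline-representative blood) AND absent from every normal
#' atrial tissue sample. This is the set expression that retained the
#' study's germline candidates.
#'
#' @param calls A variant table of per-sample calls.
#' @param manifest A cohort manifest (see [read_manifest()]).
#' @param tumor_presence `"all"` (default) requires presence in every
#'   discovery tumor; `"any"` relaxes to at least one.
#' @return Sorted character vector of variant keys.
#' @export
hereditary_candidates <- function(calls, manifest, tumor_presence = c("all", "any")) {
  hypothesis_candidates(calls, manifest, pbmc_required = TRUE,
                        tumor_presence = tumor_presence)
}

#' Somatic-hypothesis candidates
#'
#' Variants present in every discovery tumor sample but in NO discovery PBMC
#' sample and NO normal atrial tissue sample (tumor-acquired). On any cohort
#' with at least one PBMC sample this set is disjoint from
#' [hereditary_candidates()].
#'
#' @inheritParams hereditary_candidates
#' @return Sorted character vector of variant keys.
#' @export
somatic_candidates <- function(calls, manifest, tumor_presence = c("all", "any")) {
  hypothesis_candidates(calls, manifest, pbmc_required = FALSE,
                        tumor_presence = tumor_presence)
}

#' Eliminate systematic errors (recurrent cross-patient artifacts)
#'
#' A candidate is treated as a platform artifact — the same variant at the
#' same locus in different unrelated sporadic patients — when it is observed
#' in at least `min_patients` distinct patients of the sporadic (validation)
#' arm. Such candidates are removed. `arms` widens the arms whose patients
#' are counted; the sporadic-patient default is the study's definition
#' (discovery patients are expected to share a hereditary variant and must
#' not count against it).
#'
#' @param candidates Character vector of variant keys.
#' @param calls A variant table of per-sample calls for the whole cohort.
#' @param manifest A cohort manifest.
#' @param min_patients Minimum number of distinct recurrent patients (>= 2).
#' @param arms Cohort arms whose patients are counted for recurrence.
#' @return The retained subset of `candidates`, sorted.
#' @export
remove_systematic_errors <- function(candidates, calls, manifest,
                                     min_patients = 2L,
                                     arms = "validation") {
  if (min_patients < 2L) stop("min_patients must be >= 2", call. = FALSE)
  manifest <- validate_manifest(manifest)
  samples <- sample_ids_for(manifest, arm = arms)
  sub <- calls[calls$sample_id %in% samples, , drop = FALSE]
  if (!nrow(sub)) return(sort(candidates))
  patient_of <- stats::setNames(manifest$patient_id, manifest$sample_id)
  ids <- variant_id_of(sub)
  n_patients <- vapply(split(patient_of[sub$sample_id], ids),
                       function(p) length(unique(p)), integer(1))
  artifacts <- names(n_patients)[n_patients >= min_patients]
  sort(setdiff(candidates, artifacts))
}

#' Subtract a control variant database
#'
#' Removes candidates present in the lab control database (e.g. exomes of
#' normal subjects without heart disease). Matching is by exact normalized
#' variant key.
#'
#' @param candidates Character vector of variant keys.
#' @param control_db Character vector of variant keys, or a variant table
#'   from which keys are derived.
#' @return `candidates \ control_db`, sorted.
#' @export
subtract_control_db <- function(candidates, control_db) {
  if (is.data.frame(control_db)) control_db <- variant_id_of(control_db)
  sort(setdiff(candidates, control_db))
}

#' Summarize surviving candidates into genes and loci
#'
#' Builds a `candidate_set`: the surviving variant keys, their gene symbols,
#' and a provenance ledger of how many variants each stage removed (the
#' study reports this shape as "n candidate genes and m loci").
#'
#' @param candidates Character vector of variant keys.
#' @param annotations A variant table supplying `gene` per variant key.
#' @param hypothesis `"hereditary"` or `"somatic"`.
#' @param provenance Optional tibble with columns `stage`, `n_removed`.
#' @return A `candidate_set` object.
#' @export
summarize_candidates <- function(candidates, annotations,
                                 hypothesis = c("hereditary", "somatic"),
                                 provenance = NULL) {
  hypothesis <- match.arg(hypothesis)
  gene_of <- annotations |>
    dplyr::mutate(.id = variant_id_of(annotations)) |>
    dplyr::distinct(.data$.id, .data$gene)
  lookup <- stats::setNames(gene_of$gene, gene_of$.id)
  genes <- lookup[candidates]
  if (any(is.na(genes)) || any(!candidates %in% names(lookup))) {
    bad <- candidates[!candidates %in% names(lookup) | is.na(genes)]
    stop("unannotated candidate variant(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(hypothesis = hypothesis,
                 variants = sort(unname(candidates)),
                 genes = sort(unique(unname(genes))),
                 n_loci = length(unique(candidates)),
                 n_genes = length(unique(genes)),
                 provenance = provenance %||%
                   tibble::tibble(stage = character(), n_removed = integer())),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set: %s hypothesis>\n", x$hypothesis))
  cat(sprintf("  %d candidate gene(s) and %d locus/loci\n", x$n_genes, x$n_loci))
  if (x$n_genes) cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  if (nrow(x$provenance)) {
    cat("  provenance:\n")
    for (i in seq_len(nrow(x$provenance))) {
      cat(sprintf("    %-24s -%d\n", x$provenance$stage[i], x$provenance$n_removed[i]))
    }
  }
  invisible(x)
}

#' Staged candidate triage for one hypothesis
#'
#' Runs the full cross-sample stage order on screened calls: hypothesis set
#' logic, systematic-error elimination, then control-database subtraction,
#' recording a provenance ledger. All stages are intersections/differences
#' on disjoint criteria, so the final set is order-independent.
#'
#' @param screened_calls Variant table after [preliminary_screen()].
#' @param manifest Cohort manifest.
#' @param hypothesis `"hereditary"` or `"somatic"`.
#' @param control_db Variant keys (or table) of the lab control database.
#' @param min_patients Recurrence threshold for [remove_systematic_errors()].
#' @param arms Arms counted for recurrence.
#' @param tumor_presence Passed to the hypothesis set logic.
#' @return A `candidate_set`.
#' @export
triage_candidates <- function(screened_calls, manifest,
                              hypothesis = c("hereditary", "somatic"),
                              control_db = character(),
                              min_patients = 2L,
                              arms = "validation",
                              tumor_presence = c("all", "any")) {
  hypothesis <- match.arg(hypothesis)
  fn <- if (hypothesis == "hereditary") hereditary_candidates else somatic_candidates
  s0 <- fn(screened_calls, manifest, tumor_presence = tumor_presence)
  s1 <- remove_systematic_errors(s0, screened_calls, manifest,
                                 min_patients = min_patients, arms = arms)
  s2 <- subtract_control_db(s1, control_db)
  prov <- tibble::tibble(
    stage = c("hypothesis_set_logic", "systematic_errors", "control_db"),
    n_removed = c(length(unique(variant_id_of(screened_calls))) - length(s0),
                  length(s0) - length(s1),
                  length(s1) - length(s2)))
  summarize_candidates(s2, screened_calls, hypothesis, provenance = prov)
}
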