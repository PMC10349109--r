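# End-to-end orchestration: simulate (or read) -> preliminary screen ->
# hypothesis triage -> consensus pathogenicity -> expression gate, with a
# provenance ledger, fail-closed configuration parsing, and plain-text
# reporting.

pipeline_keys <- function() {
  list(
    seed = "integer",
    hypothesis = c("hereditary", "somatic", "both"),
    min_patients_systematic = "integer",
    systematic_arms = "character",
    tumor_presence = c("all", "any"),
    output_dir = "character",
    sim = names(formals(sim_config)),
    screen = names(formals(screen_config)),
    thresholds = names(formals(predictor_thresholds)),
    expression = c("min_bin", "aggregate", "change"),
    inputs = c("calls", "manifest", "control_db", "expression")
  )
}

suggest_key <- function(key, known) {
  hit <- known[which.min(utils::adist(key, known, ignore.case = TRUE))]
  if (length(hit) && utils::adist(key, hit, ignore.case = TRUE) <= 3) {
    paste0(" (did you mean \"", hit, "\"?)")
  } else ""
}

check_keys <- function(x, known, path) {
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown config key ", path, unknown[1],
         suggest_key(unknown[1], known), call. = FALSE)
  }
  invisible(x)
}

#' Validate a pipeline configuration
#'
#' Parses YAML/JSON text, a file path, or an R list into a validated
#' `pipeline_config` with all defaults applied. Parsing is fail-closed:
#' unknown keys raise an error (with a nearest-key suggestion) rather than
#' being silently ignored, because a silently misspelled filter setting
#' would invalidate the triage. Defaults encode the study conditions: MAF
#' threshold 0.001, consensus at >= 4 of 6 predictors, recurrence in >= 2
#' sporadic patients.
#'
#' @param raw NULL (all defaults), an R list, a path to a YAML/JSON file,
#'   or YAML text.
#' @return A `pipeline_config` list.
#' @export
validate_config <- function(raw = NULL) {
  x <- if (is.null(raw)) {
    list()
  } else if (is.list(raw)) {
    raw
  } else if (is.character(raw) && length(raw) == 1L) {
    if (file.exists(raw)) yaml::read_yaml(raw) else yaml::yaml.load(raw)
  } else {
    stop("config must be a list, a file path, or YAML/JSON text", call. = FALSE)
  }
  if (is.null(x)) x <- list()
  keys <- pipeline_keys()
  check_keys(x, names(keys), "")
  for (sect in c("sim", "screen", "thresholds", "expression", "inputs")) {
    if (!is.null(x[[sect]])) {
      check_keys(x[[sect]], keys[[sect]], paste0(sect, "."))
    }
  }
  if (!is.null(x$hypothesis)) {
    x$hypothesis <- match.arg(x$hypothesis, keys$hypothesis)
  }
  if (!is.null(x$min_patients_systematic) && x$min_patients_systematic < 2) {
    stop("min_patients_systematic must be >= 2", call. = FALSE)
  }
  sim_args <- x$sim %||% list()
  if (!is.null(x$seed)) sim_args$seed <- x$seed
  cfg <- list(
    seed = as.integer(x$seed %||% 1L),
    hypothesis = x$hypothesis %||% "both",
    min_patients_systematic = as.integer(x$min_patients_systematic %||% 2L),
    systematic_arms = x$systematic_arms %||% "validation",
    tumor_presence = x$tumor_presence %||% "all",
    output_dir = x$output_dir,
    sim = do.call(sim_config, sim_args),
    screen = do.call(screen_config, x$screen %||% list()),
    thresholds = do.call(predictor_thresholds, x$thresholds %||% list()),
    expression = utils::modifyList(list(min_bin = "middle", aggregate = "mean",
                                        change = "percent_of_aggregates"),
                                   x$expression %||% list()),
    inputs = x$inputs
  )
  structure(cfg, class = "pipeline_config")
}

load_pipeline_inputs <- function(cfg) {
  if (is.null(cfg$inputs)) {
    return(generate_cohort(cfg$sim))
  }
  inp <- cfg$inputs
  cohort <- list(
    manifest = read_manifest(inp$manifest),
    calls = read_variant_table(inp$calls, "annovar_tsv"),
    control_db = if (!is.null(inp$control_db)) {
      readr::read_tsv(inp$control_db, col_types = "c", progress = FALSE)$variant_id
    } else character(),
    expression = if (!is.null(inp$expression)) {
      readr::read_tsv(inp$expression, show_col_types = FALSE, progress = FALSE)
    },
    truth = NULL)
  cohort
}

triage_one_hypothesis <- function(cohort, screened, cfg, hypothesis) {
  cs <- triage_candidates(screened, cohort$manifest, hypothesis,
                          control_db = cohort$control_db,
                          min_patients = cfg$min_patients_systematic,
                          arms = cfg$systematic_arms,
                          tumor_presence = cfg$tumor_presence)
  ann <- screened |>
    dplyr::mutate(.id = variant_id_of(screened)) |>
    dplyr::filter(.data$.id %in% cs$variants) |>
    dplyr::group_by(.data$.id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  votes <- damaging_votes(ann, cfg$thresholds)
  consensus <- votes >= cfg$thresholds$min_votes
  candidates <- tibble::tibble(
    hypothesis = hypothesis,
    variant_id = ann$.id,
    gene = ann$gene,
    hgvs_c = ann$hgvs_c,
    hgvs_p = ann$hgvs_p,
    zygosity = ann$zygosity,
    damaging_votes = votes,
    consensus_damaging = consensus)
  candidates <- candidates[order(candidates$variant_id), ]
  gate <- NULL
  if (!is.null(cohort$expression) && nrow(candidates)) {
    gate <- expression_gate(unique(candidates$gene), cohort$expression,
                            cohort$manifest,
                            min_bin = cfg$expression$min_bin,
                            aggregate = cfg$expression$aggregate,
                            change = cfg$expression$change)
    candidates <- dplyr::left_join(
      candidates,
      gate[, c("gene", "control_rpkm", "case_rpkm", "percent_change",
               "control_bin", "keep")],
      by = "gene") |>
      dplyr::rename(expression_keep = "keep")
  }
  list(candidate_set = cs, candidates = candidates, gate = gate)
}

#' Run the full triage pipeline
#'
#' Orchestrates the whole analysis over a synthetic cohort (default) or
#' user-supplied input files: preliminary screening, hypothesis set logic,
#' systematic-error elimination, control-database subtraction, consensus
#' pathogenicity voting and the expression gate. Deterministic given the
#' configuration; per-stage in/out counts satisfy
#' `n_in == n_out + n_removed`.
#'
#' @param cfg A `pipeline_config` (see [validate_config()]), or anything
#'   `validate_config()` accepts.
#' @param cohort Optionally, an in-memory cohort (as from
#'   [generate_cohort()]) overriding `cfg$inputs`.
#' @return A `run_report`: `stages` ledger, `candidates` table, per-
#'   hypothesis `candidate_sets`, the effective `config` and its hash.
#' @export
run_pipeline <- function(cfg = validate_config(), cohort = NULL) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_config(cfg)
  cohort <- cohort %||% load_pipeline_inputs(cfg)
  cohort$calls <- validate_variant_table(cohort$calls)
  n_in <- length(unique(variant_id_of(cohort$calls)))
  screened <- preliminary_screen(cohort$calls, cfg$screen)
  n_screened <- length(unique(variant_id_of(screened)))
  hypotheses <- if (cfg$hypothesis == "both") c("hereditary", "somatic") else cfg$hypothesis
  results <- lapply(hypotheses, function(h) {
    triage_one_hypothesis(cohort, screened, cfg, h)
  })
  names(results) <- hypotheses
  stages <- dplyr::bind_rows(
    tibble::tibble(hypothesis = "shared", stage = "preliminary_screen",
                   n_in = n_in, n_out = n_screened),
    dplyr::bind_rows(lapply(hypotheses, function(h) {
      prov <- results[[h]]$candidate_set$provenance
      n <- c(n_screened, n_screened - cumsum(prov$n_removed))
      tibble::tibble(hypothesis = h, stage = prov$stage,
                     n_in = n[-length(n)], n_out = n[-1])
    })))
  stages$n_removed <- stages$n_in - stages$n_out
  candidates <- dplyr::bind_rows(lapply(results, `[[`, "candidates"))
  report <- structure(list(
    stages = stages,
    candidates = candidates,
    candidate_sets = lapply(results, `[[`, "candidate_set"),
    config = cfg,
    config_hash = rlang::hash(cfg),
    version = as.character(utils::packageVersion("myxotriage"))),
    class = "run_report")
  if (!is.null(cfg$output_dir)) write_run_report(report, cfg$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> myxotriage", x$version, "\n")
  cat("stages:\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  cat("\ncandidates:", nrow(x$candidates), "\n")
  if (nrow(x$candidates)) print(as.data.frame(x$candidates), row.names = FALSE)
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `candidates.tsv`, a `provenance.json` ledger (stage counts, config
#' hash, package version) and `report.md`, a human-readable summary whose
#' candidate table follows the published layout (nucleotide change, protein
#' change, variation type, classification).
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$candidates, file.path(dir, "candidates.tsv"), na = ".")
  jsonlite::write_json(
    list(version = report$version,
         config_hash = report$config_hash,
         stages = report$stages,
         n_candidates = nrow(report$candidates)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  md <- c("# Variant triage report", "",
          paste0("- package version: ", report$version),
          paste0("- config hash: ", report$config_hash),
          paste0("- final candidates: ", nrow(report$candidates)), "",
          "## Stage ledger", "",
          knit_md_table(report$stages), "",
          "## Candidates", "",
          if (nrow(report$candidates)) {
            cols <- intersect(c("hypothesis", "variant_id", "gene", "hgvs_c",
                                "hgvs_p", "zygosity", "damaging_votes",
                                "consensus_damaging", "percent_change",
                                "control_bin", "expression_keep"),
                              names(report$candidates))
            knit_md_table(report$candidates[, cols])
          } else "(no candidate genes or loci were left)")
  con <- file(file.path(dir, "report.md"), open = "wb")
  writeLines(md, con, sep = "\n")
  close(con)
  invisible(dir)
}

knit_md_table <- function(tbl) {
  fmt <- vapply(tbl, function(col) {
    vapply(col, function(x) {
      if (is.na(x)) "." else if (is.numeric(x)) format(x, digits = 6) else as.character(x)
    }, character(1))
  }, FUN.VALUE = character(nrow(tbl)))
  fmt <- matrix(fmt, nrow = nrow(tbl))
  header <- paste0("| ", paste(names(tbl), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tbl)), collapse = "|"), "|")
  rows <- apply(fmt, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
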