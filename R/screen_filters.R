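# Preliminary per-variant screening: region, functional class and
# population-frequency conditions applied to every annotated variant before
# any cross-sample logic.

#' Screening configuration
#'
#' Defaults encode the study's five preliminary screening conditions: the
#' variant lies in an exon or splicing region; its functional class is
#' nonsynonymous, frameshift, splicing, stopgain, stoploss or unknown; and
#' its minor allele frequency is below 0.001 (strictly) or missing in each
#' of the 1000 Genomes East Asian, ESP6500 and ExAC databases.
#'
#' @param allowed_regions Region annotations that pass.
#' @param allowed_func Functional classes that pass.
#' @param maf_databases Databases whose MAF must each pass.
#' @param maf_threshold Strict upper bound on each present MAF.
#' @param missing_passes Should a missing MAF pass (the "or NA" clause)?
#' @return A `screen_config` list.
#' @export
screen_config <- function(allowed_regions = c("exonic", "splicing"),
                          allowed_func = c("nonsynonymous", "frameshift",
                                           "splicing", "stopgain", "stoploss",
                                           "unknown"),
                          maf_databases = DEFAULT_MAF_DATABASES,
                          maf_threshold = 0.001,
                          missing_passes = TRUE) {
  stopifnot(is.numeric(maf_threshold), length(maf_threshold) == 1L)
  if (maf_threshold <= 0 || maf_threshold >= 1) {
    stop("maf_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (!length(maf_databases)) stop("maf_databases must be non-empty", call. = FALSE)
  bad_r <- setdiff(allowed_regions, REGION_LEVELS)
  if (length(bad_r)) stop("unknown region(s): ", paste(bad_r, collapse = ", "), call. = FALSE)
  bad_f <- setdiff(allowed_func, FUNC_LEVELS)
  if (length(bad_f)) stop("unknown func_class(es): ", paste(bad_f, collapse = ", "), call. = FALSE)
  structure(list(allowed_regions = allowed_regions,
                 allowed_func = allowed_func,
                 maf_databases = maf_databases,
                 maf_threshold = maf_threshold,
                 missing_passes = isTRUE(missing_passes)),
            class = "screen_config")
}

#' Region condition
#'
#' `TRUE` for rows whose region annotation is in the allowed set
#' (by default: exonic or splicing).
#'
#' @param tbl A variant table (or any tibble with the relevant columns).
#' @param cfg A [screen_config()].
#' @return Logical vector, one element per row.
#' @export
passes_region <- function(tbl, cfg = screen_config()) {
  !is.na(tbl$region) & tbl$region %in% cfg$allowed_regions
}

#' Functional-class condition
#'
#' `TRUE` for rows whose functional class is in the allowed set (by default:
#' nonsynonymous, frameshift, splicing, stopgain, stoploss or unknown;
#' synonymous variants fail).
#'
#' @inheritParams passes_region
#' @return Logical vector, one element per row.
#' @export
passes_function <- function(tbl, cfg = screen_config()) {
  !is.na(tbl$func_class) & tbl$func_class %in% cfg$allowed_func
}

#' Minor-allele-frequency condition
#'
#' `TRUE` only when EVERY configured database individually passes: its value
#' is missing (when `missing_passes`) or strictly below `maf_threshold`.
#' A single database at or above the threshold excludes the variant.
#'
#' @inheritParams passes_region
#' @return Logical vector, one element per row.
#' @export
passes_maf <- function(tbl, cfg = screen_config()) {
  out <- rep(TRUE, nrow(tbl))
  for (db in cfg$maf_databases) {
    col <- maf_col(db)
    v <- if (col %in% names(tbl)) tbl[[col]] else rep(NA_real_, nrow(tbl))
    ok <- ifelse(is.na(v), cfg$missing_passes, v < cfg$maf_threshold)
    out <- out & ok
  }
  out
}

#' Preliminary screen
#'
#' Applies the region, functional-class and MAF conditions jointly and
#' returns the passing rows in their original order; the input is not
#' modified. The screen is per annotated variant and sample-agnostic —
#' cross-sample reasoning happens downstream.
#'
#' @inheritParams passes_region
#' @return The subset of `tbl` passing all conditions.
#' @export
preliminary_screen <- function(tbl, cfg = screen_config()) {
  keep <- passes_region(tbl, cfg) & passes_function(tbl, cfg) & passes_maf(tbl, cfg)
  tbl[keep, , drop = FALSE]
}
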