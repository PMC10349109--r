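# Expression evidence: RPKM computation and credibility binning,
# tumor-vs-normal percent change, the expression gate applied to candidate
# genes, and two small quantification formulas used alongside it
# (2^-ddCt relative qPCR expression, xenograft tumor volume).

#' RPKM expression bins, weakest to strongest
#' @export
EXPRESSION_BINS <- c("not_credible", "background", "middle", "high")

#' Reads Per Kilobase per Million mapped reads
#'
#' `RPKM = read_count * 1e9 / (gene_length_bp * total_mapped_reads)` —
#' linear in the read count and inverse-linear in gene length and library
#' size. Gene length is the annotated transcript-model length supplied with
#' the table; no exon-union computation is attempted.
#'
#' @param read_count Non-negative read counts.
#' @param gene_length_bp Positive transcript lengths in bp.
#' @param total_mapped_reads Positive library sizes (mapped reads).
#' @return Numeric RPKM values.
#' @examples
#' compute_rpkm(1000, 1000, 1e6)  # 1000
#' @export
compute_rpkm <- function(read_count, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be > 0", call. = FALSE)
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0", call. = FALSE)
  if (any(read_count < 0)) stop("read_count must be >= 0", call. = FALSE)
  read_count * 1e9 / (gene_length_bp * total_mapped_reads)
}

#' Bin an RPKM value into a credibility level
#'
#' RPKM below 1 is not credible; `[1, 10)` is background-level expression;
#' `[10, 100)` is middle-level; 100 and above is high. The published
#' legend leaves exactly 1 and exactly 10 unassigned; half-open intervals
#' closed on the left are adopted so the bins partition `[0, Inf)`.
#'
#' @param rpkm Non-negative RPKM values.
#' @return Character vector of bin names (see [EXPRESSION_BINS]).
#' @export
bin_rpkm <- function(rpkm) {
  if (any(is.na(rpkm))) stop("rpkm must not be missing", call. = FALSE)
  if (any(rpkm < 0)) stop("rpkm must be >= 0", call. = FALSE)
  as.character(cut(rpkm, breaks = c(-Inf, 1, 10, 100, Inf),
                   labels = EXPRESSION_BINS, right = FALSE))
}

#' Percent change of a case value relative to a control value
#'
#' `(case - control) / control * 100`; negative values are decreases (a
#' result of -66 is the "average decrease of 66%" shape). Related to fold
#' change by `percent = (fold - 1) * 100`.
#'
#' @param case_value,control_value Numeric; `control_value` must be > 0.
#' @return Percent change.
#' @export
percent_change <- function(case_value, control_value) {
  if (any(control_value <= 0)) stop("control_value must be > 0", call. = FALSE)
  (case_value - control_value) / control_value * 100
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes `2^-((Ct_target,case - Ct_ref,case) -
#' (Ct_target,control - Ct_ref,control))`, the standard relative qPCR
#' quantification against a reference gene.
#'
#' @param ct_target_case,ct_ref_case Target / reference-gene Ct in the case.
#' @param ct_target_control,ct_ref_control Same in the control.
#' @return Fold change relative to control (1 = no change).
#' @export
ddct_relative_expression <- function(ct_target_case, ct_ref_case,
                                     ct_target_control, ct_ref_control) {
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Xenograft tumor volume
#'
#' `0.5 * long * short^2` in mm^3, from caliper diameters in mm.
#'
#' @param long_diameter_mm,short_diameter_mm Diameters; `long >= short > 0`.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(long_diameter_mm, short_diameter_mm) {
  if (any(short_diameter_mm <= 0)) stop("diameters must be > 0", call. = FALSE)
  if (any(short_diameter_mm > long_diameter_mm)) {
    stop("short diameter exceeds long diameter (diameters swapped?)", call. = FALSE)
  }
  0.5 * long_diameter_mm * short_diameter_mm^2
}

ensure_rpkm <- function(expr) {
  expr <- tibble::as_tibble(expr)
  if (!"rpkm" %in% names(expr)) {
    needed <- c("read_count", "gene_length_bp", "total_mapped_reads")
    missing_cols <- setdiff(needed, names(expr))
    if (length(missing_cols)) {
      stop("expression table needs either an rpkm column or ",
           paste(needed, collapse = " + "), call. = FALSE)
    }
    expr$rpkm <- compute_rpkm(expr$read_count, expr$gene_length_bp,
                              expr$total_mapped_reads)
  }
  expr
}

#' Expression gate for candidate genes
#'
#' Aggregates RPKM for each candidate gene over case (discovery tumor) and
#' control (normal atrium) samples, computes the case-vs-control percent
#' change, bins the control-side expression, and keeps a gene only when its
#' control bin reaches `min_bin` — i.e. the gene is credibly expressed in
#' the tissue of interest, the criterion that retained the moderately
#' expressed, decreased candidate and rejected the not-credibly expressed
#' one.
#'
#' @param candidate_genes Character vector of gene symbols.
#' @param expr Expression table: `gene`, `sample_id`, and either `rpkm` or
#'   `read_count` + `gene_length_bp` + `total_mapped_reads`.
#' @param manifest Cohort manifest; discovery tumor samples are cases,
#'   normal atrium samples are controls.
#' @param min_bin Weakest control-side bin that passes (default `"middle"`,
#'   i.e. above background).
#' @param aggregate `"mean"` (the published "average") or `"median"`.
#' @param change `"percent_of_aggregates"` (percent change of the
#'   aggregated case vs control values, default) or `"mean_of_percents"`
#'   (mean of per-case-sample percent changes).
#' @return A tibble: `gene`, `case_rpkm`, `control_rpkm`, `percent_change`,
#'   `control_bin`, `keep`.
#' @export
expression_gate <- function(candidate_genes, expr, manifest,
                            min_bin = "middle",
                            aggregate = c("mean", "median"),
                            change = c("percent_of_aggregates", "mean_of_percents")) {
  aggregate <- match.arg(aggregate)
  change <- match.arg(change)
  min_bin <- match.arg(min_bin, EXPRESSION_BINS)
  candidate_genes <- unique(candidate_genes)
  if (!length(candidate_genes)) {
    return(tibble::tibble(gene = character(), case_rpkm = numeric(),
                          control_rpkm = numeric(), percent_change = numeric(),
                          control_bin = character(), keep = logical()))
  }
  expr <- ensure_rpkm(expr)
  manifest <- validate_manifest(manifest)
  case_samples <- sample_ids_for(manifest, arm = "discovery", tissue = "tumor")
  control_samples <- sample_ids_for(manifest, tissue = "normal_atrium")
  agg <- if (aggregate == "mean") mean else stats::median
  rows <- lapply(candidate_genes, function(g) {
    case_v <- expr$rpkm[expr$gene == g & expr$sample_id %in% case_samples]
    ctrl_v <- expr$rpkm[expr$gene == g & expr$sample_id %in% control_samples]
    if (!length(case_v) || !length(ctrl_v)) return(NULL)
    case_rpkm <- agg(case_v)
    control_rpkm <- agg(ctrl_v)
    pc <- if (change == "percent_of_aggregates") {
      percent_change(case_rpkm, control_rpkm)
    } else {
      mean(percent_change(case_v, control_rpkm))
    }
    bin <- bin_rpkm(control_rpkm)
    tibble::tibble(gene = g, case_rpkm = case_rpkm, control_rpkm = control_rpkm,
                   percent_change = pc, control_bin = bin,
                   keep = match(bin, EXPRESSION_BINS) >= match(min_bin, EXPRESSION_BINS))
  })
  found <- vapply(rows, Negate(is.null), logical(1))
  if (!all(found)) {
    stop("gene(s) absent from expression table (case or control side): ",
         paste(candidate_genes[!found], collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(rows)
}
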