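# Domain types and I/O for multi-sample annotated variant tables.
#
# A variant table is a tibble with one row per (variant, sample) observation.
# Canonical columns (the annovar_tsv dialect writes them in this order):
#   sample_id, chrom, pos, ref, alt, zygosity, gene, region, func_class,
#   maf_<database>... , sift, polyphen2, phylop, gerp, mutationtaster, lrt,
#   hgvs_c, hgvs_p
# Missing MAFs and predictor scores are NA, never 0: the screening rule
# "MAF < threshold or NA" requires a genuine missing state.

#' Recognized variant region annotations
#' @export
REGION_LEVELS <- c("exonic", "splicing", "intronic", "UTR3", "UTR5",
                   "intergenic", "other")

#' Recognized functional-class annotations
#' @export
FUNC_LEVELS <- c("nonsynonymous", "frameshift", "splicing", "stopgain",
                 "stoploss", "synonymous", "unknown", "other")

#' Default population-frequency databases consulted by the screen
#' @export
DEFAULT_MAF_DATABASES <- c("1000g2015Aug_eas", "esp6500siv2_all", "exac03")

ZYGOSITY_LEVELS <- c("Het", "Hom")
TISSUE_LEVELS <- c("tumor", "pbmc", "normal_atrium")
ARM_LEVELS <- c("discovery", "validation", "normal_control", "lab_control")

PREDICTOR_COLS <- c("sift", "polyphen2", "phylop", "gerp", "mutationtaster", "lrt")

maf_col <- function(db) paste0("maf_", db)

#' Normalize variant alleles
#'
#' Normalizes one or more variants to a minimal left-anchored representation:
#' alleles are uppercased, then the shared allele suffix and prefix are
#' trimmed (keeping at least one base of each allele, so indels retain their
#' anchor base and `pos` advances past any trimmed prefix). Coordinates are
#' 1-based, VCF convention. Normalization is idempotent, and two variants
#' denote the same locus/allele iff their normalized `(chrom, pos, ref, alt)`
#' agree.
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based positions (positive integers).
#' @param ref,alt Reference / single alternate alleles (non-empty A/C/G/T).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant("17", 100, "CAG", "CTG")  # -> pos 101, A>T
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  n <- length(ref)
  stopifnot(length(alt) == n, length(pos) == n, length(chrom) %in% c(1L, n))
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop("invalid allele(s): ", paste(unique(c(ref[bad], alt[bad])), collapse = ", "),
         " (alleles must be non-empty A/C/G/T strings)", call. = FALSE)
  }
  if (any(pos < 1L)) stop("pos must be >= 1", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    # trim common suffix
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # trim common prefix, advancing pos
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  tibble::tibble(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt)
}

#' Canonical variant identifier
#'
#' Builds the `chrom:pos:ref>alt` key used for all set logic, after
#' [normalize_variant()] normalization, so locus identity is well-defined.
#'
#' @inheritParams normalize_variant
#' @return Character vector of variant keys.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  k <- normalize_variant(chrom, pos, ref, alt)
  paste0(k$chrom, ":", k$pos, ":", k$ref, ">", k$alt)
}

#' @rdname variant_id
#' @param tbl A variant table with `chrom`, `pos`, `ref`, `alt` columns.
#' @export
variant_id_of <- function(tbl) {
  variant_id(tbl$chrom, tbl$pos, tbl$ref, tbl$alt)
}

canonical_columns <- function(maf_databases = DEFAULT_MAF_DATABASES) {
  c("sample_id", "chrom", "pos", "ref", "alt", "zygosity", "gene", "region",
    "func_class", maf_col(maf_databases), PREDICTOR_COLS, "hgvs_c", "hgvs_p")
}

coerce_enum <- function(x, levels, what) {
  x <- as.character(x)
  unknown <- !is.na(x) & !(x %in% levels)
  if (any(unknown)) {
    message("mapping unrecognized ", what, " value(s) to \"other\": ",
            paste(unique(x[unknown]), collapse = ", "))
    x[unknown] <- "other"
  }
  x
}

#' Validate a variant table against the domain invariants
#'
#' Checks column presence, allele validity, enum restriction (unrecognized
#' region / functional-class strings are mapped to `"other"` with a message),
#' zygosity values, and that every present MAF lies in `[0, 1]`. Variant keys
#' are normalized in place.
#'
#' @param tbl A variant table (see package docs for the column contract).
#' @return The validated (possibly enum-coerced) tibble.
#' @export
validate_variant_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  required <- c("sample_id", "chrom", "pos", "ref", "alt", "zygosity")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl)) {
    norm <- normalize_variant(tbl$chrom, tbl$pos, tbl$ref, tbl$alt)
    tbl$chrom <- norm$chrom
    tbl$pos <- norm$pos
    tbl$ref <- norm$ref
    tbl$alt <- norm$alt
    bad_zyg <- !is.na(tbl$zygosity) & !(tbl$zygosity %in% ZYGOSITY_LEVELS)
    if (any(bad_zyg)) {
      stop("invalid zygosity value(s): ",
           paste(unique(tbl$zygosity[bad_zyg]), collapse = ", "),
           " (expected Het or Hom)", call. = FALSE)
    }
    if ("region" %in% names(tbl)) {
      tbl$region <- coerce_enum(tbl$region, REGION_LEVELS, "region")
    }
    if ("func_class" %in% names(tbl)) {
      tbl$func_class <- coerce_enum(tbl$func_class, FUNC_LEVELS, "func_class")
    }
    for (col in grep("^maf_", names(tbl), value = TRUE)) {
      v <- tbl[[col]]
      bad <- !is.na(v) & (v < 0 | v > 1)
      if (any(bad)) {
        stop("MAF column ", col, " has value(s) outside [0, 1]", call. = FALSE)
      }
    }
  }
  tbl
}

# ". ", "", "NA" -> NA; anything else parsed as-is
parse_missing <- function(x) {
  x <- as.character(x)
  x[x %in% c(".", "", "NA")] <- NA_character_
  x
}

parse_missing_num <- function(x) {
  suppressWarnings(as.numeric(parse_missing(x)))
}

#' Read a multi-sample variant table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`annovar_tsv`}{A tab-separated annotation table with one row per
#'     (variant, sample) and the canonical header (see
#'     [write_variant_table()]); any of `"."`, `""`, `"NA"` in MAF, predictor
#'     or HGVS columns parse to missing. Column aliases may be supplied via
#'     `col_map` (`c(file_column = "canonical_name")`).}
#'   \item{`vcf_min`}{A minimal VCF (v4.x) with per-sample GT genotypes.
#'     Multiallelic records are split into one row per alternate allele;
#'     zygosity derives from the GT allele count (one copy of the alternate
#'     allele is Het, two is Hom; genotypes carrying no copy yield no row;
#'     genotypes that are not diploid, or reference an undeclared allele, are
#'     rejected). Annotation columns are returned as missing.}
#' }
#'
#' @param path Input file.
#' @param dialect `"annovar_tsv"` or `"vcf_min"`.
#' @param col_map Optional named character vector of column aliases for the
#'   annovar_tsv dialect.
#' @return A validated variant table tibble.
#' @export
read_variant_table <- function(path, dialect = c("annovar_tsv", "vcf_min"),
                               col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(dialect,
         annovar_tsv = read_annovar_tsv(path, col_map = col_map),
         vcf_min = read_vcf_min(path))
}

read_annovar_tsv <- function(path, col_map = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (!is.null(col_map)) {
    hit <- names(raw) %in% names(col_map)
    names(raw)[hit] <- unname(col_map[names(raw)[hit]])
  }
  required <- c("sample_id", "chrom", "pos", "ref", "alt", "zygosity")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("malformed variant table ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    stop("malformed row in ", path, " line ", bad[1] + 1L,
         ", column pos: ", raw$pos[bad[1]], call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = raw$sample_id,
    chrom = raw$chrom,
    pos = pos,
    ref = toupper(raw$ref),
    alt = toupper(raw$alt),
    zygosity = raw$zygosity,
    gene = if ("gene" %in% names(raw)) parse_missing(raw$gene) else NA_character_,
    region = if ("region" %in% names(raw)) parse_missing(raw$region) else NA_character_,
    func_class = if ("func_class" %in% names(raw)) parse_missing(raw$func_class) else NA_character_
  )
  for (col in grep("^maf_", names(raw), value = TRUE)) {
    out[[col]] <- parse_missing_num(raw[[col]])
  }
  for (col in c("sift", "phylop", "gerp")) {
    out[[col]] <- if (col %in% names(raw)) parse_missing_num(raw[[col]]) else NA_real_
  }
  for (col in c("polyphen2", "mutationtaster", "lrt", "hgvs_c", "hgvs_p")) {
    out[[col]] <- if (col %in% names(raw)) parse_missing(raw[[col]]) else NA_character_
  }
  validate_variant_table(out)
}

read_vcf_min <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(empty_variant_table())
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (s in colnames(gt)) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      alleles <- strsplit(g, "[/|]")[[1]]
      if (length(alleles) != 2L || !all(grepl("^[0-9]+$", alleles))) {
        stop("unsupported genotype \"", g, "\" in ", path,
             " (sample ", s, ", ", fix$CHROM[i], ":", fix$POS[i], ")", call. = FALSE)
      }
      ai <- as.integer(alleles)
      if (any(ai > length(alts))) {
        stop("genotype \"", g, "\" references undeclared allele in ", path,
             " (sample ", s, ", ", fix$CHROM[i], ":", fix$POS[i], ")", call. = FALSE)
      }
      for (k in seq_along(alts)) {
        copies <- sum(ai == k)
        if (copies == 0L) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = s, chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]),
          ref = toupper(fix$REF[i]), alt = toupper(alts[k]),
          zygosity = if (copies == 2L) "Hom" else "Het")
      }
    }
  }
  if (!length(rows)) return(empty_variant_table())
  out <- dplyr::bind_rows(rows)
  for (col in setdiff(canonical_columns(), names(out))) {
    out[[col]] <- if (col %in% c("sift", "phylop", "gerp") ||
                      startsWith(col, "maf_")) NA_real_ else NA_character_
  }
  validate_variant_table(out[, canonical_columns()])
}

empty_variant_table <- function(maf_databases = DEFAULT_MAF_DATABASES) {
  cols <- canonical_columns(maf_databases)
  out <- tibble::as_tibble(stats::setNames(
    lapply(cols, function(col) {
      if (col == "pos") integer()
      else if (col %in% c("sift", "phylop", "gerp") || startsWith(col, "maf_")) numeric()
      else character()
    }), cols))
  out
}

#' Write a variant table
#'
#' Writers emit UTF-8, LF line endings and a deterministic column order;
#' missing values are written as `"."`. Output round-trips through
#' [read_variant_table()] with full fidelity. The `vcf_min` dialect writes
#' variant keys and per-sample GT only (annotations are not representable
#' in the minimal VCF).
#'
#' @param tbl A validated variant table.
#' @param path Output file.
#' @param dialect `"annovar_tsv"` or `"vcf_min"`.
#' @return Invisibly, `path`.
#' @export
write_variant_table <- function(tbl, path, dialect = c("annovar_tsv", "vcf_min")) {
  dialect <- match.arg(dialect)
  tbl <- validate_variant_table(tbl)
  switch(dialect,
         annovar_tsv = write_annovar_tsv(tbl, path),
         vcf_min = write_vcf_min(tbl, path))
  invisible(path)
}

write_annovar_tsv <- function(tbl, path) {
  maf_cols <- grep("^maf_", names(tbl), value = TRUE)
  if (!length(maf_cols)) maf_cols <- maf_col(DEFAULT_MAF_DATABASES)
  for (col in setdiff(c(canonical_columns(sub("^maf_", "", maf_cols))), names(tbl))) {
    tbl[[col]] <- NA
  }
  ord <- c("sample_id", "chrom", "pos", "ref", "alt", "zygosity", "gene",
           "region", "func_class", sort(maf_cols), PREDICTOR_COLS,
           "hgvs_c", "hgvs_p")
  out <- tbl[, ord]
  con <- file(path, open = "wb")  # binary mode forces LF on every platform
  on.exit(close(con))
  fmt <- function(v) {
    s <- vapply(v, function(x) {
      if (is.na(x)) "." else if (is.numeric(x)) format(x, digits = 17, scientific = NA) else as.character(x)
    }, character(1))
    s
  }
  writeLines(paste(ord, collapse = "\t"), con, sep = "\n")
  if (nrow(out)) {
    lines <- do.call(paste, c(lapply(out, fmt), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
}

write_vcf_min <- function(tbl, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  samples <- sort(unique(tbl$sample_id))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(header, con, sep = "\n")
  if (nrow(tbl)) {
    keys <- tbl |>
      dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
    for (i in seq_len(nrow(keys))) {
      hits <- tbl[tbl$chrom == keys$chrom[i] & tbl$pos == keys$pos[i] &
                  tbl$ref == keys$ref[i] & tbl$alt == keys$alt[i], ]
      gts <- vapply(samples, function(s) {
        z <- hits$zygosity[hits$sample_id == s]
        if (!length(z)) "0/0" else if (z[1] == "Hom") "1/1" else "0/1"
      }, character(1))
      writeLines(paste(c(keys$chrom[i], keys$pos[i], ".", keys$ref[i],
                         keys$alt[i], ".", ".", ".", "GT", gts),
                       collapse = "\t"), con, sep = "\n")
    }
  }
}

#' Read a cohort manifest
#'
#' The manifest maps each sequenced sample to its patient, tissue and cohort
#' arm, and drives all cross-sample set logic. Required TSV columns:
#' `sample_id`, `patient_id`, `tissue` (tumor / pbmc / normal_atrium), `arm`
#' (discovery / validation / normal_control / lab_control).
#'
#' @param path Manifest TSV.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!nrow(raw)) stop("empty manifest: ", path, call. = FALSE)
  validate_manifest(raw)
}

#' @rdname read_manifest
#' @param manifest A manifest data frame to validate in memory.
#' @export
validate_manifest <- function(manifest) {
  manifest <- tibble::as_tibble(manifest)
  required <- c("sample_id", "patient_id", "tissue", "arm")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(manifest)) stop("empty manifest", call. = FALSE)
  dup <- manifest$sample_id[duplicated(manifest$sample_id)]
  if (length(dup)) {
    stop("duplicated sample_id in manifest: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_tissue <- setdiff(unique(manifest$tissue), TISSUE_LEVELS)
  if (length(bad_tissue)) {
    stop("unknown tissue value(s): ", paste(bad_tissue, collapse = ", "),
         call. = FALSE)
  }
  bad_arm <- setdiff(unique(manifest$arm), ARM_LEVELS)
  if (length(bad_arm)) {
    stop("unknown arm value(s): ", paste(bad_arm, collapse = ", "), call. = FALSE)
  }
  manifest[, required]
}

#' Write a cohort manifest
#' @param manifest A validated manifest tibble.
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(manifest), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(manifest, sep = "\t")), con, sep = "\n")
  invisible(path)
}
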