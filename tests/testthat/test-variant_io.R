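test_that("variant normalization trims alleles, keeps the anchor base, and is idempotent", {
  # shared suffix then prefix trimming, position advances past the prefix
  k <- normalize_variant("17", 100, "CAG", "CTG")
  expect_equal(k$pos, 101L)
  expect_equal(k$ref, "A")
  expect_equal(k$alt, "T")
  # indel keeps its anchor base
  k2 <- normalize_variant("1", 50, "ATT", "AT")
  expect_equal(k2$ref, "AT")
  expect_equal(k2$alt, "A")
  expect_equal(k2$pos, 50L)
  # idempotence on random SNVs and the trimmed cases above
  set.seed(11)
  tbl <- make_variant_table(30)
  once <- normalize_variant(tbl$chrom, tbl$pos, tbl$ref, tbl$alt)
  twice <- normalize_variant(once$chrom, once$pos, once$ref, once$alt)
  expect_equal(once, twice)
  # lowercase alleles are uppercased; invalid or degenerate input errors
  expect_equal(normalize_variant("1", 1, "a", "t")$ref, "A")
  expect_error(normalize_variant("1", 1, "A", "A"), "differ")
  expect_error(normalize_variant("1", 0, "A", "T"), ">= 1")
  expect_error(normalize_variant("1", 1, "AN", "A"), "allele")
})

test_that("annovar_tsv tables round-trip with full fidelity, including missingness", {
  set.seed(21)
  tbl <- validate_variant_table(make_variant_table(100))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(tbl, path, "annovar_tsv")
  back <- read_variant_table(path, "annovar_tsv")
  expect_equal(as.data.frame(back[order(back$sample_id, back$pos), names(tbl)]),
               as.data.frame(tbl[order(tbl$sample_id, tbl$pos), ]),
               tolerance = 1e-12)
  # ".", "", "NA" all parse to a genuine missing state, never 0
  con <- file(path2 <- withr::local_tempfile(fileext = ".tsv"), "wb")
  writeLines(c("sample_id\tchrom\tpos\tref\talt\tzygosity\tgene\tregion\tfunc_class\tmaf_exac03\tsift",
               "S1\t17\t100\tA\tG\tHet\tKIF1C\texonic\tnonsynonymous\t.\tNA",
               "S1\t17\t200\tC\tT\tHet\tKIF1C\texonic\tnonsynonymous\t\t0.01"),
             con, sep = "\n")
  close(con)
  parsed <- read_variant_table(path2, "annovar_tsv")
  expect_true(is.na(parsed$maf_exac03[1]))
  expect_true(is.na(parsed$maf_exac03[2]))
  expect_true(is.na(parsed$sift[1]))
  expect_equal(parsed$sift[2], 0.01)
  # empty record list -> header-only file that reads back empty
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(tbl[0, ], p3, "annovar_tsv")
  expect_length(readLines(p3), 1L)
  expect_equal(nrow(read_variant_table(p3, "annovar_tsv")), 0L)
})

test_that("column aliasing maps vendor headers onto the canonical names", {
  con <- file(p <- withr::local_tempfile(fileext = ".tsv"), "wb")
  writeLines(c("Sample\tChr\tStart\tRef\tAlt\tGT\tGene.refGene\tFunc.refGene\tExonicFunc.refGene\tExAC_ALL",
               "S1\t17\t100\tA\tG\tHet\tKIF1C\texonic\tnonsynonymous\t0.00003"),
             con, sep = "\n")
  close(con)
  parsed <- read_variant_table(p, "annovar_tsv", col_map = c(
    Sample = "sample_id", Chr = "chrom", Start = "pos", Ref = "ref", Alt = "alt",
    GT = "zygosity", Gene.refGene = "gene", Func.refGene = "region",
    ExonicFunc.refGene = "func_class", ExAC_ALL = "maf_exac03"))
  expect_equal(parsed$gene, "KIF1C")
  expect_equal(parsed$maf_exac03, 3e-5)
})

test_that("minimal VCF reading splits multiallelic records and derives zygosity from GT", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
           "17\t100\t.\tC\tA,T\t.\t.\t.\tGT\t0/1\t1/2",
           "17\t200\t.\tG\tA\t.\t.\t.\tGT\t1/1\t0/0")
  p <- withr::local_tempfile(fileext = ".vcf")
  con <- file(p, "wb"); writeLines(vcf, con, sep = "\n"); close(con)
  tbl <- read_variant_table(p, "vcf_min")
  # k alts yield exactly k variant keys
  expect_setequal(unique(variant_id_of(tbl)),
                  c("17:100:C>A", "17:100:C>T", "17:200:G>A"))
  expect_equal(tbl$zygosity[tbl$sample_id == "S1" & tbl$pos == 100], "Het")
  # S2 carries one copy each of alt 1 and alt 2 -> two Het rows
  s2 <- tbl[tbl$sample_id == "S2" & tbl$pos == 100, ]
  expect_equal(nrow(s2), 2L)
  expect_true(all(s2$zygosity == "Het"))
  # homozygous alt, and 0/0 yields no row
  expect_equal(tbl$zygosity[tbl$sample_id == "S1" & tbl$pos == 200], "Hom")
  expect_false(any(tbl$sample_id == "S2" & tbl$pos == 200))
  # calls round-trip through the vcf_min writer
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_variant_table(tbl, p2, "vcf_min")
  back <- read_variant_table(p2, "vcf_min")
  key_cols <- c("sample_id", "chrom", "pos", "ref", "alt", "zygosity")
  expect_equal(as.data.frame(dplyr::arrange(back[key_cols], sample_id, pos, alt)),
               as.data.frame(dplyr::arrange(tbl[key_cols], sample_id, pos, alt)))
  # unsupported genotypes are rejected with a clear error
  bad <- sub("1/1", "0/3", vcf)
  con <- file(p3 <- withr::local_tempfile(fileext = ".vcf"), "wb")
  writeLines(bad, con, sep = "\n"); close(con)
  expect_error(read_variant_table(p3, "vcf_min"), "undeclared allele")
})

test_that("unrecognized annotation strings coerce to 'other' and invalid values error", {
  tbl <- make_variant_table(3)
  tbl$region[1] <- "ncRNA_exonic"
  expect_message(out <- validate_variant_table(tbl), "other")
  expect_equal(out$region[1], "other")
  tbl2 <- make_variant_table(3)
  tbl2$maf_exac03[2] <- 1.5
  expect_error(validate_variant_table(tbl2), "outside")
  tbl3 <- make_variant_table(3)
  tbl3$zygosity[1] <- "het"
  expect_error(validate_variant_table(tbl3), "zygosity")
})

test_that("manifest reading validates the study design and rejects malformed input", {
  manifest <- tibble::tibble(
    sample_id = c("D1_T", "D2_T", "D2_B", "N1", "N2", "N3"),
    patient_id = c("D1", "D2", "D2", "PN1", "PN2", "PN3"),
    tissue = c("tumor", "tumor", "pbmc", rep("normal_atrium", 3)),
    arm = c(rep("discovery", 3), rep("normal_control", 3)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(manifest, p)
  m <- read_manifest(p)
  expect_equal(nrow(m), 6L)
  expect_equal(length(unique(m$patient_id[m$arm == "discovery"])), 2L)
  # duplicated sample_id
  dup <- manifest; dup$sample_id[2] <- "D1_T"
  expect_error(validate_manifest(dup), "duplicated sample_id")
  # unknown tissue / arm
  bad <- manifest; bad$tissue[1] <- "liver"
  expect_error(validate_manifest(bad), "unknown tissue")
  bad2 <- manifest; bad2$arm[1] <- "case"
  expect_error(validate_manifest(bad2), "unknown arm")
  # empty manifest
  con <- file(p2 <- withr::local_tempfile(fileext = ".tsv"), "wb")
  writeLines("sample_id\tpatient_id\ttissue\tarm", con, sep = "\n"); close(con)
  expect_error(read_manifest(p2), "empty manifest")
})
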