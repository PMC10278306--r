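test_that("dosage_matrix enforces its invariants", {
  dm <- toy_dm()
  expect_equal(dim(dm), c(4L, 3L))
  # folded MAF recomputed from dosages
  expect_equal(dm$variants$maf, c(0.5, 0.5, 0.5))
  expect_error(dosage_matrix(matrix(3, 1, 1),
                             data.frame(id = "v", chrom = "1", pos = 1,
                                        ref = "A", alt = "C"),
                             "S1"),
               "outside \\[0, 2\\]")
  expect_error(dosage_matrix(matrix(c(0, 1), 1, 2),
                             data.frame(id = c("v", "v"), chrom = "1",
                                        pos = 1:2, ref = "A", alt = "C"),
                             "S1"),
               "duplicate variant")
  expect_error(dosage_matrix(matrix(NA_real_, 1, 1),
                             data.frame(id = "v", chrom = "1", pos = 1,
                                        ref = "A", alt = "C"),
                             "S1"),
               "missing")
  expect_error(dosage_matrix(matrix(1, 1, 1),
                             data.frame(id = "v", chrom = "1", pos = 1,
                                        ref = "A", alt = "C", maf = 0.4),
                             "S1"),
               "disagrees")
})

test_that("TSV dosages round-trip and MAF arithmetic is correct", {
  # 2 samples x 1 variant with dosages 0 and 2 -> ALT frequency 0.5
  dm <- dosage_matrix(matrix(c(0, 2), 2, 1),
                      data.frame(id = "v1", chrom = "X", pos = 10,
                                 ref = "A", alt = "C"),
                      c("S1", "S2"))
  expect_equal(dm$variants$maf, 0.5)
  path <- file.path(withr::local_tempdir(), "dos.tsv")
  write_dosages(toy_dm(), path)
  back <- read_dosages(path, "tsv")
  expect_equal(back$dosages, toy_dm()$dosages)
  expect_equal(back$variants$maf, toy_dm()$variants$maf)
  expect_equal(back$variants$imputation_r2, toy_dm()$variants$imputation_r2)
  expect_identical(back$samples$sample_id, toy_dm()$samples$sample_id)
})

test_that("VCF genotypes convert to dosages (GT fallback and DS field)", {
  dir <- withr::local_tempdir()
  gt_vcf <- file.path(dir, "gt.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("X", "100", "v1", "A", "C", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t")), gt_vcf)
  dm <- read_dosages(gt_vcf, "vcf")
  expect_equal(as.vector(dm$dosages), c(0, 1, 2))
  expect_equal(dm$variants$chrom, "X")
  expect_equal(dm$variants$pos, 100L)

  ds_vcf <- file.path(dir, "ds.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("X", "100", "v1", "A", "C", ".", ".", ".", "GT:DS",
          "0/0:0.12", "0/1:0.97", "1/1:1.85", sep = "\t")), ds_vcf)
  dm <- read_dosages(ds_vcf, "vcf")
  expect_equal(as.vector(dm$dosages), c(0.12, 0.97, 1.85))

  miss_vcf <- file.path(dir, "miss.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("X", "100", "v1", "A", "C", ".", ".", ".", "GT",
          "./.", "0/1", sep = "\t")), miss_vcf)
  expect_error(read_dosages(miss_vcf, "vcf"), "missing")
})

test_that("malformed dosage TSVs fail loudly, naming the problem", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.tsv")
  writeLines(c("sample_id\tv1", "S1\t0.5", "S2\toops"), path)
  writeLines("id\tchrom\tpos\tref\talt\tmaf\timputation_r2",
             file.path(dir, "bad.variants.tsv"))
  expect_error(read_dosages(path, "tsv"), "line")
  expect_error(read_dosages(file.path(dir, "absent.tsv"), "tsv"),
               "not found")
})

test_that("sequence-stage QC filters on MAF and imputation quality", {
  # variant below the MAF floor is removed even with high imputation R2
  set.seed(1)
  n <- 600
  dos <- cbind(c(rep(1, 2), rep(0, n - 2)),       # maf ~ 0.0017 < 0.005
               rbinom(n, 2, 0.3))
  dm <- dosage_matrix(dos,
                      data.frame(id = c("rare", "ok"), chrom = "X",
                                 pos = c(100L, 200L), ref = "A", alt = "C",
                                 imputation_r2 = c(0.9, 0.9)),
                      paste0("S", seq_len(n)))
  res <- apply_variant_qc(dm, qc_thresholds(), "sequence_filter")
  expect_identical(res$dm$variants$id, "ok")
  expect_equal(res$report$removed[res$report$criterion == "maf"], 1)

  # empty input: empty output, zero counts
  res0 <- apply_variant_qc(dm[, integer(0)], qc_thresholds(),
                           "sequence_filter")
  expect_equal(ncol(res0$dm$dosages), 0L)
  expect_true(all(res0$report$removed == 0))

  expect_error(apply_variant_qc(dm, qc_thresholds(), "nonsense"),
               "stage")
})

test_that("QC removal counts add up on a 10-variant fixture", {
  # 3 variants below MAF, 2 below R2, 1 overlapping -> 6 survive
  set.seed(42)
  n <- 1000
  make_col <- function(maf) rbinom(n, 2, maf)
  common <- replicate(7, make_col(0.3))
  rare <- replicate(3, c(rep(1, 3), rep(0, n - 3)))  # maf 0.0015
  dos <- cbind(rare, common)
  r2 <- c(0.9, 0.9, 0.1,               # third rare variant also fails R2
          0.1, rep(0.9, 6))            # one common variant fails R2 only
  dm <- dosage_matrix(dos,
                      data.frame(id = paste0("v", 1:10), chrom = "X",
                                 pos = (1:10) * 1000L, ref = "A", alt = "C",
                                 imputation_r2 = r2),
                      paste0("S", seq_len(n)))
  res <- apply_variant_qc(dm, qc_thresholds(), "sequence_filter")
  expect_equal(ncol(res$dm$dosages), 6L)
  expect_equal(res$report$removed[res$report$criterion == "maf"], 3)
  expect_equal(res$report$removed[res$report$criterion == "imputation_r2"],
               2)
  # idempotence: same thresholds twice change nothing
  res2 <- apply_variant_qc(res$dm, qc_thresholds(), "sequence_filter")
  expect_equal(res2$dm$dosages, res$dm$dosages)
  expect_true(all(res2$report$removed == 0))
})

test_that("chip-stage QC applies strict MAF and an HWE chi-square test", {
  set.seed(7)
  n <- 2000
  hwe_ok <- rbinom(n, 2, 0.4)
  # gross heterozygote excess: everyone heterozygous
  hwe_bad <- rep(1, n)
  low_maf <- rbinom(n, 2, 0.008)
  dm <- dosage_matrix(cbind(hwe_ok, hwe_bad, low_maf),
                      data.frame(id = c("ok", "het_excess", "low"),
                                 chrom = "2", pos = c(1L, 2L, 3L) * 100L,
                                 ref = "A", alt = "C"),
                      paste0("S", seq_len(n)))
  res <- apply_variant_qc(dm, qc_thresholds(), "chip_qc")
  expect_identical(res$dm$variants$id, "ok")
  expect_equal(res$report$removed[res$report$criterion == "hwe"], 1)
  # HWE P-values lie in [0,1] and equal 1 for monomorphic columns
  dm_mono <- dosage_matrix(matrix(0, 10, 1),
                           data.frame(id = "m", chrom = "2", pos = 1L,
                                      ref = "A", alt = "C"),
                           paste0("S", 1:10))
  expect_equal(hwe_test(dm_mono), 1)
})
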