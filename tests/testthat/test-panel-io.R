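test_that("built-in panel has 13 SNPs in 8 locus groups with valid alleles", {
  panel <- amd_panel()
  expect_s3_class(panel, "snp_panel")
  expect_equal(nrow(panel), 13)
  expect_equal(length(unique(panel$locus_group)), 8)
  expect_false(any(panel$risk_allele == panel$other_allele))
  expect_false(anyDuplicated(panel$snp_id) > 0)
  expect_true(all(panel$control_freq > 0 & panel$control_freq < 1))
  expect_true(all(panel$or_per_allele > 1))
})

test_that("panel loading validates records and rejects malformed configs", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "snps:",
    "  - snp_id: rs1",
    "    gene_label: GENE1",
    "    locus_group: L1",
    "    risk_allele: T",
    "    other_allele: C"
  ), f)
  p <- load_panel(f)
  expect_equal(nrow(p), 1)
  expect_equal(p$risk_allele, "T")

  expect_error(
    snp_panel(tibble::tibble(
      snp_id = "rs1", gene_label = "G", locus_group = "L",
      risk_allele = "C", other_allele = "C"
    )),
    "risk_allele equals other_allele"
  )
  expect_error(
    snp_panel(tibble::tibble(
      snp_id = c("rs1", "rs1"), gene_label = "G", locus_group = "L",
      risk_allele = "C", other_allele = "T"
    )),
    "Duplicate"
  )
  g <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("snps:", "  - snp_id: rs1", "    gene_label: GENE1"), g)
  expect_error(load_panel(g), "missing")
})

test_that("genotype tables parse, validate the dosage domain, and localize errors", {
  panel <- make_test_panel(2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "subject_id\tstatus\tsnp1\tsnp2",
    "a\tcase\t0\t2",
    "b\tcase\t1\t1",
    "c\tcontrol\t2\t0",
    "d\tcontrol\t0\t1"
  ), f)
  st <- read_genotype_table(f, panel)
  expect_equal(nrow(st), 4)
  expect_equal(st$snp1, c(0L, 1L, 2L, 0L))
  expect_equal(st$status, c("case", "case", "control", "control"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "subject_id\tstatus\tsnp1\tsnp2",
    "a\tcase\t0\t3",
    "b\tcontrol\t1\t1"
  ), bad)
  expect_error(read_genotype_table(bad, panel), "row 1, column snp2")

  missing_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tstatus\tsnp1", "a\tcase\t0"), missing_col)
  expect_error(read_genotype_table(missing_col, panel), "snp2")
})

test_that("write then read round-trips a simulated cohort and is byte-stable", {
  panel <- make_test_panel(3)
  st <- simulate_from_group_freqs(
    case_freqs = c(0.6, 0.3, 0.9), control_freqs = c(0.4, 0.3, 0.85),
    n_cases = 60, n_controls = 40, seed = 7, panel = panel
  )
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(st, f1)
  back <- read_genotype_table(f1, panel)
  expect_equal(as.data.frame(back), as.data.frame(st))
  write_genotype_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("covariates survive the round trip and subtype is cases-only", {
  panel <- make_test_panel(1)
  d <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    status = c("case", "case", "control"),
    age_years = c(70, 81, 75),
    sex = c("F", "M", "F"),
    subtype = c("GA", "mixed", NA),
    snp1 = c(0L, 2L, 1L)
  )
  st <- case_control_study(d, panel)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(st, f)
  back <- read_genotype_table(f, panel)
  expect_equal(back$subtype, c("GA", "mixed", NA))
  expect_equal(back$age_years, c(70, 81, 75))

  d$subtype[3] <- "GA"
  expect_error(case_control_study(d, panel), "only for cases")
})

test_that("VCF import counts risk alleles and rejects missing genotypes", {
  skip_if_not_installed("vcfR")
  panel <- snp_panel(tibble::tibble(
    snp_id = c("rs1", "rs2"), gene_label = c("G1", "G2"),
    locus_group = c("L1", "L2"),
    risk_allele = c("C", "T"), other_allele = c("T", "G")
  ))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trs1\tT\tC\t.\tPASS\t.\tGT\t0/1\t1|1",
    "2\t200\trs2\tT\tG\t.\tPASS\t.\tGT\t0/0\t0/1"
  ), f)
  st <- read_vcf_dosages(f, panel, status = c("case", "control"))
  # rs1: risk allele is ALT -> count 1-codes; rs2: risk allele is REF
  expect_equal(st$rs1, c(1L, 2L))
  expect_equal(st$rs2, c(2L, 1L))

  g <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\trs1\tT\tC\t.\tPASS\t.\tGT\t./.",
    "2\t200\trs2\tT\tG\t.\tPASS\t.\tGT\t0/1"
  ), g)
  expect_error(read_vcf_dosages(g, panel, status = "case"), "Missing genotype")
})
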