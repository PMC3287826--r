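test_that("VCF genotypes convert to alt-allele dosage", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
           "1\t100\tSNP1\tT\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
           "1\t200\tSNP2\tG\tC\t.\tPASS\t.\tGT\t0|1\t./.\t0/0")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_genotype_matrix(path)
  expect_equal(unname(g$calls[, "SNP1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$calls[, "SNP2"]), c(1L, NA, 0L))
  expect_equal(g$counted_allele, c("A", "C"))
  expect_equal(g$other_allele, c("T", "G"))
  expect_equal(g$subjects, c("S1", "S2", "S3"))
})

test_that("multi-allelic VCF records are rejected", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
           "1\t100\tSNP1\tT\tA,G\t.\tPASS\t.\tGT\t1/2")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_error(read_genotype_matrix(path), "multi-allelic")
})

test_that("out-of-range and malformed TSV calls are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tSNP1\tSNP2", "S1\t0\t3", "S2\t1\t0"), path)
  expect_error(read_genotype_matrix(path), "invalid call 3")
  writeLines(c("subject\tSNP1", "S1\tx"), path)
  expect_error(read_genotype_matrix(path), "parse error.*line 2")
  expect_error(
    genotype_matrix(matrix(0L, 2, 1, dimnames = list(c("S1", "S1"), "A"))),
    "duplicate subject")
  expect_error(
    genotype_matrix(matrix(0L, 1, 2, dimnames = list("S1", c("A", "A")))),
    "duplicate SNP")
})

test_that("TSV round trip reproduces a simulated matrix exactly", {
  sim <- three_pop_sim(n_genes = 4L, seed = 11L)$sim
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(sim$geno, path)
  back <- read_genotype_tsv_full(path)
  expect_identical(back$calls, sim$geno$calls)
  expect_identical(back$counted_allele, sim$geno$counted_allele)
  expect_identical(back$other_allele, sim$geno$other_allele)
  # a second round trip is idempotent
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("gene map reader validates labels and uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tgene\tfunction",
               "C1S8678\tCFH\tNonsynonymous",
               "C1S8684\tCFH\tSynonymous"), path)
  gm <- read_gene_map(path)
  expect_equal(sum(gm$gene == "CFH"), 2L)
  expect_setequal(gm$func, c("nonsynonymous", "synonymous"))

  writeLines("snp\tgene\tfunction", path)
  expect_warning(gm0 <- read_gene_map(path), "empty")
  expect_equal(nrow(gm0), 0L)

  writeLines(c("snp\tgene\tfunction", "C1S1\tX\tIntronic"), path)
  expect_error(read_gene_map(path), "intronic")

  expect_error(gene_map(c("a", "a"), c("G1", "G2"),
                        c("synonymous", "synonymous")),
               "mapped more than once")
})

test_that("minor allele frequency is computed within the subset", {
  g <- tiny_geno()
  r <- compute_minor_allele_freq(g, "C1S1")
  expect_equal(r$maf, 3 / 6)
  expect_equal(r$minor_allele, "A")  # tie broken toward the counted allele

  r2 <- compute_minor_allele_freq(g, "C1S1", subjects = c("S1", "S2", "S3")[1:2])
  expect_equal(r2$maf, 1 / 4)

  # dosages (0,0,1) -> 1/6
  calls <- matrix(c(0L, 0L, 1L), 3, 1,
                  dimnames = list(paste0("I", 1:3), "s"))
  r3 <- compute_minor_allele_freq(genotype_matrix(calls), "s")
  expect_equal(r3$maf, 1 / 6)

  # monomorphic for the counted allele flips the minor label
  r4 <- compute_minor_allele_freq(g, "C1S2")
  expect_equal(r4$maf, 0)
  expect_equal(r4$minor_allele, "G")

  # missing calls are excluded from the denominator
  r5 <- compute_minor_allele_freq(g, "C1S3")
  expect_equal(r5$n_called, 2L)
  expect_equal(r5$maf, 1 / 4)

  calls_na <- matrix(NA_integer_, 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(compute_minor_allele_freq(genotype_matrix(calls_na), "s"),
               "all calls missing")
})

test_that("MAF is invariant to swapping the counted allele and bounded", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    d <- sample(0:2, n, replace = TRUE)
    d[sample(n, rbinom(1, 2, 0.5))] <- NA
    if (all(is.na(d))) d[1] <- 1L
    g1 <- genotype_matrix(matrix(d, ncol = 1,
                                 dimnames = list(sprintf("I%02d", 1:n), "s")))
    g2 <- genotype_matrix(matrix(2L - d, ncol = 1,
                                 dimnames = list(sprintf("I%02d", 1:n), "s")))
    m1 <- compute_minor_allele_freq(g1, "s")
    m2 <- compute_minor_allele_freq(g2, "s")
    expect_equal(m1$maf, m2$maf)
    expect_gte(m1$maf, 0)
    expect_lte(m1$maf, 0.5)
  }
})

test_that("estimated MAF matches the binomial sampling oracle", {
  set.seed(7)
  n <- 2000
  d <- rbinom(n, 2, 0.10)
  g <- genotype_matrix(matrix(d, ncol = 1,
                              dimnames = list(sprintf("I%04d", 1:n), "s")))
  m <- compute_minor_allele_freq(g, "s")
  expect_lt(abs(m$maf - 0.10), 3 * sqrt(0.1 * 0.9 / (2 * n)))
})

test_that("phenotype table validation enforces coding and uniqueness", {
  df <- data.frame(subject = c("a", "b"), replicate = 1L,
                   affected = c(0L, 1L), Q1 = 0, Q2 = 0, Q4 = 0,
                   age = 50, sex = c(0L, 1L), smoke = 0L)
  expect_s3_class(phenotype_table(df), "phenotype_table")
  bad <- df; bad$affected[1] <- 2L
  expect_error(phenotype_table(bad), "affected")
  bad2 <- rbind(df, df[1, ])
  expect_error(phenotype_table(bad2), "unique")
  expect_error(phenotype_table(df[, -4]), "missing column")
})
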