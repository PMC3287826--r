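test_that("variant indicator flags carriers and maps missing to zero", {
  expect_identical(variant_indicator(c(0L, 1L, 2L, NA)), c(0L, 1L, 1L, 0L))
})

test_that("collapse_gene sums carrier indicators over a gene's SNPs", {
  calls <- rbind(S1 = c(1L, 0L, 2L),   # carries minor allele at 2 SNPs
                 S2 = c(0L, 0L, 0L),
                 S3 = c(0L, 1L, 0L),
                 S4 = c(0L, 0L, 0L))
  colnames(calls) <- paste0("C1S", 1:3)
  g <- genotype_matrix(calls)
  map <- gene_map(colnames(calls), rep("G1", 3),
                  c("nonsynonymous", "synonymous", "nonsynonymous"))
  cc <- collapse_gene(g, "G1", map)
  expect_equal(cc$counts, c(2L, 0L, 1L, 0L))
  expect_equal(cc$n_snps_used, 3L)

  # nonsynonymous-only filter drops the middle SNP
  cc_ns <- collapse_gene(g, "G1", map, filter = "nonsynonymous")
  expect_equal(cc_ns$n_snps_used, 2L)
  expect_equal(cc_ns$counts, c(2L, 0L, 0L, 0L))

  # all subjects homozygous major -> all counts zero
  g0 <- genotype_matrix(matrix(0L, 4, 2,
                               dimnames = list(paste0("S", 1:4), c("a", "b"))))
  cc0 <- collapse_gene(g0, "G", gene_map(c("a", "b"), c("G", "G"),
                                         rep("synonymous", 2)))
  expect_equal(cc0$counts, rep(0L, 4))
})

test_that("collapsed counts match a brute-force double-loop recount", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 50; s <- 8
    calls <- matrix(rbinom(n * s, 2, runif(s, 0.02, 0.9)[rep(1:s, each = n)]),
                    n, s, dimnames = list(sprintf("I%02d", 1:n),
                                          sprintf("C1S%d", 1:s)))
    g <- genotype_matrix(calls)
    map <- gene_map(colnames(calls), rep("G", s),
                    sample(c("synonymous", "nonsynonymous"), s, replace = TRUE))
    subs <- sample(g$subjects, sample(10:n, 1))
    filt <- sample(c("all", "nonsynonymous"), 1)
    cc <- suppressWarnings(collapse_gene(g, "G", map, subjects = subs,
                                         filter = filt))
    oracle <- brute_collapse(g, "G", map, subs, filter = filt)
    if (is.null(cc)) {
      expect_null(oracle)
    } else {
      expect_equal(cc$counts, oracle)
      # conservation: total counts = number of carrier pairs
      expect_equal(sum(cc$counts), sum(oracle))
    }
  }
})

test_that("counts are invariant to SNP order and to monomorphic additions", {
  set.seed(12)
  n <- 30
  calls <- matrix(rbinom(n * 4, 2, 0.2), n, 4,
                  dimnames = list(sprintf("I%02d", 1:n), paste0("s", 1:4)))
  g <- genotype_matrix(calls)
  map <- gene_map(paste0("s", 1:4), rep("G", 4), rep("nonsynonymous", 4))
  base <- collapse_gene(g, "G", map)

  perm <- c(3, 1, 4, 2)
  g2 <- genotype_matrix(calls[, perm])
  map2 <- gene_map(paste0("s", perm), rep("G", 4), rep("nonsynonymous", 4))
  expect_equal(collapse_gene(g2, "G", map2)$counts, base$counts)

  # a SNP with zero minor-allele dosage throughout never changes counts
  calls3 <- cbind(calls, s5 = 0L)
  map3 <- gene_map(paste0("s", 1:5), rep("G", 5), rep("nonsynonymous", 5))
  expect_equal(collapse_gene(genotype_matrix(calls3), "G", map3)$counts,
               base$counts)
})

test_that("minor-allele orientation flips between divergent groups", {
  # one SNP with counted-allele frequency 0.98 in group A, 0.02 in group B
  set.seed(8)
  nA <- 100; nB <- 160  # unequal sizes keep the pooled frequency below 0.5
  d <- c(rbinom(nA, 2, 0.98), rbinom(nB, 2, 0.02))
  subj <- sprintf("I%03d", seq_len(nA + nB))
  g <- genotype_matrix(matrix(d, ncol = 1, dimnames = list(subj, "C1S8678")),
                       counted_allele = "A", other_allele = "G")
  map <- gene_map("C1S8678", "CFH", "nonsynonymous")
  A <- subj[1:nA]; B <- subj[nA + 1:nB]

  mA <- compute_minor_allele_freq(g, "C1S8678", A)
  mB <- compute_minor_allele_freq(g, "C1S8678", B)
  expect_equal(mA$minor_allele, "G")
  expect_equal(mB$minor_allele, "A")

  # pooled vs per-group collapsing differ exactly where the orientation flips
  ccA <- collapse_gene(g, "CFH", map, subjects = A)
  pooled <- collapse_gene(g, "CFH", map)
  mPool <- compute_minor_allele_freq(g, "C1S8678")
  expect_false(identical(ccA$counts, pooled$counts[1:nA]))
  # within A the carriers are of the allele rare in A
  expect_equal(ccA$counts, as.integer(d[1:nA] <= 1))
})

test_that("collapse_all skips filtered-out genes and matches collapse_gene", {
  calls <- matrix(rbinom(40, 2, 0.3), 10, 4,
                  dimnames = list(sprintf("I%02d", 1:10), paste0("s", 1:4)))
  g <- genotype_matrix(calls)
  map <- gene_map(paste0("s", 1:4), c("A", "A", "B", "B"),
                  c("nonsynonymous", "synonymous", "synonymous", "synonymous"))
  all_genes <- collapse_all(g, map)
  expect_named(all_genes, c("A", "B"))
  ns <- collapse_all(g, map, filter = "nonsynonymous")
  expect_named(ns, "A")
  expect_equal(attr(ns, "skipped"), "B")
  expect_equal(ns$A$counts,
               collapse_gene(g, "A", map, filter = "nonsynonymous")$counts)
})

test_that("the MAF ceiling excludes common variants from the burden", {
  set.seed(3)
  calls <- cbind(rare = rbinom(200, 2, 0.01), common = rbinom(200, 2, 0.4))
  rownames(calls) <- sprintf("I%03d", 1:200)
  g <- genotype_matrix(calls)
  map <- gene_map(c("rare", "common"), c("G", "G"), rep("nonsynonymous", 2))
  cc <- collapse_gene(g, "G", map, maf_max = 0.05)
  expect_equal(cc$snps_used, "rare")
  expect_equal(cc$counts, unname(as.integer(calls[, "rare"] >= 1)))
})
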