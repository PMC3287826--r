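# Shared fixtures and independent oracles, built in code at test time.

# Small hand-specified genotype matrix.
tiny_geno <- function() {
  calls <- rbind(S1 = c(0L, 2L, 1L),
                 S2 = c(1L, 2L, 0L),
                 S3 = c(2L, 2L, NA))
  colnames(calls) <- c("C1S1", "C1S2", "C1S3")
  genotype_matrix(calls, counted_allele = c("A", "C", "G"),
                  other_allele = c("T", "G", "A"))
}

# Brute-force collapsing oracle: explicit double loop over (subject, SNP),
# recomputing the subset minor allele per SNP by direct counting.
brute_collapse <- function(geno, gene, map, subjects, filter = "all",
                           maf_max = NULL) {
  snps <- map$snp[map$gene == gene]
  if (filter == "nonsynonymous")
    snps <- intersect(snps, map$snp[map$func == "nonsynonymous"])
  keep <- character()
  for (s in snps) {
    d <- geno$calls[match(subjects, geno$subjects), match(s, geno$snps)]
    f <- sum(d, na.rm = TRUE) / (2 * sum(!is.na(d)))
    maf <- min(f, 1 - f)
    if (is.null(maf_max) || maf <= maf_max) keep <- c(keep, s)
  }
  if (length(keep) == 0) return(NULL)
  counts <- integer(length(subjects))
  for (ii in seq_along(subjects)) {
    for (s in keep) {
      d <- geno$calls[match(subjects, geno$subjects), match(s, geno$snps)]
      f <- sum(d, na.rm = TRUE) / (2 * sum(!is.na(d)))
      di <- d[ii]
      if (f > 0.5) di <- 2L - di          # orient to the subset minor allele
      if (!is.na(di) && di >= 1) counts[ii] <- counts[ii] + 1L
    }
  }
  counts
}

# Term-by-term ZIP log-likelihood: direct density evaluation, no log-space
# rearrangement, independent of the package's stabilized path.
naive_zip_loglik <- function(gamma, beta, design) {
  a <- drop(design$Xz %*% gamma)
  p <- 1 / (1 + exp(-a))
  mu <- exp(drop(design$Xm %*% beta))
  y <- design$y
  f <- ifelse(y == 0,
              p + (1 - p) * exp(-mu),
              (1 - p) * exp(-mu) * mu^y / factorial(y))
  sum(log(f))
}

# Intercept-only ZIP maximum likelihood via the zero-fraction / mean system:
# mean(y) = (1 - p) mu and P(0) = p + (1 - p) exp(-mu), solved for mu by
# uniroot. Returns c(p, mu).
zip_moment_mle <- function(y) {
  z <- mean(y == 0)
  mb <- mean(y)
  g <- function(mu) {
    p <- (z - exp(-mu)) / (1 - exp(-mu))
    (1 - p) * mu - mb
  }
  lo <- mb + 1e-8
  hi <- max(-log(max(1e-12, z)) + 10, lo + 1)
  mu <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  p <- (z - exp(-mu)) / (1 - exp(-mu))
  c(p = p, mu = mu)
}

# Random design + coefficients for ZIP fitter tests.
random_zip_case <- function(n, seed, k = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", seq_len(k))))
  gamma <- c(-1, 0.5, rep(0.2, k - 1))
  beta <- c(0.2, 0.4, rep(0.1, k - 1))
  y <- simulate_zip_counts(cbind(1, X), cbind(1, X), gamma, beta, seed = seed)
  list(design = zip_design(y, X), gamma = gamma, beta = beta)
}

# Genotype simulation with three well-separated populations.
three_pop_sim <- function(n_genes = 12L, seed = 5L, pop_sizes = c(A = 60L, B = 60L, C = 60L),
                          divergence_sd = 3) {
  des <- simulation_design(pop_sizes = pop_sizes, n_genes = n_genes,
                           divergence_sd = divergence_sd, seed = seed,
                           n_replicates = 2L)
  list(design = des, sim = simulate_genotypes(des))
}
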