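# Genotype PCA for stratification control: eigenvector covariates,
# outlier detection, and ancestry-group assignment.
#
# Columns are standardized the way Eigenstrat does — centered at twice the
# allele frequency and scaled by the binomial SD sqrt(2f(1-f)) — and the
# top-K left singular vectors of the standardized matrix are used both as
# regression covariates and (top 2, via k-means) for grouping subjects.

#' Principal components of a standardized genotype matrix
#'
#' @param geno a [genotype_matrix].
#' @param k number of eigenvectors to return (default 10).
#' @param subjects optional subject subset.
#' @param exclude_snps optional SNP IDs to leave out of the decomposition.
#'   Rare variants private to one ancestry are maximally ancestry-informative,
#'   so they dominate the PC loadings; adjusting a gene's burden test for PCs
#'   computed *including* that gene's own SNPs then absorbs the very signal
#'   under test. Excluding the tested region (leave-one-gene-out PCA) keeps
#'   the eigenvectors a pure background-ancestry adjustment.
#' @return object of class `eigen_decomposition`: `subjects`, `vectors`
#'   (N x k orthonormal, columns `PC1..PCk`), `values` (eigenvalues of the
#'   subject covariance, descending), `snps_used`.
#' @export
compute_eigenvectors <- function(geno, k = 10L, subjects = NULL,
                                 exclude_snps = NULL) {
  if (is.null(subjects)) subjects <- geno$subjects
  if (!is.null(exclude_snps)) {
    keep <- !(geno$snps %in% exclude_snps)
    if (!any(keep)) stop("exclude_snps removes every SNP")
    geno$snps <- geno$snps[keep]
    geno$calls <- geno$calls[, keep, drop = FALSE]
    geno$counted_allele <- geno$counted_allele[keep]
    geno$other_allele <- geno$other_allele[keep]
  }
  i <- match(subjects, geno$subjects)
  if (anyNA(i)) stop("unknown subject(s): ",
                     paste(subjects[is.na(i)], collapse = ", "))
  n <- length(subjects)
  if (n < k + 1) stop("need at least k + 1 subjects (n = ", n, ", k = ", k, ")")
  X <- geno$calls[i, , drop = FALSE]
  storage.mode(X) <- "double"
  # mean-impute missing calls, then center/scale at the allele frequency
  cm <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- cm[idx[, 2]]
  }
  f <- cm / 2
  poly <- is.finite(f) & f > 0 & f < 1
  if (!any(poly)) stop("all SNPs are monomorphic in the subset")
  X <- X[, poly, drop = FALSE]
  f <- f[poly]
  S <- sweep(X, 2, 2 * f, "-")
  S <- sweep(S, 2, sqrt(2 * f * (1 - f)), "/")
  G <- tcrossprod(S) / ncol(S)
  e <- eigen(G, symmetric = TRUE)
  k <- as.integer(k)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(k)) {
    m <- which.max(abs(vec[, j]))
    if (vec[m, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("PC", seq_len(k))
  rownames(vec) <- subjects
  structure(list(subjects = subjects, vectors = vec,
                 values = pmax(e$values[seq_len(k)], 0),
                 snps_used = geno$snps[poly]),
            class = "eigen_decomposition")
}

#' @export
print.eigen_decomposition <- function(x, ...) {
  cat(sprintf("eigen_decomposition: %d subjects, %d PCs, %d SNPs used\n",
              length(x$subjects), ncol(x$vectors), length(x$snps_used)))
  invisible(x)
}

#' Iterative PCA outlier detection
#'
#' Subjects farther than `sd_threshold` standard deviations from the mean
#' along any of the top `k` PCs are flagged and removed, the decomposition
#' is recomputed on the remainder, and the process repeats up to
#' `n_iterations` times or until no subject is flagged.
#'
#' @param geno a [genotype_matrix].
#' @param k PCs to scan (default 10).
#' @param sd_threshold flagging threshold in SDs (default 6).
#' @param n_iterations maximum removal rounds (default 5).
#' @param subjects optional starting subset.
#' @return character vector of outlier subject IDs (possibly empty).
#' @export
detect_outliers <- function(geno, k = 10L, sd_threshold = 6,
                            n_iterations = 5L, subjects = NULL) {
  if (sd_threshold <= 0) stop("sd_threshold must be positive")
  keep <- if (is.null(subjects)) geno$subjects else subjects
  outliers <- character()
  if (!is.finite(sd_threshold)) return(outliers)
  for (it in seq_len(n_iterations)) {
    if (length(keep) < k + 2)
      stop("outlier removal would leave too few subjects")
    eig <- compute_eigenvectors(geno, k = k, subjects = keep)
    sc <- scale(eig$vectors)
    flag <- apply(abs(sc) > sd_threshold, 1, any)
    if (!any(flag)) break
    outliers <- c(outliers, keep[flag])
    keep <- keep[!flag]
    if (length(keep) == 0) stop("outlier removal emptied the sample")
  }
  outliers
}

#' Assign subjects to ancestry groups
#'
#' Either passes user-supplied labels through verbatim, or k-means on the
#' top two PCs (fixed seed, `nstart` restarts so empty clusters are
#' avoided).
#'
#' @param eig an [compute_eigenvectors()] result.
#' @param n_groups number of groups for k-means.
#' @param labels optional named vector of user labels (names = subject IDs);
#'   returned verbatim when supplied.
#' @param seed RNG seed for k-means (default 1).
#' @param nstart k-means restarts (default 10).
#' @return named character vector: subject ID -> group label.
#' @export
assign_groups <- function(eig, n_groups = NULL, labels = NULL, seed = 1L,
                          nstart = 10L) {
  if (!is.null(labels)) {
    miss <- setdiff(eig$subjects, names(labels))
    if (length(miss)) stop("labels missing for subject(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    return(structure(as.character(labels[eig$subjects]),
                     names = eig$subjects))
  }
  if (is.null(n_groups) || n_groups < 1) stop("n_groups must be >= 1")
  n <- length(eig$subjects)
  if (n_groups > n) stop("n_groups exceeds the number of subjects")
  if (n_groups == 1)
    return(structure(rep("G1", n), names = eig$subjects))
  xy <- eig$vectors[, seq_len(min(2L, ncol(eig$vectors))), drop = FALSE]
  km <- with_local_seed(seed, stats::kmeans(xy, centers = n_groups,
                                            nstart = nstart))
  structure(paste0("G", km$cluster), names = eig$subjects)
}

#' Write eigenvectors as TSV (subject, PC1..PCk)
#' @param eig an `eigen_decomposition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eigenvectors <- function(eig, path) {
  df <- data.frame(subject = eig$subjects, eig$vectors, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read eigenvectors from TSV, e.g. precomputed external covariates
#' @param path file with columns subject, PC1..PCk.
#' @return an `eigen_decomposition` (eigenvalues `NA`, `snps_used` empty).
#' @export
read_eigenvectors <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject") stop("first column must be `subject`: ", path)
  vec <- as.matrix(df[, -1, drop = FALSE])
  rownames(vec) <- df$subject
  structure(list(subjects = as.character(df$subject), vectors = vec,
                 values = rep(NA_real_, ncol(vec)), snps_used = character()),
            class = "eigen_decomposition")
}
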