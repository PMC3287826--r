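# Minor-allele frequency, computed within the analysis subset in use.
#
# The minor allele of a SNP is subset-dependent: a variant rare in one
# ancestry group can be the major allele in another, so every MAF here is
# computed (and the minor allele labelled) relative to an explicit subject
# subset, and collapsing re-orients dosages within that subset.

#' Minor-allele frequency of one SNP within a subject subset
#'
#' Frequency of the less-common allele among non-missing calls in the
#' subset. Ties at 0.5 are broken toward the counted allele. Monomorphic
#' SNPs get MAF 0 with the minor allele reported as whichever allele is
#' absent.
#'
#' @param geno a [genotype_matrix].
#' @param snp SNP ID.
#' @param subjects subject IDs defining the analysis subset (default: all).
#' @return a list of class `maf_record`: `snp`, `minor_allele`, `maf`,
#'   `n_called`, `counted_is_minor`, `subset_n`.
#' @export
compute_minor_allele_freq <- function(geno, snp, subjects = NULL) {
  j <- match(snp, geno$snps)
  if (is.na(j)) stop("SNP not present: ", snp)
  if (is.null(subjects)) subjects <- geno$subjects
  if (length(subjects) == 0) stop("subject subset is empty")
  i <- match(subjects, geno$subjects)
  if (anyNA(i)) stop("unknown subject(s): ",
                     paste(subjects[is.na(i)], collapse = ", "))
  d <- geno$calls[i, j]
  n_called <- sum(!is.na(d))
  if (n_called == 0) stop("all calls missing for SNP ", snp, " in subset")
  f_counted <- sum(d, na.rm = TRUE) / (2 * n_called)
  counted_is_minor <- f_counted <= 0.5  # tie goes to the counted allele
  structure(list(
    snp = snp,
    minor_allele = if (counted_is_minor) geno$counted_allele[j] else geno$other_allele[j],
    maf = if (counted_is_minor) f_counted else 1 - f_counted,
    n_called = n_called,
    counted_is_minor = counted_is_minor,
    subset_n = length(subjects)
  ), class = "maf_record")
}

# Vectorised MAF over all SNPs for a subject subset. Returns a data.frame
# with one row per SNP; used by collapsing and PCA scaling. SNPs with all
# calls missing get NA maf (flagged downstream).
maf_table <- function(geno, subjects = NULL) {
  if (is.null(subjects)) subjects <- geno$subjects
  i <- match(subjects, geno$subjects)
  if (anyNA(i)) stop("unknown subject(s): ",
                     paste(subjects[is.na(i)], collapse = ", "))
  calls <- geno$calls[i, , drop = FALSE]
  n_called <- colSums(!is.na(calls))
  f_counted <- colSums(calls, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  f_counted[n_called == 0] <- NA_real_
  counted_is_minor <- !is.na(f_counted) & f_counted <= 0.5
  data.frame(
    snp = geno$snps,
    f_counted = f_counted,
    maf = ifelse(counted_is_minor, f_counted, 1 - f_counted),
    counted_is_minor = counted_is_minor,
    minor_allele = ifelse(counted_is_minor, geno$counted_allele, geno$other_allele),
    n_called = n_called,
    stringsAsFactors = FALSE
  )
}
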