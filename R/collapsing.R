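# Rare-variant collapsing: per-SNP carrier indicators summed within genes.
#
# For each SNP the dosage is first oriented to the minor allele of the
# analysis subset; the carrier indicator is 1 when at least one copy of
# that minor allele is present. Summing indicators over a gene's SNPs gives
# the per-subject count that is the outcome of the zero-inflated Poisson
# model. Missing calls contribute 0 (a subject is never counted as a
# carrier of an unobserved variant).

#' Carrier indicator for a minor-allele dosage
#'
#' @param dosage integer vector of minor-allele copies (0/1/2), `NA` for
#'   missing.
#' @return integer vector of 0/1: 1 when at least one minor allele is
#'   carried, 0 otherwise; missing maps to 0.
#' @export
variant_indicator <- function(dosage) {
  out <- as.integer(!is.na(dosage) & dosage >= 1)
  out
}

#' Collapse rare variants of one gene into per-subject counts
#'
#' @param geno a [genotype_matrix].
#' @param gene gene symbol present in `gene_map`.
#' @param gene_map a [gene_map] data.frame.
#' @param subjects subject subset (default: all). Minor alleles are
#'   re-determined within this subset.
#' @param filter `"all"` or `"nonsynonymous"`: which function classes to
#'   collapse.
#' @param maf_max optional MAF ceiling in (0, 0.5]; SNPs whose subset MAF
#'   exceeds it are excluded. Default `NULL` collapses every minor allele.
#' @param dosage if `TRUE`, sum minor-allele copies instead of carrier
#'   indicators (sensitivity analysis; the default indicator coding is the
#'   method proper).
#' @return an object of class `collapsed_counts`: `gene`, `subjects`,
#'   `counts`, `n_snps_used`, `snps_used`, `filter`, `maf_max`,
#'   `n_missing_calls`. `NULL` with a warning if no SNP passes the filter.
#' @export
collapse_gene <- function(geno, gene, gene_map, subjects = NULL,
                          filter = c("all", "nonsynonymous"),
                          maf_max = NULL, dosage = FALSE) {
  filter <- match.arg(filter)
  if (is.null(subjects)) subjects <- geno$subjects
  if (length(subjects) == 0) stop("subject subset is empty")
  rows <- gene_map[gene_map$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0) stop("gene not in gene map: ", gene)
  if (filter == "nonsynonymous")
    rows <- rows[rows$func == "nonsynonymous", , drop = FALSE]
  snps <- intersect(rows$snp, geno$snps)
  mt <- NULL
  if (length(snps)) {
    mt <- maf_table(geno, subjects)
    if (!is.null(maf_max)) {
      m <- mt$maf[match(snps, mt$snp)]
      snps <- snps[!is.na(m) & m <= maf_max]
    }
  }
  if (length(snps) == 0) {
    warning("gene ", gene, ": no SNPs pass the active filter; skipped")
    return(NULL)
  }
  collapse_counts_core(geno, gene, snps, subjects, filter, maf_max, dosage,
                       mt = mt)
}

collapse_counts_core <- function(geno, gene, snps, subjects, filter,
                                 maf_max, dosage, mt = NULL) {
  i <- match(subjects, geno$subjects)
  if (anyNA(i)) stop("unknown subject(s): ",
                     paste(subjects[is.na(i)], collapse = ", "))
  j <- match(snps, geno$snps)
  calls <- geno$calls[i, j, drop = FALSE]
  if (is.null(mt)) mt <- maf_table(geno, subjects)
  flip <- !mt$counted_is_minor[j]
  # orient each column to the subset's minor allele
  if (any(flip))
    calls[, flip] <- 2L - calls[, flip, drop = FALSE]
  n_missing <- sum(is.na(calls))
  if (dosage) {
    calls[is.na(calls)] <- 0L
    counts <- as.integer(rowSums(calls))
  } else {
    ind <- matrix(variant_indicator(calls), nrow = nrow(calls))
    counts <- as.integer(rowSums(ind))
  }
  structure(list(gene = gene, subjects = subjects, counts = counts,
                 n_snps_used = length(snps), snps_used = snps,
                 filter = filter, maf_max = maf_max,
                 n_missing_calls = n_missing),
            class = "collapsed_counts")
}

#' @export
print.collapsed_counts <- function(x, ...) {
  cat(sprintf("collapsed_counts: gene %s, %d subjects, %d SNPs, filter=%s%s\n",
              x$gene, length(x$subjects), x$n_snps_used, x$filter,
              if (is.null(x$maf_max)) "" else sprintf(", maf<=%g", x$maf_max)))
  invisible(x)
}

#' Collapse every gene in a map
#'
#' Genes with no SNPs passing the filter are skipped (not assigned zero
#' counts) so the tested-gene count used for Bonferroni correction reflects
#' the tests actually performed.
#'
#' @inheritParams collapse_gene
#' @return named list of [collapse_gene()] results in lexicographic gene
#'   order; skipped genes are absent and recorded in the
#'   `"skipped"` attribute.
#' @export
collapse_all <- function(geno, gene_map, subjects = NULL,
                         filter = c("all", "nonsynonymous"),
                         maf_max = NULL, dosage = FALSE) {
  filter <- match.arg(filter)
  if (is.null(subjects)) subjects <- geno$subjects
  genes <- sort(unique(gene_map$gene))
  mt <- maf_table(geno, subjects)
  out <- vector("list", length(genes))
  names(out) <- genes
  skipped <- character()
  for (g in genes) {
    rows <- gene_map[gene_map$gene == g, , drop = FALSE]
    if (filter == "nonsynonymous")
      rows <- rows[rows$func == "nonsynonymous", , drop = FALSE]
    snps <- intersect(rows$snp, geno$snps)
    if (length(snps) && !is.null(maf_max)) {
      m <- mt$maf[match(snps, mt$snp)]
      snps <- snps[!is.na(m) & m <= maf_max]
    }
    if (length(snps) == 0) { skipped <- c(skipped, g); next }
    out[[g]] <- collapse_counts_core(geno, g, snps, subjects, filter,
                                     maf_max, dosage, mt = mt)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "skipped") <- skipped
  out
}

#' Write collapsed counts as a subjects-by-genes TSV
#'
#' @param collapsed a named list from [collapse_all()].
#' @param path output path. Filter settings are embedded as header comments.
#' @return `path`, invisibly.
#' @export
write_collapsed_counts <- function(collapsed, path) {
  if (length(collapsed) == 0) stop("no collapsed genes to write")
  subjects <- collapsed[[1]]$subjects
  mat <- vapply(collapsed, function(cc) cc$counts, numeric(length(subjects)))
  con <- file(path, "w")
  on.exit(close(con))
  cc1 <- collapsed[[1]]
  writeLines(sprintf("#filter=%s maf_max=%s", cc1$filter,
                     if (is.null(cc1$maf_max)) "none" else cc1$maf_max), con)
  df <- data.frame(subject = subjects, mat, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
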