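# Genotype, gene-map and phenotype input/output.

#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds subject-by-SNP allele-count calls (dosage of the
#' counted allele, 0/1/2, `NA` for missing) together with per-SNP allele
#' labels. Calls are validated on construction: every non-missing call must
#' lie in \{0, 1, 2\} and subject/SNP identifiers must be unique.
#'
#' @param calls integer matrix, subjects in rows, SNPs in columns; entries in
#'   \{0, 1, 2\} or `NA`.
#' @param subjects character vector of subject IDs (defaults to rownames).
#' @param snps character vector of SNP IDs (defaults to colnames).
#' @param counted_allele per-SNP label of the allele the dosage counts
#'   (e.g. the VCF ALT allele).
#' @param other_allele per-SNP label of the remaining allele.
#' @return an object of class `genotype_matrix` with fields `subjects`,
#'   `snps`, `calls`, `counted_allele`, `other_allele`.
#' @export
genotype_matrix <- function(calls, subjects = rownames(calls),
                            snps = colnames(calls),
                            counted_allele = rep("A1", ncol(calls)),
                            other_allele = rep("A2", ncol(calls))) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(subjects) || is.null(snps))
    stop("subject and SNP identifiers are required")
  subjects <- as.character(subjects)
  snps <- as.character(snps)
  if (nrow(calls) != length(subjects) || ncol(calls) != length(snps))
    stop("dimensions of `calls` do not match subjects x snps")
  if (anyDuplicated(subjects))
    stop("duplicate subject IDs: ", paste(unique(subjects[duplicated(subjects)]), collapse = ", "))
  if (anyDuplicated(snps))
    stop("duplicate SNP IDs: ", paste(unique(snps[duplicated(snps)]), collapse = ", "))
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid call %d at subject %s, SNP %s: calls must be 0/1/2 or NA",
                 calls[bad][1], subjects[idx[1]], snps[idx[2]]))
  }
  if (length(counted_allele) != length(snps) || length(other_allele) != length(snps))
    stop("allele labels must have one entry per SNP")
  dimnames(calls) <- list(subjects, snps)
  structure(list(subjects = subjects, snps = snps, calls = calls,
                 counted_allele = as.character(counted_allele),
                 other_allele = as.character(other_allele)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%d missing calls)\n",
              length(x$subjects), length(x$snps), sum(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read a genotype matrix from VCF or TSV
#'
#' The TSV dialect has a header row of SNP IDs, the first column holding
#' subject IDs, and cells in \{0, 1, 2\} or `NA`. VCF input (v4.x) uses the
#' GT field converted to ALT-allele dosage; multi-allelic records are
#' rejected because the collapsing method is defined for biallelic SNPs.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`; guessed from the file extension by
#'   default.
#' @return a [genotype_matrix].
#' @export
read_genotype_matrix <- function(path, format = c("guess", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, tsv = read_genotype_tsv(path), vcf = read_genotype_vcf(path))
}

read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2) stop("genotype TSV needs a subject column plus >= 1 SNP column: ", path)
  subjects <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "integer")
  nonnum <- is.na(mat) & !(is.na(df[, -1, drop = FALSE]) |
                             df[, -1, drop = FALSE] == "NA")
  if (any(nonnum)) {
    ln <- which(rowSums(nonnum) > 0)[1] + 1L  # +1 for header line
    stop(sprintf("parse error in %s, line %d: non-numeric genotype call", path, ln))
  }
  genotype_matrix(mat, subjects = subjects, snps = colnames(df)[-1])
}

read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multi-allelic sites not supported: ",
         paste(fix[multi, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # gt is SNP x subject; convert GT strings to ALT-allele dosage
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al) || any(al > 1)) stop("unsupported GT code: ", g)
    sum(al)
  })
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(t(dose), subjects = colnames(gt), snps = ids,
                  counted_allele = alt, other_allele = fix[, "REF"])
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [read_genotype_matrix()] for the TSV dialect; allele labels are
#' stored as header comments so a round trip preserves them.
#'
#' @param geno a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#counted_allele\t", paste(geno$counted_allele, collapse = "\t")),
               paste0("#other_allele\t", paste(geno$other_allele, collapse = "\t"))), con)
  df <- data.frame(subject = geno$subjects, geno$calls, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype TSV written by [write_genotype_tsv()], restoring allele
#' labels from the header comments.
#' @param path file path.
#' @return a [genotype_matrix].
#' @export
read_genotype_tsv_full <- function(path) {
  hdr <- readLines(path, n = 2)
  g <- read_genotype_tsv(path)
  for (line in hdr[startsWith(hdr, "#")]) {
    parts <- strsplit(line, "\t")[[1]]
    key <- sub("^#", "", parts[1])
    if (key %in% c("counted_allele", "other_allele") &&
        length(parts) == length(g$snps) + 1L)
      g[[key]] <- parts[-1]
  }
  g
}

#' Read a SNP-to-gene annotation table
#'
#' Expects a tab-delimited file with columns `snp`, `gene`, `function`
#' (case-insensitive header). Function class must be `Synonymous` or
#' `Nonsynonymous` (case-insensitive); each SNP must map to exactly one gene.
#'
#' @param path file path.
#' @return a `gene_map` data.frame with columns `snp`, `gene`, `func`
#'   (normalised to lowercase labels).
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty gene map: ", path)
    return(gene_map(character(), character(), character()))
  }
  names(df) <- tolower(names(df))
  need <- c("snp", "gene")
  fn_col <- intersect(c("function.", "function", "func"), names(df))[1]
  if (!all(need %in% names(df)) || is.na(fn_col))
    stop("gene map must have columns snp, gene, function: ", path)
  gene_map(df$snp, df$gene, df[[fn_col]])
}

#' Construct and validate a gene map
#'
#' @param snp,gene,func parallel character vectors; `func` entries must be
#'   synonymous/nonsynonymous (case-insensitive).
#' @return a `gene_map` data.frame.
#' @export
gene_map <- function(snp, gene, func) {
  func <- tolower(as.character(func))
  bad <- setdiff(unique(func), c("synonymous", "nonsynonymous"))
  if (length(bad))
    stop("unknown function class label(s): ", paste(bad, collapse = ", "),
         " (allowed: Synonymous, Nonsynonymous)")
  snp <- as.character(snp); gene <- as.character(gene)
  if (anyDuplicated(snp)) {
    dup <- unique(snp[duplicated(snp)])
    stop("SNP(s) mapped more than once: ", paste(dup, collapse = ", "))
  }
  structure(data.frame(snp = snp, gene = gene, func = func,
                       stringsAsFactors = FALSE),
            class = c("gene_map", "data.frame"))
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited with columns `subject`, `replicate`, `affected`, `Q1`, `Q2`,
#' `Q4`, `age`, `sex`, `smoke`. `affected`, `sex` and `smoke` are 0/1;
#' (subject, replicate) pairs must be unique.
#'
#' @param path file path.
#' @return a data.frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  phenotype_table(df)
}

#' Validate a phenotype table
#' @param df data.frame with the columns documented in [read_phenotypes()].
#' @return the validated data.frame, classed `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  need <- c("subject", "replicate", "affected", "Q1", "Q2", "Q4",
            "age", "sex", "smoke")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$affected %in% 0:1)) stop("`affected` must be 0/1")
  if (!all(df$sex %in% 0:1)) stop("`sex` must be 0/1")
  if (!all(df$smoke %in% 0:1)) stop("`smoke` must be 0/1")
  if (anyDuplicated(df[, c("subject", "replicate")]))
    stop("(subject, replicate) pairs must be unique")
  df$subject <- as.character(df$subject)
  class(df) <- c("phenotype_table", "data.frame")
  df
}
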