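# Per-gene association scan, multiple-testing control, and replicate power.

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (genes actually tested).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a positive count")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / m
}

# Assemble the per-gene regression inputs: phenotype/trait value plus age,
# sex, smoking and the first n_pcs eigenvector columns, all entering both
# ZIP components. Age and eigenvectors are mean-centered for optimizer
# conditioning (Wald/LRT p-values are invariant to centering).
build_gene_design <- function(counts, pheno, trait, eig = NULL, n_pcs = 10L) {
  i <- match(counts$subjects, pheno$subject)
  if (anyNA(i))
    stop("phenotypes missing for subject(s): ",
         paste(utils::head(counts$subjects[is.na(i)], 5), collapse = ", "))
  ph <- pheno[i, , drop = FALSE]
  x <- switch(trait,
              disease = ph$affected,
              Q1 = ph$Q1, Q2 = ph$Q2, Q4 = ph$Q4,
              stop("unknown trait: ", trait))
  covs <- cbind(trait = x,
                age = ph$age - mean(ph$age),
                sex = ph$sex,
                smoke = ph$smoke)
  if (!is.null(eig) && n_pcs > 0) {
    j <- match(counts$subjects, eig$subjects)
    if (anyNA(j))
      stop("eigenvectors missing for subject(s): ",
           paste(utils::head(counts$subjects[is.na(j)], 5), collapse = ", "))
    pcs <- eig$vectors[j, seq_len(min(n_pcs, ncol(eig$vectors))), drop = FALSE]
    pcs <- sweep(pcs, 2, colMeans(pcs))
    covs <- cbind(covs, pcs)
  }
  zip_design(counts$counts, covs)
}

#' Test one gene's collapsed counts for trait association
#'
#' Fits the ZIP regression of the gene's counts on the trait plus
#' covariates and eigenvectors, then tests the trait coefficient
#' (Wald z on the Poisson-mean component by default, or a joint LRT
#' dropping the trait from both components).
#'
#' @param counts a [collapse_gene()] result.
#' @param pheno a [phenotype_table] restricted to one replicate.
#' @param trait `"disease"`, `"Q1"`, `"Q2"` or `"Q4"`.
#' @param eig optional [compute_eigenvectors()] result.
#' @param n_pcs eigenvectors to adjust for (default 10).
#' @param test `"wald"` or `"lrt"`.
#' @param control passed to [fit_zip()].
#' @return one-row data.frame: gene, trait, filter, n, n_snps, beta1, se,
#'   statistic, p, fallback, converged, skip_reason.
#' @export
test_gene <- function(counts, pheno, trait, eig = NULL, n_pcs = 10L,
                      test = c("wald", "lrt"), control = list()) {
  test <- match.arg(test)
  row <- data.frame(gene = counts$gene, trait = trait,
                    filter = counts$filter, n = length(counts$subjects),
                    n_snps = counts$n_snps_used,
                    beta1 = NA_real_, se = NA_real_, statistic = NA_real_,
                    p = NA_real_, fallback = NA_character_,
                    converged = NA, skip_reason = NA_character_,
                    stringsAsFactors = FALSE)
  design <- tryCatch(build_gene_design(counts, pheno, trait, eig, n_pcs),
                     error = function(e) e)
  if (inherits(design, "error")) {
    if (grepl("missing for subject", conditionMessage(design)))
      stop(design)
    row$skip_reason <- conditionMessage(design)
    return(row)
  }
  if ("trait" %in% design$dropped) {
    row$skip_reason <- "constant trait"
    return(row)
  }
  fit <- tryCatch(fit_zip(design, control), error = function(e) e)
  if (inherits(fit, "error")) {
    row$skip_reason <- conditionMessage(fit)
    return(row)
  }
  row$fallback <- fit$fallback
  row$converged <- fit$converged
  if (fit$fallback == "degenerate") {
    row$skip_reason <- paste0("degenerate: ", fit$fallback_reason)
    return(row)
  }
  if (test == "wald") {
    w <- wald_test(fit, "trait")
    row$beta1 <- w$estimate; row$se <- w$se
    row$statistic <- w$statistic; row$p <- w$p.value
  } else {
    red_cov <- design$Xm[, setdiff(colnames(design$Xm),
                                   c("(Intercept)", "trait")), drop = FALSE]
    red_design <- zip_design(design$y, red_cov)
    # seed the reduced fit from the full optimum (trait coefficients
    # removed), and vice versa if the reduced supremum comes out higher:
    # the mixture likelihood is multimodal and nested fits must agree
    red_ctl <- control
    if (fit$fallback == "none")
      red_ctl$start <- c(fit$gamma[colnames(red_design$Xz)],
                         fit$beta[colnames(red_design$Xm)])
    red <- tryCatch(fit_zip(red_design, red_ctl), error = function(e) e)
    if (!inherits(red, "error") && red$fallback == "none" &&
        !is.na(red$loglik) && !is.na(fit$loglik) &&
        red$loglik > fit$loglik + 1e-6) {
      full_ctl <- control
      g0 <- structure(numeric(ncol(design$Xz)), names = colnames(design$Xz))
      b0 <- structure(numeric(ncol(design$Xm)), names = colnames(design$Xm))
      g0[names(red$gamma)] <- red$gamma
      b0[names(red$beta)] <- red$beta
      full_ctl$start <- c(g0, b0)
      refit <- tryCatch(fit_zip(design, full_ctl), error = function(e) e)
      if (!inherits(refit, "error") && !is.na(refit$loglik) &&
          (is.na(fit$loglik) || refit$loglik >= fit$loglik)) fit <- refit
      row$fallback <- fit$fallback
      row$converged <- fit$converged
    }
    lr <- if (inherits(red, "error")) red else
      tryCatch(lrt_test(fit, red), error = function(e) e)
    if (inherits(lr, "error")) {
      row$skip_reason <- conditionMessage(lr)
      return(row)
    }
    row$beta1 <- unname(fit$beta["trait"])
    row$se <- sqrt(fit$vcov["trait", "trait"])
    row$statistic <- lr$statistic; row$p <- lr$p.value
  }
  row
}

#' Gene-based association scan
#'
#' Collapses every gene and tests it against the chosen trait, pooled or
#' within ancestry groups. Per-group scans re-determine minor alleles and
#' collapsed counts within each group; all scans adjust for the leading
#' eigenvectors of the pooled genotype matrix.
#'
#' @param geno a [genotype_matrix].
#' @param map a [gene_map].
#' @param pheno a [phenotype_table] for a single replicate.
#' @param trait `"disease"`, `"Q1"`, `"Q2"` or `"Q4"`.
#' @param filter `"all"` or `"nonsynonymous"`.
#' @param groups `NULL` for a pooled scan, or a named vector
#'   subject -> group label for per-group scans.
#' @param maf_max optional MAF ceiling for collapsing.
#' @param n_pcs eigenvectors to adjust for (default 10).
#' @param alpha nominal level (default 0.05).
#' @param m_fixed optional fixed test count for a paper-style Bonferroni
#'   threshold reported alongside the tested-gene one.
#' @param test `"wald"` or `"lrt"`.
#' @param eig optional precomputed eigenvectors (otherwise computed here).
#' @param collapsed optional precomputed [collapse_all()] output (pooled
#'   scans only).
#' @param control passed to [fit_zip()].
#' @return object of class `zip_scan`: `results` data.frame with
#'   significance flags, `m` (genes with a completed test), `m_collapsed`,
#'   `thresholds`, `config`, `skipped_genes`, `skipped_groups`.
#' @export
run_scan <- function(geno, map, pheno, trait = "disease",
                     filter = c("all", "nonsynonymous"), groups = NULL,
                     maf_max = NULL, n_pcs = 10L, alpha = 0.05,
                     m_fixed = NULL, test = c("wald", "lrt"), eig = NULL,
                     collapsed = NULL, control = list()) {
  filter <- match.arg(filter)
  test <- match.arg(test)
  if (anyDuplicated(pheno$subject))
    stop("phenotype table must hold a single replicate per subject")
  subjects <- intersect(geno$subjects, pheno$subject)
  if (length(subjects) == 0) stop("no subjects shared between genotypes and phenotypes")
  if (is.null(eig) && n_pcs > 0)
    eig <- compute_eigenvectors(geno, k = n_pcs, subjects = subjects)

  scan_one <- function(subs, label, pre_collapsed = NULL) {
    cc <- if (is.null(pre_collapsed))
      suppressWarnings(collapse_all(geno, map, subjects = subs,
                                    filter = filter, maf_max = maf_max))
    else pre_collapsed
    rows <- lapply(cc, test_gene, pheno = pheno, trait = trait, eig = eig,
                   n_pcs = n_pcs, test = test, control = control)
    res <- if (length(rows)) do.call(rbind, rows) else NULL
    list(res = res, skipped = attr(cc, "skipped"), label = label,
         m_collapsed = length(cc))
  }

  skipped_groups <- character()
  if (is.null(groups)) {
    parts <- list(scan_one(subjects, "pooled", collapsed))
  } else {
    groups <- groups[intersect(names(groups), subjects)]
    min_n <- 2L * (5L + n_pcs) + 2L  # coefficients in both components
    parts <- list()
    for (g in sort(unique(groups))) {
      subs <- names(groups)[groups == g]
      if (length(subs) <= min_n) {
        skipped_groups <- c(skipped_groups, g)
        message("group ", g, " skipped: ", length(subs),
                " subjects cannot support ", min_n, " coefficients")
        next
      }
      parts[[g]] <- scan_one(subs, g)
    }
    if (length(parts) == 0) stop("no group large enough to scan")
  }

  results <- do.call(rbind, lapply(parts, function(p) {
    if (is.null(p$res)) return(NULL)
    cbind(group = p$label, p$res, stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL
  m <- sum(!is.na(results$p))
  if (m == 0) stop("no gene produced a completed test")
  thr <- list(nominal = alpha,
              bonferroni = bonferroni_threshold(alpha, m),
              bonferroni_fixed = if (is.null(m_fixed)) NULL
                                 else bonferroni_threshold(alpha, m_fixed))
  results$significant_nominal <- !is.na(results$p) & results$p < thr$nominal
  results$significant_bonferroni <- !is.na(results$p) & results$p < thr$bonferroni
  structure(list(results = results, m = m,
                 m_collapsed = sum(vapply(parts, function(p) p$m_collapsed, 0L)),
                 thresholds = thr,
                 config = list(trait = trait, filter = filter,
                               maf_max = maf_max, n_pcs = n_pcs,
                               alpha = alpha, test = test,
                               grouped = !is.null(groups)),
                 skipped_genes = unique(unlist(lapply(parts, `[[`, "skipped"))),
                 skipped_groups = skipped_groups),
            class = "zip_scan")
}

#' @export
print.zip_scan <- function(x, ...) {
  cat(sprintf("zip_scan: trait=%s filter=%s, %d result rows (m=%d), %d significant at %g, %d at Bonferroni %.3g\n",
              x$config$trait, x$config$filter, nrow(x$results),
              as.integer(x$m),
              as.integer(sum(x$results$significant_nominal)),
              x$config$alpha,
              as.integer(sum(x$results$significant_bonferroni)),
              x$thresholds$bonferroni))
  invisible(x)
}

#' Scan every phenotype replicate over fixed genotypes
#'
#' Eigenvectors and collapsed counts are computed once and reused, since
#' neither depends on the phenotype replicate.
#'
#' @inheritParams run_scan
#' @param pheno a [phenotype_table] holding multiple replicates.
#' @param replicates replicate IDs to scan (default: all present).
#' @param eig optional precomputed [compute_eigenvectors()] result (e.g. a
#'   leave-one-gene-out decomposition); computed from `geno` when `NULL`.
#' @return data.frame of per-replicate results (a `replicate` column is
#'   prepended), with attribute `"m"` the per-replicate tested-gene count
#'   from the first replicate.
#' @export
run_replicate_scans <- function(geno, map, pheno, trait = "disease",
                                filter = c("all", "nonsynonymous"),
                                groups = NULL, maf_max = NULL, n_pcs = 10L,
                                alpha = 0.05, m_fixed = NULL,
                                test = c("wald", "lrt"), control = list(),
                                replicates = NULL, eig = NULL) {
  filter <- match.arg(filter)
  test <- match.arg(test)
  if (is.null(replicates)) replicates <- sort(unique(pheno$replicate))
  subjects <- intersect(geno$subjects, pheno$subject)
  if (is.null(eig) && n_pcs > 0)
    eig <- compute_eigenvectors(geno, k = n_pcs, subjects = subjects)
  collapsed <- if (is.null(groups))
    suppressWarnings(collapse_all(geno, map, subjects = subjects,
                                  filter = filter, maf_max = maf_max))
  else NULL
  out <- lapply(replicates, function(r) {
    ph <- pheno[pheno$replicate == r, , drop = FALSE]
    sc <- run_scan(geno, map, ph, trait = trait, filter = filter,
                   groups = groups, maf_max = maf_max, n_pcs = n_pcs,
                   alpha = alpha, m_fixed = m_fixed, test = test, eig = eig,
                   collapsed = collapsed, control = control)
    cbind(replicate = r, sc$results, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "m") <- sum(!is.na(out[[1]]$p))
  res
}

#' Replicate-based power / replication-rate summary
#'
#' For each (group, gene, trait, filter), the proportion of replicates
#' whose p-value falls below the nominal level and below the Bonferroni
#' threshold. Replicates with no completed test (NA p) stay in the
#' denominator as non-significant, and their count is reported.
#'
#' @param results data.frame from [run_replicate_scans()] (must contain a
#'   `replicate` column).
#' @param alpha nominal level (default 0.05).
#' @param bonferroni Bonferroni threshold; default 0.05 / (tested genes per
#'   replicate) taken from the results.
#' @param conf confidence level of the binomial (Clopper-Pearson) intervals.
#' @return data.frame sorted by group then gene: n_replicates, n_na,
#'   power_nominal, power_bonferroni, and their CI bounds.
#' @export
replicate_power <- function(results, alpha = 0.05, bonferroni = NULL,
                            conf = 0.95) {
  if (!"replicate" %in% names(results) || length(unique(results$replicate)) < 1)
    stop("need results from at least one replicate")
  if (is.null(bonferroni)) {
    m <- attr(results, "m")
    if (is.null(m))
      m <- sum(!is.na(results$p[results$replicate == results$replicate[1]]))
    bonferroni <- bonferroni_threshold(alpha, m)
  }
  key <- interaction(results$group, results$gene, results$trait,
                     results$filter, drop = TRUE)
  out <- lapply(split(results, key), function(d) {
    nrep <- nrow(d)
    k_nom <- sum(!is.na(d$p) & d$p < alpha)
    k_bon <- sum(!is.na(d$p) & d$p < bonferroni)
    ci_n <- binom_ci(k_nom, nrep, conf)
    ci_b <- binom_ci(k_bon, nrep, conf)
    data.frame(group = d$group[1], gene = d$gene[1], trait = d$trait[1],
               filter = d$filter[1], n_replicates = nrep,
               n_na = sum(is.na(d$p)),
               power_nominal = k_nom / nrep,
               nominal_lo = ci_n[1], nominal_hi = ci_n[2],
               power_bonferroni = k_bon / nrep,
               bonferroni_lo = ci_b[1], bonferroni_hi = ci_b[2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$group, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "thresholds") <- c(nominal = alpha, bonferroni = bonferroni)
  res
}

#' Write scan results, power summaries and a run manifest
#'
#' @param scan a `zip_scan` (or the data.frame from
#'   [run_replicate_scans()]).
#' @param power optional [replicate_power()] output.
#' @param dir output directory (created if absent).
#' @param seed seed recorded in the manifest.
#' @return invisibly, the paths written.
#' @export
report_scan <- function(scan, power = NULL, dir, seed = NA) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", dir)
  results <- if (inherits(scan, "zip_scan")) scan$results else scan
  paths <- file.path(dir, "results.tsv")
  utils::write.table(results, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(power)) {
    p <- file.path(dir, "power.tsv")
    utils::write.table(power, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "zipburden",
    version = as.character(utils::packageVersion("zipburden")),
    seed = seed,
    config = if (inherits(scan, "zip_scan")) scan$config else NULL,
    m = if (inherits(scan, "zip_scan")) scan$m else attr(scan, "m"),
    thresholds = if (inherits(scan, "zip_scan")) scan$thresholds else
      as.list(attr(power, "thresholds")),
    skipped_genes = if (inherits(scan, "zip_scan")) scan$skipped_genes else NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(paths, mp))
}
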