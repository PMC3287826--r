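# Zero-inflated Poisson regression, fitted by joint maximum likelihood.
#
# The mixture: each count T_i is a structural zero with probability p_i,
# otherwise Poisson(mu_i). Both components carry the full covariate set
# through canonical links,
#     logit(p_i) = z_i' gamma,   log(mu_i) = x_i' beta,
# and the association test is of the phenotype coefficient beta_1 in the
# Poisson-mean component (a joint 2-df likelihood-ratio test dropping the
# phenotype from both components is available as an alternative).
#
# Zero-count terms are evaluated in log space:
#     log f(0) = log1pexp(-(a_i + mu_i)) - log1pexp(-a_i),  a_i = z_i'gamma,
# which is exact for arbitrarily extreme linear predictors.

#' Build a ZIP design
#'
#' Bundles the count outcome with the zero-component and mean-component
#' design matrices (the same covariates enter both by default). Constant
#' columns other than the intercept are dropped, and each matrix must be
#' full column rank.
#'
#' @param counts non-negative integer outcome vector.
#' @param covariates numeric matrix or data.frame of covariates (no
#'   intercept column; one is added).
#' @return a list of class `zip_design` with elements `y`, `Xz`, `Xm`,
#'   `dropped` (names of constant columns removed).
#' @export
zip_design <- function(counts, covariates) {
  y <- counts
  if (any(is.na(y)) || any(y < 0) || any(y != round(y)))
    stop("outcome counts must be non-negative integers")
  X <- as.matrix(covariates)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (!all(is.finite(X))) {
    bad <- colnames(X)[apply(X, 2, function(c) any(!is.finite(c)))]
    stop("non-finite covariate value(s) in: ", paste(bad, collapse = ", "))
  }
  const <- apply(X, 2, function(c) max(c) == min(c))
  dropped <- colnames(X)[const]
  X <- X[, !const, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, X)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient after dropping constant columns")
  structure(list(y = as.integer(y), Xz = X, Xm = X, dropped = dropped),
            class = "zip_design")
}

#' Zero-inflated Poisson log-likelihood
#'
#' @param gamma coefficients of the logit(p) component (length =
#'   `ncol(design$Xz)`).
#' @param beta coefficients of the log(mu) component (length =
#'   `ncol(design$Xm)`).
#' @param design a [zip_design].
#' @return the log-likelihood (scalar).
#' @export
zip_loglik <- function(gamma, beta, design) {
  stopifnot(length(gamma) == ncol(design$Xz),
            length(beta) == ncol(design$Xm))
  a <- drop(design$Xz %*% gamma)
  eta <- drop(design$Xm %*% beta)
  if (any(!is.finite(a)) || any(!is.finite(eta)) || any(abs(eta) > 709)) {
    Xall <- cbind(design$Xz, design$Xm)
    scl <- apply(abs(Xall), 2, max)
    stop("non-finite linear predictor; check the scale of covariate ",
         colnames(Xall)[which.max(scl)])
  }
  mu <- exp(eta)
  y <- design$y
  z <- y == 0
  ll <- numeric(length(y))
  ll[z] <- log1pexp(-(a[z] + mu[z])) - log1pexp(-a[z])
  ll[!z] <- -log1pexp(a[!z]) + y[!z] * eta[!z] - mu[!z] - lgamma(y[!z] + 1)
  sum(ll)
}

# Analytic gradient of zip_loglik in c(gamma, beta).
zip_grad <- function(gamma, beta, design) {
  a <- drop(design$Xz %*% gamma)
  eta <- drop(design$Xm %*% beta)
  mu <- exp(eta)
  y <- design$y
  z <- y == 0
  wa <- numeric(length(y))
  wm <- numeric(length(y))
  wa[z] <- stats::plogis(a[z] + mu[z]) - stats::plogis(a[z])
  wm[z] <- mu[z] * (stats::plogis(a[z] + mu[z]) - 1)
  wa[!z] <- -stats::plogis(a[!z])
  wm[!z] <- y[!z] - mu[!z]
  c(drop(crossprod(design$Xz, wa)), drop(crossprod(design$Xm, wm)))
}

#' Fit a zero-inflated Poisson regression
#'
#' Joint maximum likelihood by BFGS with the analytic gradient, warm-started
#' from a Poisson GLM (`beta`) and the excess-zero fraction (`gamma`
#' intercept), with jittered restarts on non-convergence. Standard errors
#' come from the observed information (numerical Hessian at the optimum).
#'
#' Degenerate outcomes trigger explicit fallbacks instead of a forced
#' mixture fit: all-zero counts give `fallback = "degenerate"` (no test
#' possible); counts with no zeros, a fitted mixture collapsing onto its
#' Poisson boundary, or quasi-separation in the zero component (fitted
#' structural-zero probabilities reaching 1 for individual observations,
#' where the mixture likelihood has no finite optimum) give
#' `fallback = "poisson"`, with coefficients and standard errors from the
#' plain Poisson GLM.
#'
#' @param design a [zip_design].
#' @param control list: `maxit` (default 300), `reltol` (1e-10),
#'   `restarts` (5), `boundary_p` (1e-4; maximum fitted zero-inflation
#'   probability below which the fit is treated as plain Poisson),
#'   `separation_p` (1e-6; a fitted zero-inflation probability above
#'   `1 - separation_p` marks quasi-separation in the zero component — a
#'   deterministic structural-zero assignment with no finite optimum —
#'   and falls back to the Poisson fit), `start` (optional extra starting
#'   vector `c(gamma, beta)`).
#' @return an object of class `zip_fit`: `gamma`, `beta`, `vcov` (full
#'   coefficient covariance, gamma block first), `loglik`,
#'   `loglik_poisson`, `converged`, `fallback` in
#'   `c("none", "poisson", "degenerate")`, `n`, `df`.
#' @export
fit_zip <- function(design, control = list()) {
  ctl <- utils::modifyList(list(maxit = 300L, reltol = 1e-10, restarts = 5L,
                                boundary_p = 1e-4, separation_p = 1e-6),
                           control)
  y <- design$y
  n <- length(y)
  kz <- ncol(design$Xz); km <- ncol(design$Xm)
  if (n <= kz + km)
    stop("need more observations than coefficients (n = ", n,
         ", coefficients = ", kz + km, ")")

  if (all(y == 0)) return(zip_fit_degenerate(design, "all counts are zero"))

  pois <- suppressWarnings(
    stats::glm.fit(design$Xm, y, family = stats::poisson()))
  beta0 <- pois$coefficients
  ll_pois <- zip_poisson_loglik(beta0, design)

  if (!any(y == 0)) {
    return(zip_fit_poisson(design, reason = "no zero counts"))
  }

  # gamma warm start from the zero fraction in excess of the Poisson fit;
  # the likelihood is multimodal, so a moderate-inflation start (and any
  # caller-supplied starts, e.g. from a nested fit) are tried as well and
  # the best optimum kept
  p0_obs <- mean(y == 0)
  p0_pois <- mean(exp(-pois$fitted.values))
  excess <- (p0_obs - p0_pois) / max(1 - p0_pois, 1e-8)
  excess <- min(max(excess, 1e-4), 0.999)
  gamma0 <- c(stats::qlogis(excess), rep(0, kz - 1))
  starts <- list(c(gamma0, beta0),
                 c(stats::qlogis(0.25), rep(0, kz - 1), beta0))
  if (!is.null(ctl$start)) starts <- c(starts, list(ctl$start))
  start <- starts[[1]]

  negll <- function(par) {
    v <- tryCatch(zip_loglik(par[seq_len(kz)], par[kz + seq_len(km)], design),
                  error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  neggr <- function(par) {
    g <- zip_grad(par[seq_len(kz)], par[kz + seq_len(km)], design)
    if (any(!is.finite(g))) rep(0, length(par)) else -g
  }

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, negll, neggr, method = "BFGS",
                   control = list(maxit = ctl$maxit, reltol = ctl$reltol)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  for (attempt in seq_len(ctl$restarts)) {
    if (!is.null(best) && best$convergence == 0 && best$value < 1e9) break
    # deterministic jitter so refits never depend on the caller's RNG state
    par <- start + with_local_seed(1000L + attempt,
                                   stats::rnorm(length(start), sd = 0.5))
    opt <- tryCatch(
      stats::optim(par, negll, neggr, method = "BFGS",
                   control = list(maxit = ctl$maxit, reltol = ctl$reltol)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best) || best$value >= 1e9)
    return(zip_fit_degenerate(design, "optimization failed"))

  par <- best$par
  gamma <- par[seq_len(kz)]; beta <- par[kz + seq_len(km)]
  names(gamma) <- colnames(design$Xz); names(beta) <- colnames(design$Xm)
  ll <- -best$value

  # Mixture collapsed to its Poisson boundary: the zero-inflation block of
  # the information is flat there, so report the Poisson fit honestly.
  p_hat <- stats::plogis(drop(design$Xz %*% gamma))
  if (max(p_hat) < ctl$boundary_p)
    return(zip_fit_poisson(design, reason = "zero-inflation at boundary",
                           loglik_zip = ll))

  # Quasi-separation in the zero component: with continuous covariates the
  # logistic part can label individual zero counts as structural with
  # fitted probability 1, sending coefficients to infinity and the
  # likelihood up a ridge that has no finite optimum. Such a "fit" assigns
  # mixture membership deterministically per observation, so the mixture is
  # degenerate there and the Poisson model is reported instead.
  if (max(p_hat) > 1 - ctl$separation_p)
    return(zip_fit_poisson(design, reason = "zero-component separation"))

  H <- tryCatch(stats::optimHess(par, negll, neggr), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) <= 0)) {
    V2 <- if (!is.null(H)) tryCatch(MASS::ginv(H), error = function(e) NULL) else NULL
    if (is.null(V2) || any(!is.finite(diag(V2))) ||
        any(diag(V2)[kz + seq_len(km)] <= 0))
      return(zip_fit_degenerate(design, "singular observed information"))
    V <- V2
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(c(paste0("zero_", names(gamma)), names(beta)),
                      c(paste0("zero_", names(gamma)), names(beta)))

  structure(list(gamma = gamma, beta = beta, vcov = V,
                 loglik = ll, loglik_poisson = ll_pois,
                 converged = best$convergence == 0,
                 fallback = "none", n = n, df = kz + km,
                 design = design),
            class = "zip_fit")
}

zip_poisson_loglik <- function(beta, design) {
  eta <- drop(design$Xm %*% beta)
  sum(stats::dpois(design$y, exp(eta), log = TRUE))
}

zip_fit_poisson <- function(design, reason, loglik_zip = NULL) {
  km <- ncol(design$Xm)
  fit <- suppressWarnings(
    stats::glm.fit(design$Xm, design$y, family = stats::poisson()))
  beta <- fit$coefficients
  names(beta) <- colnames(design$Xm)
  # observed = expected information for the canonical-link Poisson GLM
  W <- fit$fitted.values
  XtWX <- crossprod(design$Xm * W, design$Xm)
  V <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(V)) return(zip_fit_degenerate(design, "singular Poisson information"))
  dimnames(V) <- list(names(beta), names(beta))
  ll_pois <- zip_poisson_loglik(beta, design)
  structure(list(gamma = NULL, beta = beta, vcov = V,
                 loglik = if (is.null(loglik_zip)) ll_pois else loglik_zip,
                 loglik_poisson = ll_pois,
                 converged = fit$converged, fallback = "poisson",
                 fallback_reason = reason, n = length(design$y), df = km,
                 design = design),
            class = "zip_fit")
}

zip_fit_degenerate <- function(design, reason) {
  structure(list(gamma = NULL, beta = NULL, vcov = NULL,
                 loglik = NA_real_, loglik_poisson = NA_real_,
                 converged = FALSE, fallback = "degenerate",
                 fallback_reason = reason, n = length(design$y), df = 0L,
                 design = design),
            class = "zip_fit")
}

#' @export
print.zip_fit <- function(x, ...) {
  cat(sprintf("zip_fit: n = %d, fallback = %s, converged = %s, logLik = %s\n",
              x$n, x$fallback, x$converged, format(x$loglik, digits = 6)))
  if (!is.null(x$beta)) {
    cat("log(mu) coefficients:\n"); print(x$beta)
  }
  if (!is.null(x$gamma)) {
    cat("logit(p) coefficients:\n"); print(x$gamma)
  }
  invisible(x)
}

#' Wald test of a single coefficient
#'
#' Tests the null that the named coefficient is zero using the fitted
#' covariance: z = estimate / SE, two-sided normal p-value. The default
#' targets the phenotype coefficient in the Poisson-mean component; under a
#' Poisson fallback the Poisson fit's coefficient is tested.
#'
#' @param fit a [fit_zip()] result.
#' @param coefficient name (or index) of the mean-component coefficient to
#'   test.
#' @param component `"mean"` or `"zero"`.
#' @return list with `estimate`, `se`, `statistic` (z), `p.value`.
#' @export
wald_test <- function(fit, coefficient = 2L, component = c("mean", "zero")) {
  component <- match.arg(component)
  if (fit$fallback == "degenerate")
    stop("no test possible for a degenerate fit (",
         fit$fallback_reason, ")")
  if (component == "zero") {
    if (fit$fallback == "poisson")
      stop("zero component unavailable under the Poisson fallback")
    est <- fit$gamma[coefficient]
    vn <- paste0("zero_", names(fit$gamma)[if (is.numeric(coefficient)) coefficient else match(coefficient, names(fit$gamma))])
  } else {
    est <- fit$beta[coefficient]
    vn <- names(fit$beta)[if (is.numeric(coefficient)) coefficient else match(coefficient, names(fit$beta))]
  }
  if (length(est) != 1L || is.na(est))
    stop("coefficient not found: ", coefficient)
  se <- sqrt(fit$vcov[vn, vn])
  z <- unname(est / se)
  list(estimate = unname(est), se = unname(se), statistic = z,
       p.value = 2 * stats::pnorm(-abs(z)))
}

#' Likelihood-ratio test between nested ZIP fits
#'
#' Compares the achieved ZIP log-likelihood suprema of the two designs;
#' for a fit that collapsed onto its Poisson boundary the supremum equals
#' the Poisson log-likelihood, so fits from different fallback classes
#' remain comparable. Degrees of freedom count the design columns dropped
#' from both components.
#'
#' @param full fit of the full design.
#' @param reduced fit of the design without the phenotype column(s).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
lrt_test <- function(full, reduced) {
  if (full$fallback == "degenerate" || reduced$fallback == "degenerate")
    stop("no test possible for a degenerate fit")
  df <- (ncol(full$design$Xz) + ncol(full$design$Xm)) -
    (ncol(reduced$design$Xz) + ncol(reduced$design$Xm))
  if (df < 0) stop("reduced design has more coefficients than the full design")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6)
    stop("full-model log-likelihood below reduced model: optimization failure, refit required")
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}
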