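new_mr_result <- function(method, beta, se, n_ivs, snps = NULL,
                          exposure = "exposure", outcome = "outcome",
                          removed = NULL) {
  w <- wald_test(beta, se)
  structure(list(
    estimate = tibble::tibble(exposure = exposure, outcome = outcome,
                              method = method, n_ivs = n_ivs, beta = beta,
                              se = se, z = w$z, pvalue = w$pvalue,
                              pvalue_adjusted = NA_real_),
    snps = snps,
    removed = removed %||% tibble::tibble(snp_id = character(),
                                          reason = character())
  ), class = "mr_result")
}

#' Wald test of a causal estimate
#'
#' `z = beta / se`, two-sided p-value from the standard normal (the statistic
#' is asymptotically standard normal under the null).
#'
#' @param beta_xy Causal effect estimate.
#' @param se_xy Its standard error (> 0).
#' @return A list with `z` and `pvalue`.
#' @export
wald_test <- function(beta_xy, se_xy) {
  if (any(se_xy <= 0)) abort("wald_test: se must be positive")
  z <- beta_xy / se_xy
  list(z = z, pvalue = 2 * pnorm(-abs(z)))
}

#' Causal effect from refined-score MR
#'
#' Combines refined (direct) exposure effects, single-locus exposure effects,
#' and outcome effects into the ratio-of-covariances causal estimate
#' `sum(b~ b_YZ / se_YZ^2) / sum(b~ b_XZ / se_YZ^2)`: the Wald ratio of the
#' outcome and exposure associations of the composite genetic score weighted
#' by the refined coefficients, with `1/var(b_YZ)` standing in for the
#' genotype variances. The delta-method standard error is
#' `sqrt( sum_ij rho_ij b~_i b~_j / (se_i se_j) ) / |sum b~ b_XZ / se^2|`.
#'
#' @param data A data frame with one row per instrument and columns `b_tilde`
#'   (refined exposure effect), `b_xz` (single-locus exposure effect), `b_yz`
#'   and `se_yz` (outcome effect and SE), optionally `snp_id`. Alternatively
#'   pass the vectors via the named arguments.
#' @param rho Instrument correlation matrix (defaults to identity,
#'   appropriate only for independent instruments).
#' @param b_tilde,b_xz,b_yz,se_yz Vector inputs used when `data` is `NULL`.
#' @param exposure,outcome Labels carried into the estimate.
#' @return An object of class `mr_result`; see [glance.mr_result()] and
#'   [tidy.mr_result()].
#' @examples
#' mr_river(b_tilde = c(0.5, 0.2), b_xz = c(0.5, 0.2),
#'          b_yz = c(0.3, 0.1), se_yz = c(0.1, 0.1))
#' @export
mr_river <- function(data = NULL, rho = NULL, b_tilde = NULL, b_xz = NULL,
                     b_yz = NULL, se_yz = NULL, exposure = "exposure",
                     outcome = "outcome") {
  if (!is.null(data)) {
    b_tilde <- data$b_tilde; b_xz <- data$b_xz
    b_yz <- data$b_yz; se_yz <- data$se_yz
  }
  p <- length(b_tilde)
  stopifnot(p >= 1, length(b_xz) == p, length(b_yz) == p,
            length(se_yz) == p)
  if (is.null(rho)) rho <- diag(p)
  w <- 1 / se_yz^2
  denom <- sum(b_tilde * b_xz * w)
  if (denom == 0) {
    abort("mr_river: instruments collectively null for exposure")
  }
  beta <- sum(b_tilde * b_yz * w) / denom
  quad <- sum(rho * outer(b_tilde / se_yz, b_tilde / se_yz))
  if (quad < 0) {
    abort("mr_river: negative variance quadratic form; rho is not positive semidefinite")
  }
  se <- sqrt(quad) / abs(denom)
  snps <- tibble::tibble(
    snp_id = if (!is.null(data) && !is.null(data$snp_id)) data$snp_id
             else paste0("snp", seq_len(p)),
    b_tilde = b_tilde, b_xz = b_xz, b_yz = b_yz, se_yz = se_yz,
    wald_ratio = b_yz / b_xz)
  new_mr_result("mr_river", beta, se, p, snps, exposure, outcome)
}

#' Correlated inverse-variance-weighted estimator
#'
#' Generalized IVW using the full outcome-side variance-covariance matrix
#' `Omega_ij = rho_ij se_yz_i se_yz_j`:
#' `beta = (b_xz' Omega^-1 b_yz) / (b_xz' Omega^-1 b_xz)` with
#' `se = 1 / sqrt(b_xz' Omega^-1 b_xz)`. With `rho = I` this is classical
#' fixed-effect IVW.
#'
#' @inheritParams mr_river
#' @param data A data frame with columns `b_xz`, `b_yz`, `se_yz`, optionally
#'   `snp_id`.
#' @return An `mr_result`.
#' @export
mr_ivw <- function(data = NULL, rho = NULL, b_xz = NULL, b_yz = NULL,
                   se_yz = NULL, exposure = "exposure", outcome = "outcome") {
  if (!is.null(data)) {
    b_xz <- data$b_xz; b_yz <- data$b_yz; se_yz <- data$se_yz
  }
  p <- length(b_xz)
  stopifnot(p >= 1, length(b_yz) == p, length(se_yz) == p)
  if (is.null(rho)) rho <- diag(p)
  omega <- rho * outer(se_yz, se_yz)
  oi <- tryCatch(solve(omega, cbind(b_xz, b_yz)), error = function(e) {
    abort("mr_ivw: singular outcome covariance matrix")
  })
  denom <- sum(b_xz * oi[, 1])
  if (denom <= 0) abort("mr_ivw: non-positive precision quadratic form")
  beta <- sum(b_xz * oi[, 2]) / denom
  se <- 1 / sqrt(denom)
  snps <- tibble::tibble(
    snp_id = if (!is.null(data) && !is.null(data$snp_id)) data$snp_id
             else paste0("snp", seq_len(p)),
    b_xz = b_xz, b_yz = b_yz, se_yz = se_yz, wald_ratio = b_yz / b_xz)
  new_mr_result("ivw", beta, se, p, snps, exposure, outcome)
}

#' GSMR-style generalized least-squares estimator
#'
#' Combines per-SNP Wald ratios `beta_i = b_yz_i / b_xz_i` by generalized
#' least squares. The first-order delta variance of each ratio is
#' `(se_yz_i^2 + beta_i^2 se_xz_i^2) / b_xz_i^2`, and the LD-aware covariance
#' is `V_ij = rho_ij sd_i sd_j`; then `beta = (1' V^-1 beta) / (1' V^-1 1)`
#' with `se = 1 / sqrt(1' V^-1 1)`.
#'
#' @inheritParams mr_river
#' @param data A data frame with columns `b_xz`, `se_xz`, `b_yz`, `se_yz`,
#'   optionally `snp_id`.
#' @param se_xz Exposure-side standard errors (vector interface).
#' @return An `mr_result`.
#' @export
mr_gls <- function(data = NULL, rho = NULL, b_xz = NULL, se_xz = NULL,
                   b_yz = NULL, se_yz = NULL, exposure = "exposure",
                   outcome = "outcome") {
  if (!is.null(data)) {
    b_xz <- data$b_xz; se_xz <- data$se_xz
    b_yz <- data$b_yz; se_yz <- data$se_yz
  }
  p <- length(b_xz)
  stopifnot(p >= 1, length(se_xz) == p, length(b_yz) == p,
            length(se_yz) == p)
  if (any(b_xz == 0)) {
    abort("mr_gls: zero exposure beta gives an undefined Wald ratio")
  }
  if (is.null(rho)) rho <- diag(p)
  ratio <- b_yz / b_xz
  v <- (se_yz^2 + ratio^2 * se_xz^2) / b_xz^2
  V <- rho * outer(sqrt(v), sqrt(v))
  vi <- tryCatch(solve(V, cbind(1, ratio)), error = function(e) {
    abort("mr_gls: singular ratio covariance matrix")
  })
  denom <- sum(vi[, 1])
  if (denom <= 0) abort("mr_gls: non-positive precision sum")
  beta <- sum(vi[, 2]) / denom
  se <- 1 / sqrt(denom)
  snps <- tibble::tibble(
    snp_id = if (!is.null(data) && !is.null(data$snp_id)) data$snp_id
             else paste0("snp", seq_len(p)),
    b_xz = b_xz, se_xz = se_xz, b_yz = b_yz, se_yz = se_yz,
    wald_ratio = ratio)
  new_mr_result("gls", beta, se, p, snps, exposure, outcome)
}

#' HEIDI-style pleiotropy outlier filter
#'
#' Tests each instrument's Wald ratio against the reference instrument's (the
#' one with the smallest exposure p-value, the "top instrument" convention).
#' For instrument i, `d_i = beta_i - beta_ref` with a first-order delta-method
#' variance that includes the covariance induced by the LD correlation with
#' the reference; `d_i^2 / var(d_i)` is referred to a chi-square(1) and the
#' SNP is removed when its p-value falls below `alpha`. Single pass; with
#' fewer than 3 instruments the filter is skipped with a warning.
#'
#' @param data A data frame with columns `snp_id`, `b_xz`, `se_xz`,
#'   `pvalue_xz` (exposure p-values used to pick the reference), `b_yz`,
#'   `se_yz`.
#' @param rho Instrument correlation matrix in `data`'s row order.
#' @param alpha Removal threshold on the heterogeneity p-value (default 0.01,
#'   the conventional HEIDI default).
#' @return A list with `retained` and `removed` (character vectors of SNP
#'   ids) and `detail`, a per-SNP tibble of the heterogeneity statistics.
#' @export
heidi_filter <- function(data, rho = NULL, alpha = 0.01) {
  p <- nrow(data)
  if (is.null(rho)) rho <- diag(p)
  if (p < 3) {
    warn("heidi_filter: fewer than 3 instruments; filtering skipped")
    return(list(retained = data$snp_id, removed = character(0),
                detail = NULL))
  }
  pv <- data$pvalue_xz %||% (2 * pnorm(-abs(data$b_xz / data$se_xz)))
  ref <- order(pv, data$snp_id)[1]
  ratio <- data$b_yz / data$b_xz
  v <- (data$se_yz^2 + ratio^2 * data$se_xz^2) / data$b_xz^2
  # cov(beta_i, beta_ref): outcome and exposure samples are independent, each
  # contributing an LD-correlation term through the delta expansion
  cov_ir <- rho[, ref] *
    (data$se_yz * data$se_yz[ref] +
       ratio * ratio[ref] * data$se_xz * data$se_xz[ref]) /
    (data$b_xz * data$b_xz[ref])
  d <- ratio - ratio[ref]
  var_d <- v + v[ref] - 2 * cov_ir
  stat <- ifelse(var_d > 0, d^2 / var_d, 0)
  p_het <- pchisq(stat, df = 1, lower.tail = FALSE)
  p_het[ref] <- 1
  removed <- data$snp_id[p_het < alpha]
  list(retained = setdiff(data$snp_id, removed), removed = removed,
       detail = tibble::tibble(snp_id = data$snp_id, wald_ratio = ratio,
                               d = d, var_d = var_d, p_het = p_het,
                               is_reference = seq_len(p) == ref))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m p)` for a family of `m` tests (`m` may exceed the number
#' of p-values supplied, e.g. when only a subset of a scan is passed in).
#'
#' @param pvalues Numeric vector of p-values.
#' @param m Family size; defaults to `length(pvalues)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvalues, m = length(pvalues)) {
  if (m < length(pvalues)) abort("bonferroni: m must be >= length(pvalues)")
  p.adjust(pvalues, method = "bonferroni", n = m)
}

#' @describeIn mr_river One-row tibble with the estimate, SE, Wald statistic
#'   and p-value.
#' @param x An `mr_result`.
#' @param ... Unused.
#' @export
glance.mr_result <- function(x, ...) x$estimate

#' @describeIn mr_river Per-instrument tibble of the inputs and Wald ratios.
#' @export
tidy.mr_result <- function(x, ...) x$snps

#' @export
print.mr_result <- function(x, ...) {
  e <- x$estimate
  cat("<mr_result> ", e$method, ": ", e$exposure, " -> ", e$outcome, "\n",
      "  beta = ", signif(e$beta, 4), " (se ", signif(e$se, 4), "), z = ",
      signif(e$z, 4), ", p = ", format(e$pvalue, digits = 3), ", ",
      e$n_ivs, " instruments\n", sep = "")
  invisible(x)
}
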