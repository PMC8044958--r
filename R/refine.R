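#' Pairwise regression-slope matrix of the instruments
#'
#' Entry (i, j) is the simple-regression slope of SNP j's genotype on SNP i's,
#' `rho_ij * sqrt(var_j / var_i)`, with a unit diagonal. Inverting this matrix
#' converts single-locus exposure effects (which absorb the effects of
#' correlated neighbours) into multivariable-equivalent direct effects. The
#' condition number of the matrix is attached: ill-conditioning signals
#' instruments in such strong LD that the decomposition is unstable and
#' stricter pruning is needed.
#'
#' @param reference An [ld_reference][build_reference] covering the
#'   instruments, in analysis order.
#' @return An object of class `theta_matrix`: list with `theta` (p x p),
#'   `condition_number`, `rho` and `snp_ids`.
#' @export
build_theta <- function(reference) {
  rho <- reference$rho
  v <- reference$variances
  sdv <- sqrt(v)
  # theta_ij = rho_ij * sd_j / sd_i
  theta <- rho * outer(1 / sdv, sdv)
  diag(theta) <- 1
  structure(list(theta = theta, condition_number = kappa(theta, exact = TRUE),
                 rho = rho, snp_ids = reference$snp_ids),
            class = "theta_matrix")
}

#' Refine single-locus exposure effects into direct effects
#'
#' Solves `theta %*% b_tilde = b_xz` so that each refined coefficient is the
#' direct effect of its SNP on the exposure controlling for the other
#' instruments, recovered from single-variant summary statistics plus the LD
#' reference alone. The covariance of the refined coefficients is propagated
#' as `theta^-1 Omega theta^-T` with `Omega_ij = rho_ij se_i se_j` (the usual
#' approximation for the covariance of single-locus estimates); it is reported
#' for diagnostics and is not used by the causal-effect standard error.
#'
#' @param b_xz Numeric vector of single-locus exposure betas, in the theta
#'   matrix's SNP order.
#' @param theta A `theta_matrix` from [build_theta()].
#' @param se_xz Optional standard errors of `b_xz` (enables `cov_b_tilde` and
#'   `se_tilde`).
#' @param max_condition Maximum acceptable condition number of theta; beyond
#'   it the solve is refused and stricter LD pruning is advised.
#' @return An object of class `refined_coef`: list with `snp_ids`, `b_tilde`,
#'   `source_b`, `cov_b_tilde` (or `NULL`) and `theta`.
#' @examples
#' ref <- structure(list(snp_ids = c("a", "b"),
#'                       rho = matrix(c(1, .5, .5, 1), 2),
#'                       variances = c(a = 1, b = 1)),
#'                  class = "ld_reference")
#' refine_coefficients(c(1, 0.8), build_theta(ref))
#' @export
refine_coefficients <- function(b_xz, theta, se_xz = NULL,
                                max_condition = 1e6) {
  stopifnot(inherits(theta, "theta_matrix"))
  p <- length(b_xz)
  if (p != nrow(theta$theta)) abort("refine_coefficients: dimension mismatch")
  if (!is.finite(theta$condition_number) ||
      theta$condition_number > max_condition) {
    abort(paste0("refine_coefficients: theta condition number ",
                 format(theta$condition_number, digits = 4), " exceeds ",
                 format(max_condition),
                 "; prune instruments at a stricter r2 threshold"))
  }
  b_tilde <- tryCatch(solve(theta$theta, b_xz), error = function(e) {
    abort(paste0("refine_coefficients: theta is singular; ",
                 "prune instruments at a stricter r2 threshold"))
  })
  resid <- max(abs(theta$theta %*% b_tilde - b_xz))
  if (resid > 1e-10 * max(1, max(abs(b_xz)))) {
    abort("refine_coefficients: reconstruction residual exceeds tolerance")
  }
  cov_b_tilde <- NULL
  if (!is.null(se_xz)) {
    omega <- theta$rho * outer(se_xz, se_xz)
    tinv <- solve(theta$theta)
    cov_b_tilde <- tinv %*% omega %*% t(tinv)
    cov_b_tilde <- (cov_b_tilde + t(cov_b_tilde)) / 2
  }
  structure(list(snp_ids = theta$snp_ids, b_tilde = as.numeric(b_tilde),
                 source_b = as.numeric(b_xz), cov_b_tilde = cov_b_tilde,
                 theta = theta),
            class = "refined_coef")
}

#' @describeIn refine_coefficients Per-SNP tibble of original and refined
#'   coefficients (with `se_tilde` when the covariance is available).
#' @param x A `refined_coef` object.
#' @param ... Unused.
#' @export
tidy.refined_coef <- function(x, ...) {
  out <- tibble::tibble(snp_id = x$snp_ids, b = x$source_b,
                        b_tilde = x$b_tilde)
  if (!is.null(x$cov_b_tilde)) out$se_tilde <- sqrt(diag(x$cov_b_tilde))
  out
}

#' @export
print.refined_coef <- function(x, ...) {
  cat("<refined_coef> ", length(x$b_tilde), " instruments\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
print.theta_matrix <- function(x, ...) {
  cat("<theta_matrix> ", nrow(x$theta), " x ", ncol(x$theta),
      ", condition number ", format(x$condition_number, digits = 4), "\n",
      sep = "")
  invisible(x)
}
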