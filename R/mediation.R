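#' Sobel test of an indirect (mediated) effect
#'
#' For an upstream -> mediator effect `a` and a mediator -> outcome effect
#' `b`, the indirect effect is `a * b` with standard error
#' `sqrt(a^2 se_b^2 + b^2 se_a^2)` and a two-sided normal p-value. When both
#' `a` and `b` are zero the statistic is defined as 0 with p = 1.
#'
#' @param a,se_a Upstream-on-mediator effect and its SE (from MR).
#' @param b,se_b Mediator-on-outcome effect and its SE (from MR).
#' @param upstream_label,mediator_label,outcome_label Node labels.
#' @return A one-row tibble with `a`, `se_a`, `b`, `se_b`, `indirect`,
#'   `se_indirect`, `z`, `pvalue` and the labels.
#' @examples
#' sobel_test(0.5, 0.1, 0.4, 0.1)
#' @export
sobel_test <- function(a, se_a, b, se_b, upstream_label = "upstream",
                       mediator_label = "mediator",
                       outcome_label = "outcome") {
  if (any(se_a <= 0) || any(se_b <= 0)) {
    abort("sobel_test: standard errors must be positive")
  }
  indirect <- a * b
  se_indirect <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  z <- ifelse(se_indirect > 0, indirect / se_indirect, 0)
  pvalue <- ifelse(se_indirect > 0, 2 * pnorm(-abs(z)), 1)
  tibble::tibble(upstream = upstream_label, mediator = mediator_label,
                 outcome = outcome_label, a = a, se_a = se_a, b = b,
                 se_b = se_b, indirect = indirect,
                 se_indirect = se_indirect, z = z, pvalue = pvalue)
}

#' Two-step MR mediation network
#'
#' Links two collections of MR estimates: step 1 (upstream traits on
#' candidate mediators) and step 2 (mediators on the final outcome). For
#' every upstream -> mediator edge significant in step 1 whose mediator is
#' itself significant in step 2, a Sobel mediation record is emitted, giving
#' the indirect effect of the upstream trait on the outcome through that
#' mediator. Within each step, significance is assessed on
#' Bonferroni-adjusted p-values at level `alpha` (adjusted within the step's
#' own family unless the table already carries `pvalue_adjusted`).
#'
#' @param step1 Tibble of MR estimates with columns `exposure`, `outcome`,
#'   `beta`, `se`, `pvalue` (and optionally `pvalue_adjusted`): upstream ->
#'   mediator.
#' @param step2 Same schema: mediator -> final outcome.
#' @param alpha Significance level applied to the adjusted p-values.
#' @return A tibble of mediation records (one per retained upstream ->
#'   mediator -> outcome path) with an `effect_sign` column for network
#'   rendering; zero rows when nothing is significant.
#' @export
two_step_network <- function(step1, step2, alpha = 0.05) {
  prep <- function(df) {
    df <- tibble::as_tibble(df)
    if (!"pvalue_adjusted" %in% names(df) ||
        all(is.na(df$pvalue_adjusted))) {
      df$pvalue_adjusted <- bonferroni(df$pvalue)
    }
    df[df$pvalue_adjusted < alpha, , drop = FALSE]
  }
  s1 <- prep(step1)
  s2 <- prep(step2)
  if (nrow(s1) == 0 || nrow(s2) == 0) {
    return(tibble::tibble(upstream = character(), mediator = character(),
                          outcome = character(), a = numeric(),
                          se_a = numeric(), b = numeric(), se_b = numeric(),
                          indirect = numeric(), se_indirect = numeric(),
                          z = numeric(), pvalue = numeric(),
                          effect_sign = numeric()))
  }
  pairs <- dplyr::inner_join(
    dplyr::select(s1, upstream = "exposure", mediator = "outcome",
                  a = "beta", se_a = "se"),
    dplyr::select(s2, mediator = "exposure", final_outcome = "outcome",
                  b = "beta", se_b = "se"),
    by = "mediator")
  out <- sobel_test(pairs$a, pairs$se_a, pairs$b, pairs$se_b,
                    upstream_label = pairs$upstream,
                    mediator_label = pairs$mediator,
                    outcome_label = pairs$final_outcome)
  out$effect_sign <- sign(out$indirect)
  out
}

#' Write a mediation edge list as TSV
#'
#' @param network Tibble from [two_step_network()].
#' @param path Output path.
#' @return `network`, invisibly.
#' @export
write_network <- function(network, path) {
  readr::write_tsv(network, path, progress = FALSE)
  invisible(network)
}
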