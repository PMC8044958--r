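#' Full summary-data MR pipeline
#'
#' Runs the complete analysis for one exposure-outcome pair: harmonize the
#' two summary datasets against the LD reference, select instruments by
#' exposure p-value, LD-prune them, apply the pleiotropy outlier filter,
#' refine the exposure coefficients through the LD reference, and compute
#' every requested estimator. Per-stage SNP counts are recorded so the
#' instrument attrition funnel is reproducible.
#'
#' @param exposure,outcome `sumstats` tibbles from [read_sumstats()] (or
#'   paths, which are read with `column_map`).
#' @param reference An [ld_reference][build_reference] (or a path to a VCF /
#'   dosage panel, which is read and built with `variance_mode = "hwe"` for
#'   genotype input).
#' @param p_threshold Exposure p-value cutoff for instrument selection
#'   (default `5e-8`, the genome-wide significance convention).
#' @param r2_prune LD-pruning threshold on squared correlation (default 0.5).
#' @param heidi_alpha Pleiotropy-filter threshold (default 0.01); `NULL`
#'   disables the filter.
#' @param methods Estimators to run.
#' @param column_map Column mapping used when `exposure`/`outcome` are paths.
#' @param m_tests Family size for the Bonferroni adjustment of the returned
#'   p-values (defaults to the number of estimates produced by this call;
#'   pass the scan-wide count when the call is part of a larger scan).
#' @return A tibble of class `mr_scan` with one row per method (schema of
#'   [write_results()]); attributes `stages` (per-stage SNP counts),
#'   `removed` (SNP-level removals with reasons) and `provenance` (config
#'   echo).
#' @export
run_mr <- function(exposure, outcome, reference, p_threshold = 5e-8,
                   r2_prune = 0.5, heidi_alpha = 0.01,
                   methods = c("mr_river", "ivw", "gls"),
                   column_map = sumstats_cols(), m_tests = NULL) {
  if (is.character(exposure)) {
    exposure <- read_sumstats(exposure, column_map, side = "exposure")
  }
  if (is.character(outcome)) {
    outcome <- read_sumstats(outcome, column_map, side = "outcome")
  }
  if (is.character(reference)) {
    panel <- if (grepl("\\.vcf(\\.gz)?$", reference)) {
      read_vcf_panel(reference)
    } else {
      read_dosage_panel(reference)
    }
    reference <- build_reference(panel, variance_mode = "hwe")
  }
  stages <- c(exposure_input = nrow(exposure), outcome_input = nrow(outcome))

  h <- harmonize(exposure, outcome, reference)
  removed <- tibble::tibble(snp_id = character(), reason = character())
  stages["harmonized"] <- nrow(h$exposure)

  keep <- h$exposure$pvalue < p_threshold
  removed <- dplyr::bind_rows(removed, tibble::tibble(
    snp_id = h$exposure$snp_id[!keep], reason = "above-p-threshold"))
  exp <- h$exposure[keep, , drop = FALSE]
  out <- h$outcome[keep, , drop = FALSE]
  if (nrow(exp) == 0) {
    abort("run_mr: no instruments pass the exposure p-value threshold")
  }
  stages["p_selected"] <- nrow(exp)

  ref <- subset_reference(reference, exp$snp_id)
  kept_ids <- ld_prune(ref, setNames(exp$pvalue, exp$snp_id), r2_prune)
  removed <- dplyr::bind_rows(removed, tibble::tibble(
    snp_id = setdiff(exp$snp_id, kept_ids), reason = "ld-pruned"))
  idx <- match(kept_ids, exp$snp_id)
  exp <- exp[idx, , drop = FALSE]
  out <- out[idx, , drop = FALSE]
  ref <- subset_reference(ref, kept_ids)
  stages["ld_pruned"] <- nrow(exp)

  if (!is.null(heidi_alpha)) {
    hf <- heidi_filter(
      tibble::tibble(snp_id = exp$snp_id, b_xz = exp$beta, se_xz = exp$se,
                     pvalue_xz = exp$pvalue, b_yz = out$beta,
                     se_yz = out$se),
      rho = ref$rho, alpha = heidi_alpha)
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      snp_id = hf$removed, reason = "heidi-outlier"))
    idx <- match(hf$retained, exp$snp_id)
    idx <- sort(idx)
    exp <- exp[idx, , drop = FALSE]
    out <- out[idx, , drop = FALSE]
    ref <- subset_reference(ref, exp$snp_id)
  }
  stages["heidi_filtered"] <- nrow(exp)

  theta <- build_theta(ref)
  rc <- refine_coefficients(exp$beta, theta, se_xz = exp$se)

  labels <- list(exposure = attr(exposure, "trait_label") %||% "exposure",
                 outcome = attr(outcome, "trait_label") %||% "outcome")
  results <- lapply(methods, function(m) {
    est <- switch(m,
      mr_river = mr_river(b_tilde = rc$b_tilde, b_xz = exp$beta,
                          b_yz = out$beta, se_yz = out$se, rho = ref$rho,
                          exposure = labels$exposure,
                          outcome = labels$outcome),
      ivw = mr_ivw(b_xz = exp$beta, b_yz = out$beta, se_yz = out$se,
                   rho = ref$rho, exposure = labels$exposure,
                   outcome = labels$outcome),
      gls = mr_gls(b_xz = exp$beta, se_xz = exp$se, b_yz = out$beta,
                   se_yz = out$se, rho = ref$rho,
                   exposure = labels$exposure, outcome = labels$outcome),
      abort(paste0("run_mr: unknown method: ", m)))
    est$estimate
  })
  res <- dplyr::bind_rows(results)
  res$pvalue_adjusted <- bonferroni(res$pvalue, m = m_tests %||% nrow(res))
  structure(res, class = c("mr_scan", class(res)),
            stages = stages, removed = removed,
            refined = rc,
            provenance = list(p_threshold = p_threshold,
                              r2_prune = r2_prune,
                              heidi_alpha = heidi_alpha,
                              methods = methods,
                              stages = as.list(stages)))
}

#' Run a named simulation study from a configuration list
#'
#' Thin dispatcher over [simulate_refine_study()] and [simulate_mr_study()]
#' for config-file-driven runs (YAML/JSON parsed upstream into a list).
#'
#' @param study `"refine"` or `"mr"`.
#' @param config Named list of fields for [refine_sim_config()] or
#'   [mr_sim_config()].
#' @param ... Passed to the study function (e.g. `methods`, `alpha`).
#' @return The study's result object.
#' @export
run_simulation <- function(study, config = list(), ...) {
  switch(study,
    refine = simulate_refine_study(do.call(refine_sim_config, config)),
    mr = simulate_mr_study(do.call(mr_sim_config, config), ...),
    abort(paste0("run_simulation: unknown study: ", study)))
}

#' @export
print.mr_scan <- function(x, ...) {
  stages <- attr(x, "stages")
  cat("<mr_scan> instrument funnel: ",
      paste(names(stages), stages, sep = "=", collapse = " -> "), "\n",
      sep = "")
  NextMethod()
}
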