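#' Default column mapping for GWAS/mQTL summary-statistic files
#'
#' The default header dialect (`SNP`, `A1`, `A2`, `freq`, `b`, `se`, `p`, `N`)
#' is the one used by most public mQTL and GWAS releases. Override any entry
#' to match the file at hand, e.g. `sumstats_cols(snp_id = "rsid", n = NULL)`.
#' Set `n = NULL` (or any field's entry) to mark a column as absent.
#'
#' @param snp_id,effect_allele,other_allele,eaf,beta,se,pvalue,n File header
#'   names for the corresponding record fields; `NULL` means the column is not
#'   present in the file (allowed for `eaf` and `n` only).
#' @return A named list mapping record fields to file headers.
#' @export
sumstats_cols <- function(snp_id = "SNP", effect_allele = "A1",
                          other_allele = "A2", eaf = "freq", beta = "b",
                          se = "se", pvalue = "p", n = "N") {
  list(snp_id = snp_id, effect_allele = effect_allele,
       other_allele = other_allele, eaf = eaf, beta = beta, se = se,
       pvalue = pvalue, n = n)
}

new_sumstats <- function(df, trait_label, side) {
  stopifnot(side %in% c("exposure", "outcome"))
  structure(df, class = c("sumstats", class(tibble::tibble())),
            trait_label = trait_label, side = side)
}

#' Read GWAS summary statistics
#'
#' Reads a delimited (whitespace, tab or comma; optionally gzipped) summary
#' file into a validated tibble of per-SNP association records. Rows that
#' violate the record invariants (identical alleles, non-ACGT alleles,
#' `se <= 0`, `eaf` outside \[0, 1\], `pvalue` outside (0, 1\], non-positive
#' `n`, or unparseable numbers) are dropped and counted; the tally is attached
#' as the `"n_dropped"` attribute and reported via a message.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Mapping from record fields to file headers, as produced by
#'   [sumstats_cols()].
#' @param side `"exposure"` or `"outcome"` — which side of the two-sample MR
#'   design this file describes.
#' @param trait_label Trait name carried through to results.
#' @return A tibble of class `sumstats` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`;
#'   attributes `trait_label`, `side`, `n_dropped`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tA1\tA2\tfreq\tb\tse\tp\tN",
#'              "rs1\tA\tG\t0.2\t0.1\t0.02\t5e-7\t1000"), tf)
#' read_sumstats(tf, side = "exposure", trait_label = "metabolite")
#' @export
read_sumstats <- function(path, column_map = sumstats_cols(),
                          side = c("exposure", "outcome"),
                          trait_label = "trait") {
  side <- match.arg(side)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (ncol(raw) <= 1) { # not whitespace-delimited; let readr guess , or \t
    raw <- readr::read_delim(path, col_types = readr::cols(.default = "c"),
                             progress = FALSE, show_col_types = FALSE)
  }
  if (nrow(raw) == 0) abort(paste0("empty summary-statistics file: ", path))

  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
                 "pvalue")
  for (field in mandatory) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      abort(paste0("mandatory column missing from ", path, ": ", field,
                   " (expected header '", col %||% "<unmapped>", "')"))
    }
  }
  pick <- function(field) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw)) rep(NA_character_, nrow(raw))
    else raw[[col]]
  }
  df <- tibble::tibble(
    snp_id = pick("snp_id"),
    effect_allele = toupper(pick("effect_allele")),
    other_allele = toupper(pick("other_allele")),
    eaf = suppressWarnings(as.numeric(pick("eaf"))),
    beta = suppressWarnings(as.numeric(pick("beta"))),
    se = suppressWarnings(as.numeric(pick("se"))),
    pvalue = suppressWarnings(as.numeric(pick("pvalue"))),
    n = suppressWarnings(as.numeric(pick("n")))
  )

  bases <- c("A", "C", "G", "T")
  ok <- !is.na(df$snp_id) &
    df$effect_allele %in% bases & df$other_allele %in% bases &
    df$effect_allele != df$other_allele &
    is.finite(df$beta) &
    is.finite(df$se) & df$se > 0 &
    is.finite(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1 &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)) &
    (is.na(df$n) | df$n > 0)
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  df <- df[!duplicated(df$snp_id), , drop = FALSE]
  if (nrow(df) == 0) abort(paste0("no valid records in ", path))
  if (n_dropped > 0) {
    inform(paste0("read_sumstats: dropped ", n_dropped,
                  " malformed record(s) from ", basename(path)))
  }
  out <- new_sumstats(df, trait_label, side)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write summary statistics back to disk
#'
#' Emits the default header dialect (`SNP A1 A2 freq b se p N`),
#' tab-delimited, preserving row order so that read/write round-trips are
#' stable.
#'
#' @param data A `sumstats` tibble (or any data frame with the same columns).
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_sumstats <- function(data, path) {
  out <- tibble::tibble(SNP = data$snp_id, A1 = data$effect_allele,
                        A2 = data$other_allele, freq = data$eaf,
                        b = data$beta, se = data$se, p = data$pvalue,
                        N = data$n)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(data)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Restricts both datasets to their shared SNPs, places the outcome effects on
#' the exposure's effect-allele convention (flipping the outcome beta sign and
#' replacing `eaf` by `1 - eaf` where the allele pair is swapped), removes
#' strand-ambiguous palindromic SNPs (A/T or C/G) whose effect-allele
#' frequency lies in `palindromic_window` on either side, removes SNPs whose
#' allele pairs cannot be reconciled, and (when `reference` is supplied)
#' removes SNPs absent from the LD reference. Output order follows the
#' exposure dataset. Removal counts per reason are attached as the
#' `"removals"` attribute of the returned list.
#'
#' @param exposure,outcome `sumstats` tibbles from [read_sumstats()].
#' @param reference Optional LD reference from [build_reference()]; SNPs it
#'   lacks are dropped.
#' @param palindromic_window Frequency window within which palindromic SNPs
#'   are considered unresolvable (default `c(0.4, 0.6)`, the conservative
#'   community default).
#' @return A list with elements `exposure` and `outcome` (harmonized
#'   `sumstats` tibbles with identical `snp_id` order) and attribute
#'   `removals`, a tibble of per-reason removal counts.
#' @export
harmonize <- function(exposure, outcome, reference = NULL,
                      palindromic_window = c(0.4, 0.6)) {
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    abort("harmonize: both datasets must be non-empty")
  }
  removals <- c(not_shared = 0, allele_mismatch = 0,
                `palindromic-ambiguous` = 0, not_in_reference = 0)

  shared <- exposure$snp_id[exposure$snp_id %in% outcome$snp_id]
  removals["not_shared"] <-
    (nrow(exposure) - length(shared)) + (nrow(outcome) - length(shared))
  exp <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  out <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  same <- exp$effect_allele == out$effect_allele &
    exp$other_allele == out$other_allele
  swapped <- exp$effect_allele == out$other_allele &
    exp$other_allele == out$effect_allele
  mismatch <- !(same | swapped)
  removals["allele_mismatch"] <- sum(mismatch)

  # flip swapped outcome records onto the exposure convention
  out$beta[swapped] <- -out$beta[swapped]
  out$eaf[swapped] <- 1 - out$eaf[swapped]
  out$effect_allele[swapped] <- exp$effect_allele[swapped]
  out$other_allele[swapped] <- exp$other_allele[swapped]

  lo <- palindromic_window[1]; hi <- palindromic_window[2]
  ambiguous_freq <- function(f) !is.na(f) & f >= lo & f <= hi
  pal <- is_palindromic(exp$effect_allele, exp$other_allele) &
    (ambiguous_freq(exp$eaf) | ambiguous_freq(out$eaf))
  removals["palindromic-ambiguous"] <- sum(pal & !mismatch)

  keep <- !mismatch & !pal
  if (!is.null(reference)) {
    in_ref <- exp$snp_id %in% reference$snp_ids
    removals["not_in_reference"] <- sum(keep & !in_ref)
    keep <- keep & in_ref
  }
  exp <- exp[keep, , drop = FALSE]
  out <- out[keep, , drop = FALSE]
  if (nrow(exp) == 0) abort("harmonize: zero SNPs left after harmonization")

  res <- list(
    exposure = new_sumstats(exp, attr(exposure, "trait_label"), "exposure"),
    outcome = new_sumstats(out, attr(outcome, "trait_label"), "outcome")
  )
  attr(res, "removals") <- tibble::tibble(reason = names(removals),
                                          n = unname(removals))
  res
}

#' Write MR estimates to a tab-delimited file
#'
#' One row per estimate with the columns `exposure`, `outcome`, `method`,
#' `n_ivs`, `beta`, `se`, `z`, `pvalue`, `pvalue_adjusted`, in input order at
#' full precision. An empty input yields a header-only file.
#'
#' @param estimates A tibble of MR estimates, e.g. rows returned by
#'   [glance.mr_result()] or the result table from [run_mr()].
#' @param path Output path.
#' @return `estimates`, invisibly.
#' @export
write_results <- function(estimates, path) {
  cols <- c("exposure", "outcome", "method", "n_ivs", "beta", "se", "z",
            "pvalue", "pvalue_adjusted")
  est <- as.data.frame(estimates)
  for (col in setdiff(cols, names(est))) est[[col]] <- rep(NA, nrow(est))
  est <- est[, cols, drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(est) > 0) {
    fmt <- function(x) {
      if (is.numeric(x)) vapply(x, function(v) format(v, digits = 17),
                                character(1)) else as.character(x)
    }
    body <- do.call(paste, c(lapply(est, fmt), sep = "\t"))
    writeLines(body, con)
  }
  invisible(estimates)
}

#' @export
print.sumstats <- function(x, ...) {
  cat("<sumstats> ", attr(x, "side"), " side, trait '",
      attr(x, "trait_label"), "', ", nrow(x), " SNPs\n", sep = "")
  NextMethod()
}
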