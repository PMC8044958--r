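#' Genotype panel constructor
#'
#' A genotype panel holds effect-allele dosages (0/1/2, `NA` allowed) for the
#' candidate instruments, one row per reference individual, and is the raw
#' material for [build_reference()].
#'
#' @param dosages Numeric matrix, individuals x SNPs, entries in
#'   \{0, 1, 2, NA\}.
#' @param snp_ids Character vector of SNP identifiers (defaults to column
#'   names of `dosages`).
#' @param effect_alleles Per-SNP counted allele (defaults to `"A"`).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, snp_ids = colnames(dosages),
                           effect_alleles = rep("A", ncol(dosages))) {
  dosages <- as.matrix(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  if (anyDuplicated(snp_ids)) abort("genotype_panel: duplicate snp_ids")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) abort("genotype_panel: dosages must be 0, 1, 2 or NA")
  colnames(dosages) <- snp_ids
  structure(list(snp_ids = snp_ids, dosages = dosages,
                 effect_alleles = effect_alleles),
            class = "genotype_panel")
}

#' Read a genotype panel from a delimited dosage matrix
#'
#' The file must have a header of SNP ids and one row per individual; fields
#' are effect-allele counts (0/1/2) with `NA` for missing.
#'
#' @param path Path to the (optionally gzipped) delimited file.
#' @return A `genotype_panel`.
#' @export
read_dosage_panel <- function(path) {
  df <- readr::read_table(path, col_types = readr::cols(.default = "d"),
                          progress = FALSE, na = c("NA", "."))
  genotype_panel(as.matrix(df), snp_ids = names(df))
}

#' Read a genotype panel from a VCF file
#'
#' Dosage is the count of the record's ALT allele in the GT field.
#' Multi-allelic sites are rejected.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A `genotype_panel`.
#' @export
read_vcf_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) {
    abort("read_vcf_panel: multi-allelic sites are not supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"),
                  numeric(1)))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
  ids <- vcfR::getID(v)
  if (anyNA(ids)) ids <- paste0("snp", seq_along(ids))
  genotype_panel(t(dos), snp_ids = ids, effect_alleles = alt)
}

#' Write a genotype panel as a minimal VCF
#'
#' Emits an unphased GT-only VCFv4.2 file; primarily used to exercise the VCF
#' ingestion path with programmatically generated fixtures.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @param ref_alleles,alt_alleles Optional REF/ALT bases; ALT defaults to the
#'   panel's effect alleles and REF to a different base.
#' @return `panel`, invisibly.
#' @export
write_vcf_panel <- function(panel, path, ref_alleles = NULL,
                            alt_alleles = NULL) {
  p <- length(panel$snp_ids)
  alt <- alt_alleles %||% panel$effect_alleles
  ref <- ref_alleles %||% ifelse(alt == "A", "G", "A")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  n <- nrow(panel$dosages)
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("ind", seq_len(n))), collapse = "\t")
  )
  for (j in seq_len(p)) {
    d <- panel$dosages[, j]
    g <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    lines <- c(lines, paste(c("1", j, panel$snp_ids[j], ref[j], alt[j], ".",
                              "PASS", ".", "GT", g), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(panel)
}

#' Build an LD reference from a genotype panel
#'
#' Computes the SNP-SNP Pearson correlation matrix (pairwise-complete over
#' non-missing individuals) and per-SNP variances. Variances are either the
#' empirical column variance (`"empirical"`) or the Hardy-Weinberg value
#' `2 p (1 - p)` at the observed effect-allele frequency (`"hwe"`, the
#' default, matching the use of public allele-frequency resources).
#'
#' @param panel A `genotype_panel`, or a plain numeric matrix of per-SNP
#'   measurements (individuals x SNPs; used for Gaussian instruments in
#'   simulations, where `variance_mode` must be `"empirical"`).
#' @param variance_mode `"hwe"` or `"empirical"`.
#' @return An object of class `ld_reference`: list with `snp_ids`, `rho`
#'   (symmetric correlation matrix with unit diagonal) and `variances`.
#' @export
build_reference <- function(panel, variance_mode = c("hwe", "empirical")) {
  variance_mode <- match.arg(variance_mode)
  if (inherits(panel, "genotype_panel")) {
    mat <- panel$dosages
    ids <- panel$snp_ids
  } else {
    mat <- as.matrix(panel)
    ids <- colnames(mat) %||% paste0("snp", seq_len(ncol(mat)))
    if (variance_mode == "hwe") {
      abort("build_reference: hwe variance mode requires a genotype_panel")
    }
  }
  if (nrow(mat) < 2) abort("build_reference: need at least 2 individuals")
  n_obs <- colSums(!is.na(mat))
  v_emp <- apply(mat, 2, var, na.rm = TRUE)
  bad <- n_obs < 2 | !is.finite(v_emp) | v_emp <= 0
  if (any(bad)) {
    abort(paste0("build_reference: monomorphic or unusable SNP(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  rho <- cor(mat, use = "pairwise.complete.obs")
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(ids, ids)
  variances <- if (variance_mode == "hwe") {
    p_hat <- colMeans(mat, na.rm = TRUE) / 2
    2 * p_hat * (1 - p_hat)
  } else {
    v_emp
  }
  structure(list(snp_ids = ids, rho = rho,
                 variances = setNames(as.numeric(variances), ids)),
            class = "ld_reference")
}

#' Subset an LD reference to a set of SNPs, preserving its order
#'
#' @param reference An `ld_reference`.
#' @param snp_ids SNPs to keep (must all be present).
#' @return An `ld_reference` restricted to `snp_ids`, in the given order.
#' @export
subset_reference <- function(reference, snp_ids) {
  idx <- match(snp_ids, reference$snp_ids)
  if (anyNA(idx)) abort("subset_reference: SNP(s) missing from reference")
  structure(list(snp_ids = reference$snp_ids[idx],
                 rho = reference$rho[idx, idx, drop = FALSE],
                 variances = reference$variances[idx]),
            class = "ld_reference")
}

#' Greedy LD pruning of candidate instruments
#'
#' Visits SNPs in ascending exposure p-value (ties broken lexicographically by
#' SNP id) and retains a SNP iff its squared correlation with every
#' already-retained SNP is at most `r2_threshold` — the standard clumping
#' rule. The returned ids preserve the reference's SNP order.
#'
#' @param reference An `ld_reference`.
#' @param pvalues Named numeric vector of exposure p-values covering every
#'   reference SNP (names = SNP ids), or an unnamed vector in reference order.
#' @param r2_threshold Squared-correlation threshold in (0, 1\].
#' @return Character vector of retained SNP ids, in reference order.
#' @export
ld_prune <- function(reference, pvalues, r2_threshold = 0.5) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    abort("ld_prune: r2_threshold must be in (0, 1]")
  }
  ids <- reference$snp_ids
  if (!is.null(names(pvalues))) {
    if (!all(ids %in% names(pvalues))) {
      abort("ld_prune: pvalues must cover all reference SNPs")
    }
    pvalues <- pvalues[ids]
  } else if (length(pvalues) != length(ids)) {
    abort("ld_prune: pvalues must cover all reference SNPs")
  }
  visit <- order(pvalues, ids)
  rho <- reference$rho
  retained <- integer(0)
  for (i in visit) {
    if (all(rho[i, retained]^2 <= r2_threshold)) retained <- c(retained, i)
  }
  ids[sort(retained)]
}

#' @export
print.ld_reference <- function(x, ...) {
  cat("<ld_reference> ", length(x$snp_ids), " SNPs; mean |rho| off-diagonal = ",
      signif(mean(abs(x$rho[upper.tri(x$rho)])), 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$dosages), " individuals x ",
      length(x$snp_ids), " SNPs\n", sep = "")
  invisible(x)
}
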