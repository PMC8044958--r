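#!/usr/bin/env Rscript
# Optional real-data benchmark: blood metabolites -> educational attainment.
#
# This script is network/data dependent and is NOT run by the test suite.
# It needs three locally downloaded inputs:
#
#   --edu     EduYears GWAS summary statistics (SSGAC; https://www.thessgac.org/data),
#             tab-delimited with columns mappable to SNP/A1/A2/freq/b/se/p/N.
#   --mqtl-dir  Directory of per-metabolite QTL summary files
#             (http://metabolomics.helmholtz-muenchen.de/gwas), one file per
#             metabolite, same column dialect.
#   --panel   1000 Genomes EUR reference genotypes for the instrument SNPs,
#             as VCF (bi-allelic records only) or a 0/1/2 dosage matrix.
#
# For each metabolite: select instruments at p < 5e-8, prune at r2 = 0.5,
# filter pleiotropic outliers at alpha = 0.01, refine through the panel and
# estimate with the refined-score and GLS estimators; Bonferroni-adjust
# across metabolites. Estimates for butyrylcarnitine, 1,5-anhydroglucitol
# and homocitrulline are the benchmark quantities; expect agreement to
# roughly two significant figures, with residual differences driven by the
# LD-panel version and release of the summary files.
#
#   Rscript scripts/realdata-benchmark.R --edu edu.tsv.gz \
#       --mqtl-dir mqtl/ --panel eur_instruments.vcf.gz --out benchmark.tsv

suppressPackageStartupMessages({
  library(optparse)
  library(mrriver)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--edu", type = "character"),
  make_option("--mqtl-dir", type = "character", dest = "mqtl_dir"),
  make_option("--panel", type = "character"),
  make_option("--out", type = "character", default = "benchmark.tsv")
)))
stopifnot(!is.null(opts$edu), !is.null(opts$mqtl_dir), !is.null(opts$panel))

outcome <- read_sumstats(opts$edu, side = "outcome", trait_label = "EduYears")
panel <- if (grepl("\\.vcf(\\.gz)?$", opts$panel)) {
  read_vcf_panel(opts$panel)
} else {
  read_dosage_panel(opts$panel)
}
reference <- build_reference(panel, variance_mode = "hwe")

mqtl_files <- list.files(opts$mqtl_dir, full.names = TRUE)
message("scanning ", length(mqtl_files), " metabolite QTL files")

scan_one <- function(path) {
  label <- sub("\\.[^.]*(\\.gz)?$", "", basename(path))
  tryCatch({
    exposure <- read_sumstats(path, side = "exposure", trait_label = label)
    run_mr(exposure, outcome, reference, p_threshold = 5e-8,
           r2_prune = 0.5, heidi_alpha = 0.01,
           methods = c("mr_river", "gls"))
  }, error = function(e) {
    message(label, ": skipped (", conditionMessage(e), ")")
    NULL
  })
}

results <- dplyr::bind_rows(lapply(mqtl_files, scan_one))
# adjust across the whole scan, separately per method
results <- results |>
  dplyr::group_by(method) |>
  dplyr::mutate(pvalue_adjusted = bonferroni(pvalue)) |>
  dplyr::ungroup()

write_results(results, opts$out)
message("wrote ", opts$out)
print(dplyr::filter(results, pvalue_adjusted < 0.05))
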