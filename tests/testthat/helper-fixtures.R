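# shared fixture builders; everything is generated in code at test time

make_sumstats <- function(n = 5, side = "exposure", seed = 42,
                          snp_ids = sprintf("rs%04d", seq_len(n))) {
  set.seed(seed)
  df <- tibble::tibble(
    snp_id = snp_ids,
    effect_allele = sample(c("A", "C"), n, replace = TRUE),
    other_allele = "G",
    eaf = round(runif(n, 0.05, 0.95), 3),
    beta = round(rnorm(n, 0, 0.1), 4),
    se = round(runif(n, 0.01, 0.05), 4),
    pvalue = round(runif(n, 1e-10, 0.99), 6),
    n = 1000
  )
  mrriver:::new_sumstats(df, "trait", side)
}

write_sumstats_file <- function(data, path = tempfile(fileext = ".tsv")) {
  write_sumstats(data, path)
  path
}

# direct ld_reference construction for algebraic tests
make_reference <- function(rho, variances = rep(1, nrow(rho)),
                           snp_ids = paste0("s", seq_len(nrow(rho)))) {
  dimnames(rho) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, rho = rho,
                 variances = stats::setNames(variances, snp_ids)),
            class = "ld_reference")
}

equicorr <- function(p, rho) {
  m <- matrix(rho, p, p)
  diag(m) <- 1
  m
}
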