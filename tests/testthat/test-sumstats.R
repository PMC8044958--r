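test_that("well-formed files round-trip with nothing dropped", {
  ss <- make_sumstats(3)
  path <- write_sumstats_file(ss)
  got <- read_sumstats(path, side = "exposure")
  expect_equal(nrow(got), 3)
  expect_equal(attr(got, "n_dropped"), 0)
  expect_equal(got$snp_id, ss$snp_id)
  expect_equal(got$beta, ss$beta)
  expect_equal(got$se, ss$se)
  # write -> read -> write fixpoint
  path2 <- tempfile(fileext = ".tsv")
  write_sumstats(got, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invariant-violating rows are dropped and tallied", {
  ss <- make_sumstats(4)
  ss$se[2] <- 0             # se must be > 0
  ss$effect_allele[3] <- ss$other_allele[3]  # identical alleles
  path <- write_sumstats_file(ss)
  expect_message(got <- read_sumstats(path, side = "exposure"),
                 "dropped 2")
  expect_equal(nrow(got), 2)
  expect_equal(attr(got, "n_dropped"), 2)
  expect_false(any(got$snp_id %in% ss$snp_id[2:3]))
})

test_that("lowercase alleles are parsed case-insensitively and re-emitted uppercase", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tfreq\tb\tse\tp\tN",
               "rs1\ta\tg\t0.2\t0.1\t0.02\t5e-7\t1000"), path)
  got <- read_sumstats(path, side = "exposure")
  expect_equal(got$effect_allele, "A")
  expect_equal(got$other_allele, "G")
  path2 <- tempfile(fileext = ".tsv")
  write_sumstats(got, path2)
  again <- read_sumstats(path2, side = "exposure")
  expect_equal(as.data.frame(again), as.data.frame(got))
})

test_that("missing mandatory columns and empty files are hard errors", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tfreq\tb\tse\tp\tN",
               "rs1\tA\t0.2\t0.1\t0.02\t5e-7\t1000"), path)
  expect_error(read_sumstats(path, side = "exposure"), "other_allele")
  empty <- tempfile(fileext = ".tsv")
  writeLines("SNP\tA1\tA2\tfreq\tb\tse\tp\tN", empty)
  expect_error(read_sumstats(empty, side = "exposure"), "empty|no valid")
  expect_error(read_sumstats(tempfile(), side = "exposure"), "not found")
})

test_that("custom column maps and comma/gzip input are honoured", {
  path <- tempfile(fileext = ".csv.gz")
  con <- gzfile(path, "wt")
  writeLines(c("rsid,EA,OA,af,est,stderr,pval,size",
               "rs9,T,C,0.31,0.05,0.01,0.001,500"), con)
  close(con)
  got <- read_sumstats(path,
                       sumstats_cols(snp_id = "rsid", effect_allele = "EA",
                                     other_allele = "OA", eaf = "af",
                                     beta = "est", se = "stderr",
                                     pvalue = "pval", n = "size"),
                       side = "outcome")
  expect_equal(got$snp_id, "rs9")
  expect_equal(got$beta, 0.05)
  expect_equal(attr(got, "side"), "outcome")
})

test_that("harmonize keeps identical coding unchanged and flips swapped alleles", {
  exp <- make_sumstats(4, side = "exposure")
  out <- make_sumstats(4, side = "outcome", seed = 99,
                       snp_ids = exp$snp_id)
  out$effect_allele <- exp$effect_allele
  out$other_allele <- exp$other_allele
  # swap SNP 2's coding on the outcome side
  out$effect_allele[2] <- exp$other_allele[2]
  out$other_allele[2] <- exp$effect_allele[2]
  b2 <- out$beta[2]; f2 <- out$eaf[2]
  h <- harmonize(exp, out)
  expect_equal(h$exposure$snp_id, h$outcome$snp_id)
  expect_equal(h$outcome$beta[2], -b2)
  expect_equal(h$outcome$eaf[2], 1 - f2)
  expect_equal(h$outcome$beta[-2], out$beta[-2])
  expect_equal(h$outcome$effect_allele, h$exposure$effect_allele)
})

test_that("ambiguous palindromic SNPs and reference-absent SNPs are removed with reasons", {
  exp <- make_sumstats(4, side = "exposure")
  out <- make_sumstats(4, side = "outcome", seed = 7, snp_ids = exp$snp_id)
  out$effect_allele <- exp$effect_allele
  out$other_allele <- exp$other_allele
  exp$effect_allele[1] <- "A"; exp$other_allele[1] <- "T"
  out$effect_allele[1] <- "A"; out$other_allele[1] <- "T"
  exp$eaf[1] <- 0.5
  ref <- make_reference(equicorr(3, 0), snp_ids = exp$snp_id[2:4])
  h <- harmonize(exp, out, reference = ref)
  expect_false(exp$snp_id[1] %in% h$exposure$snp_id)
  removals <- attr(h, "removals")
  expect_equal(removals$n[removals$reason == "palindromic-ambiguous"], 1)
  # drop a SNP from the reference: it must be removed too
  ref2 <- make_reference(equicorr(2, 0), snp_ids = exp$snp_id[2:3])
  h2 <- harmonize(exp, out, reference = ref2)
  expect_setequal(h2$exposure$snp_id, exp$snp_id[2:3])
  r2 <- attr(h2, "removals")
  expect_equal(r2$n[r2$reason == "not_in_reference"], 1)
})

test_that("harmonize is idempotent and ordered by the exposure dataset", {
  exp <- make_sumstats(6, side = "exposure")
  out <- make_sumstats(6, side = "outcome", seed = 5, snp_ids = exp$snp_id)
  out$effect_allele <- exp$other_allele
  out$other_allele <- exp$effect_allele
  h1 <- harmonize(exp, out)
  h2 <- harmonize(h1$exposure, h1$outcome)
  expect_equal(as.data.frame(h2$exposure), as.data.frame(h1$exposure))
  expect_equal(as.data.frame(h2$outcome), as.data.frame(h1$outcome))
  # permuting the outcome rows changes nothing (order fixed by exposure)
  perm <- sample(seq_len(nrow(out)))
  h3 <- harmonize(exp, out[perm, ])
  expect_equal(as.data.frame(h3$outcome), as.data.frame(h1$outcome))
})

test_that("harmonize errors when nothing is shared", {
  exp <- make_sumstats(3, side = "exposure")
  out <- make_sumstats(3, side = "outcome",
                       snp_ids = c("rx1", "rx2", "rx3"))
  expect_error(harmonize(exp, out), "zero SNPs")
})

test_that("write_results emits the full schema, empty collections, and fixpoints", {
  path <- tempfile(fileext = ".tsv")
  write_results(tibble::tibble(), path)
  lines <- readLines(path)
  expect_equal(length(lines), 1)
  expect_match(lines, "^exposure\toutcome\tmethod\tn_ivs\tbeta\tse\tz")

  est <- glance(mr_river(b_tilde = 0.5, b_xz = 0.5, b_yz = 0.25,
                         se_yz = 0.1))
  write_results(est, path)
  expect_equal(length(readLines(path)), 2)
  back <- utils::read.delim(path)  # base parser is correctly rounded
  expect_equal(back$beta, est$beta)
  expect_equal(back$se, est$se)
  path2 <- tempfile(fileext = ".tsv")
  write_results(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
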