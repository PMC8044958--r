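test_that("refined-score estimator matches hand-computed values", {
  # independent instruments, b_tilde = b_xz: textbook IVW numbers
  r <- mr_river(b_tilde = c(0.5, 0.2), b_xz = c(0.5, 0.2),
                b_yz = c(0.3, 0.1), se_yz = c(0.1, 0.1))
  expect_equal(r$estimate$beta, 17 / 29, tolerance = 1e-12)
  expect_equal(r$estimate$se, sqrt(1 / 29), tolerance = 1e-12)
  # single instrument: Wald ratio with se = se_yz / |b_xz|
  r1 <- mr_river(b_tilde = 0.5, b_xz = 0.5, b_yz = 0.25, se_yz = 0.1)
  expect_equal(r1$estimate$beta, 0.5)
  expect_equal(r1$estimate$se, 0.1 / 0.5)
  # all-null outcome
  r0 <- mr_river(b_tilde = c(.5, .2), b_xz = c(.5, .2), b_yz = c(0, 0),
                 se_yz = c(.1, .1))
  expect_equal(r0$estimate$beta, 0)
  expect_equal(r0$estimate$pvalue, 1)
})

test_that("estimate invariants hold: z, p, and the se scaling law", {
  r <- mr_river(b_tilde = c(.4, .1), b_xz = c(.5, .2), b_yz = c(.3, .1),
                se_yz = c(.1, .2), rho = equicorr(2, 0.3))
  e <- r$estimate
  expect_equal(e$z, e$beta / e$se, tolerance = 1e-12)
  expect_equal(e$pvalue, 2 * pnorm(-abs(e$z)), tolerance = 1e-12)
  # doubling every outcome se doubles the causal se
  r2 <- mr_river(b_tilde = c(.4, .1), b_xz = c(.5, .2), b_yz = c(.3, .1),
                 se_yz = 2 * c(.1, .2), rho = equicorr(2, 0.3))
  expect_equal(r2$estimate$se, 2 * e$se, tolerance = 1e-12)
})

test_that("with independent instruments and b_tilde = b_xz, the refined estimator is IVW", {
  set.seed(21)
  for (p in c(1, 3, 8)) {
    b_xz <- rnorm(p, 0, 0.2)
    b_yz <- rnorm(p, 0, 0.1)
    se_yz <- runif(p, 0.02, 0.2)
    a <- mr_river(b_tilde = b_xz, b_xz = b_xz, b_yz = b_yz, se_yz = se_yz)
    b <- mr_ivw(b_xz = b_xz, b_yz = b_yz, se_yz = se_yz)
    expect_equal(a$estimate$beta, b$estimate$beta, tolerance = 1e-10)
    expect_equal(a$estimate$se, b$estimate$se, tolerance = 1e-10)
    # the delta-method se reduces to the classical IVW se
    expect_equal(a$estimate$se, 1 / sqrt(sum(b_xz^2 / se_yz^2)),
                 tolerance = 1e-10)
  }
})

test_that("the causal estimate and se are invariant to rescaling the refined weights", {
  set.seed(22)
  b_t <- rnorm(5); b_xz <- rnorm(5); b_yz <- rnorm(5)
  se_yz <- runif(5, 0.05, 0.3)
  rho <- equicorr(5, 0.4)
  base <- mr_river(b_tilde = b_t, b_xz = b_xz, b_yz = b_yz, se_yz = se_yz,
                   rho = rho)
  for (a in c(-3, 0.01, 7)) {
    sc <- mr_river(b_tilde = a * b_t, b_xz = b_xz, b_yz = b_yz,
                   se_yz = se_yz, rho = rho)
    expect_equal(sc$estimate$beta, base$estimate$beta, tolerance = 1e-10)
    expect_equal(sc$estimate$se, base$estimate$se, tolerance = 1e-10)
  }
})

test_that("every estimator reduces to the Wald ratio for one instrument and is sign-equivariant", {
  set.seed(23)
  est_all <- function(b_xz, se_xz, b_yz, se_yz, rho = NULL) {
    list(
      mr_river(b_tilde = b_xz, b_xz = b_xz, b_yz = b_yz, se_yz = se_yz,
               rho = rho),
      mr_ivw(b_xz = b_xz, b_yz = b_yz, se_yz = se_yz, rho = rho),
      mr_gls(b_xz = b_xz, se_xz = se_xz, b_yz = b_yz, se_yz = se_yz,
             rho = rho))
  }
  for (e in est_all(0.4, 0.05, 0.3, 0.1)) {
    expect_equal(e$estimate$beta, 0.3 / 0.4, tolerance = 1e-10)
  }
  b_xz <- rnorm(4, 0.3, 0.05); se_xz <- runif(4, .02, .1)
  b_yz <- rnorm(4, 0.1, 0.05); se_yz <- runif(4, .02, .1)
  rho <- equicorr(4, 0.25)
  pos <- est_all(b_xz, se_xz, b_yz, se_yz, rho)
  neg <- est_all(b_xz, se_xz, -b_yz, se_yz, rho)
  for (k in 1:3) {
    expect_equal(neg[[k]]$estimate$beta, -pos[[k]]$estimate$beta,
                 tolerance = 1e-10)
    expect_equal(neg[[k]]$estimate$se, pos[[k]]$estimate$se,
                 tolerance = 1e-10)
  }
})

test_that("GLS combination matches hand-computed inverse-variance weights", {
  # ratios 0.5 and 0.3 with variances 0.01 and 0.04: weights 100 and 25
  g <- mr_gls(b_xz = c(1, 1), se_xz = c(1e-9, 1e-9), b_yz = c(0.5, 0.3),
              se_yz = c(0.1, 0.2))
  expect_equal(g$estimate$beta, (100 * 0.5 + 25 * 0.3) / 125,
               tolerance = 1e-6)
  expect_equal(g$estimate$se, 1 / sqrt(125), tolerance = 1e-6)
  # a constant ratio vector is returned exactly
  g2 <- mr_gls(b_xz = c(.2, .4, .1), se_xz = c(.01, .02, .01),
               b_yz = 0.7 * c(.2, .4, .1), se_yz = c(.05, .04, .06))
  expect_equal(g2$estimate$beta, 0.7, tolerance = 1e-10)
  expect_error(mr_gls(b_xz = c(0.5, 0), se_xz = c(.1, .1),
                      b_yz = c(.1, .1), se_yz = c(.1, .1)),
               "undefined")
})

test_that("Wald test matches the normal quantiles", {
  expect_equal(wald_test(0, 1)$pvalue, 1)
  expect_equal(wald_test(1.959964, 1)$pvalue, 0.05, tolerance = 1e-6)
  expect_equal(wald_test(-1.959964, 1)$pvalue, 0.05, tolerance = 1e-6)
  expect_error(wald_test(1, 0), "positive")
})

test_that("the pleiotropy filter removes only gross Wald-ratio outliers", {
  # 5 instruments with identical ratios: nothing removed
  d <- tibble::tibble(snp_id = paste0("s", 1:5), b_xz = rep(0.5, 5),
                      se_xz = rep(0.01, 5), pvalue_xz = seq(1e-8, 1e-4,
                      length.out = 5), b_yz = rep(0.25, 5),
                      se_yz = rep(0.01, 5))
  f <- heidi_filter(d)
  expect_equal(f$removed, character(0))
  # make s3's ratio 10 sds away from the reference: var(d) = 2 * (0.01/0.5)^2
  # when ratios are equal; engineer b_yz so d / sd(d) = 10
  d2 <- d
  sd_d <- sqrt(2) * 0.01 / 0.5
  d2$b_yz[3] <- 0.25 + 10 * sd_d * 0.5
  f2 <- heidi_filter(d2, alpha = 0.01)
  expect_equal(f2$removed, "s3")
  expect_lt(f2$detail$p_het[3], 1e-10)
  # reference instrument (smallest exposure p) is never removed
  expect_true(f2$detail$is_reference[1])
  expect_true("s1" %in% f2$retained)
})

test_that("the pleiotropy filter is skipped with a warning below 3 instruments", {
  d <- tibble::tibble(snp_id = c("a", "b"), b_xz = c(.5, .4),
                      se_xz = c(.01, .01), pvalue_xz = c(1e-8, 1e-7),
                      b_yz = c(.1, .5), se_yz = c(.01, .01))
  expect_warning(f <- heidi_filter(d), "skipped")
  expect_equal(f$retained, c("a", "b"))
})

test_that("Bonferroni adjustment caps at one and honours the family size", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 10), 1)
  expect_equal(bonferroni(1.77e-7, m = 260), 4.602e-5, tolerance = 1e-3)
  expect_lt(bonferroni(1.77e-7, m = 260), 0.05)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m must be")
})
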