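# Independent oracles -------------------------------------------------------

# Upper tail by direct pmf summation from the count upward (avoids the
# catastrophic cancellation of 1 - lower_sum for deep tails).
pois_tail_oracle <- function(k, lambda, n_terms = 400) {
  if (k <= 0) return(1)
  j <- k:(k + n_terms)
  sum(exp(-lambda + j * log(lambda) - lgamma(j + 1)))
}
nb_tail_oracle <- function(k, mu, alpha, n_terms = 2000) {
  if (k <= 0) return(1)
  sum(stats::dnbinom(k:(k + n_terms), mu = mu, size = 1 / alpha))
}
# Benjamini-Hochberg step-up by its definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

test_that("exactly proportional data force the slope", {
  set.seed(7)
  dp <- round(runif(100, 2000, 4000))
  ao <- round(0.001 * dp)
  fit <- fit_robust_nb(dp, ao)
  expect_gte(fit$e, 0.0009)
  expect_lte(fit$e, 0.0011)
})

test_that("all-zero variant reads hit the error-rate floor with p = 1 downstream", {
  dp <- rep(2500L, 30)
  fit <- fit_robust_nb(dp, rep(0L, 30))
  expect_equal(fit$e, 1e-6)
  expect_equal(fit$alpha, 0)
  expect_true(fit$converged)
  expect_equal(variant_pvalue(fit, 2500, 0), 1)
})

test_that("too few samples refuses to fit", {
  expect_error(fit_robust_nb(rep(2500, 5), rep(0, 5)), class = "insufficient_cohort")
})

test_that("zero-depth samples are dropped with a note, not treated as negatives", {
  dp <- c(rep(2500L, 25), 0L)
  ao <- c(rpois(25, 1), 0L)
  expect_message(fit <- fit_robust_nb(dp, ao), "zero-depth")
  expect_true(is.na(fit$weights[26]))
})

test_that("robust fit resists high-AF contamination; a plain fit does not", {
  set.seed(101)
  n <- 500
  dp <- round(runif(n + 5, 2000, 4000))
  ao <- rpois(n + 5, 4.2e-4 * dp)
  contam <- n + seq_len(5)
  ao[contam] <- ao[contam] + rbinom(5, dp[contam], 0.05)
  fit <- fit_robust_nb(dp, ao)
  oracle_e <- sum(ao[seq_len(n)]) / sum(dp[seq_len(n)])
  expect_lt(abs(fit$e / oracle_e - 1), 0.15)
  expect_true(all(fit$weights[contam] == 0))
  plain <- plasmakras:::fit_nb_ml(dp, ao, e_floor = 1e-6)
  expect_gt(plain$e, 2 * oracle_e)
})

test_that("error-rate recovery holds under 10% contamination (property)", {
  errs <- vapply(1:10, function(s) {
    set.seed(3000 + s)
    dp <- round(runif(500, 2000, 4000))
    ao <- rpois(500, 4.2e-4 * dp)
    ao[1:50] <- ao[1:50] + rbinom(50, dp[1:50], 0.05)
    abs(fit_robust_nb(dp, ao)$e / 4.2e-4 - 1)
  }, numeric(1))
  expect_true(all(errs < 0.2))
  expect_lt(mean(errs), 0.15)
})

test_that("tail p-values match the Poisson limit to 1e-10 relative error", {
  fit <- structure(list(e = 1e-3, alpha = 0), class = "error_model_fit")
  for (ao in c(0, 1, 2, 5, 10, 20)) {
    p <- variant_pvalue(fit, 1000, ao)
    expect_equal(p, pois_tail_oracle(ao, 1), tolerance = 1e-10)
  }
  # the printed example: e=1e-3, dp=1000, ao=5 -> exact Poisson(1) tail
  expect_equal(variant_pvalue(fit, 1000, 5), pois_tail_oracle(5, 1),
               tolerance = 1e-10)
})

test_that("overdispersion fattens the tail and matches direct NB summation", {
  fit0 <- structure(list(e = 1e-3, alpha = 0), class = "error_model_fit")
  fit5 <- structure(list(e = 1e-3, alpha = 0.5), class = "error_model_fit")
  p0 <- variant_pvalue(fit0, 1000, 5)
  p5 <- variant_pvalue(fit5, 1000, 5)
  expect_gt(p5, p0)
  expect_equal(p5, nb_tail_oracle(5, 1, 0.5), tolerance = 1e-10)
})

test_that("p is monotone in AO and power grows with depth", {
  fit <- structure(list(e = 4.2e-4, alpha = 0.1), class = "error_model_fit")
  p <- variant_pvalue(fit, rep(2500, 21), 0:20)
  expect_true(all(diff(p) <= 0))
  expect_error(variant_pvalue(fit, 100, 200), "exceeds")
  # at fixed AF, deeper sequencing gives smaller tail p for a true variant
  depths <- c(500, 1000, 2500, 5000, 10000)
  pv <- variant_pvalue(fit, depths, round(0.005 * depths))
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("q-values are BH step-up", {
  expect_equal(qvalues(0.05), 0.05)
  expect_equal(qvalues(c(0.001, 0.5)), c(0.002, 0.5))
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(qvalues(numeric(0)), numeric(0))
  expect_error(qvalues(c(0.5, 0)), "0, 1")
  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    expect_equal(qvalues(p), bh_oracle(p))
    expect_true(all(qvalues(p) >= p))
  }
})

test_that("Phred mapping is exact and capped", {
  expect_equal(phred(1e-3), 30)
  expect_equal(phred(1), 0)
  expect_equal(phred(1e-10), 100)
  expect_equal(phred(0), 255)
  expect_equal(phred(1e-40), 255)
  expect_error(phred(-0.1), "0, 1")
  expect_error(phred(1.1), "0, 1")
})

test_that("RVSB evaluates the strand-bias formula with its conventions", {
  expect_equal(rvsb(5, 5, 1000, 1000), 0.5)
  expect_equal(rvsb(10, 0, 1000, 1000), 1.0)
  expect_equal(rvsb(9, 1, 1000, 1000), 0.9)
  expect_error(rvsb(0, 0, 1000, 1000), "no variant reads")
  d <- rvsb(3, 0, 1000, 0)  # all depth on one strand: degenerate, flagged
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "degenerate"))
  set.seed(5)
  for (i in 1:50) {
    dp_p <- sample(0:3000, 1); dp_m <- sample(1:3000, 1)
    ao_p <- sample(0:min(dp_p, 50), 1); ao_m <- sample(0:min(dp_m, 50), 1)
    if (ao_p + ao_m == 0) ao_m <- 1
    v <- as.numeric(rvsb(ao_p, ao_m, dp_p, dp_m))
    expect_gte(v, 0.5); expect_lte(v, 1)
    expect_equal(v, as.numeric(rvsb(ao_m, ao_p, dp_m, dp_p)))  # strand swap
  }
})

test_that("caller finds a lone 50% AF sample among wild types at the QVAL cap", {
  set.seed(9)
  dp <- round(rnorm(96, 2500, 300))
  ao <- rpois(96, 4.2e-4 * dp)
  ao[1] <- ao[1] + rbinom(1, dp[1], 0.5)
  st <- data.frame(contig = "chr12", pos = 25398284L, ref = "C", alt = "A",
                   sample = sprintf("S%02d", 1:96),
                   DP_p = dp %/% 2, DP_m = dp - dp %/% 2,
                   AO_p = ao %/% 2, AO_m = ao - ao %/% 2)
  m <- validate_site_count_matrix(st)
  calls <- call_variants(m)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$sample, "S01")
  expect_equal(calls$QVAL, 255)
})

test_that("caller emits nothing on an all-zero matrix and skips thin sites", {
  m <- simulate_null(30, e = 0, seed = 4)
  expect_equal(nrow(call_variants(m)), 0L)
  thin <- simulate_null(10, seed = 5)
  expect_warning(out <- call_variants(thin), "insufficient cohort")
  expect_equal(nrow(out), 0L)
})

test_that("rvsb_max flags calls instead of dropping them", {
  set.seed(31)
  dp <- round(rnorm(60, 2500, 200))
  ao <- rpois(60, 4.2e-4 * dp)
  ao[1] <- ao[1] + rbinom(1, dp[1], 0.1)
  st <- data.frame(contig = "chr12", pos = 25398284L, ref = "C", alt = "A",
                   sample = sprintf("S%02d", 1:60),
                   DP_p = dp %/% 2, DP_m = dp - dp %/% 2,
                   AO_p = ao, AO_m = 0L)  # fully strand-restricted variants
  m <- validate_site_count_matrix(st)
  flagged <- call_variants(m, rvsb_max = 0.85)
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$filter, "strand_bias")
  expect_gt(flagged$RVSB, 0.85)
})

test_that("null matrices yield near-uniform p-values and <1% site-wise false calls", {
  # both printed per-chip error rates
  for (e in c(4.2e-4, 1.4e-4)) {
    any_call <- logical(60)
    pool_p <- numeric(0)
    for (s in seq_len(60)) {
      m <- simulate_null(150, e = e, alpha = 0.1, seed = 10000 + s)
      dp <- scm_dp(m); ao <- scm_ao(m)
      fit <- fit_robust_nb(dp, ao)
      p <- variant_pvalue(fit, dp, ao)
      pool_p <- c(pool_p, p)
      any_call[s] <- any(phred(qvalues(p)) > 30 & ao > 0)
    }
    expect_lt(mean(any_call), 0.01)
    # coarse rank-uniformity: discrete upper-tail p-values are
    # super-uniform, so P(p <= t) must not exceed t by much at any t
    for (t in c(0.01, 0.05, 0.2, 0.5)) {
      expect_lt(mean(pool_p <= t), t + 0.03)
    }
  }
})
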