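test_that("inclusion boundaries: >=4 ng inclusive, >1000 reads strict", {
  s <- data.frame(id = c("A", "B", "C", "D", "E"),
                  cfdna_yield_ng = c(3.9, 4.0, 10, NA, 10),
                  mean_depth = c(2500, 1001, 1000, 2500, NA))
  r <- apply_inclusion(s)
  expect_equal(r$included$id, "B")
  expect_equal(r$excluded$reason[r$excluded$id == "A"], "low-yield")
  expect_equal(r$excluded$reason[r$excluded$id == "C"], "low-depth")
  expect_equal(r$excluded$reason[r$excluded$id == "D"], "missing-yield")
})

test_that("a 967-subject series with 64 failures keeps 903", {
  set.seed(12)
  s <- data.frame(id = sprintf("V%03d", 1:967),
                  cfdna_yield_ng = runif(967, 5, 40),
                  mean_depth = round(runif(967, 1500, 4500)))
  fail <- sample(967, 64)
  s$cfdna_yield_ng[fail[1:40]] <- runif(40, 0.5, 3.9)
  s$mean_depth[fail[41:64]] <- round(runif(24, 100, 1000))
  r <- apply_inclusion(s)
  expect_equal(nrow(r$included), 903L)
  expect_equal(nrow(r$excluded), 64L)
})

make_call <- function(sample, cdna, af) {
  pc <- parse_cdna(cdna)
  ref <- kras_reference()
  annotate_calls(data.frame(
    sample = sample, contig = "chr12",
    pos = vapply(pc$cdna_pos, cdna_to_genomic, numeric(1), reference = ref),
    ref = unname(plasmakras:::COMPLEMENT[pc$ref]),
    alt = unname(plasmakras:::COMPLEMENT[pc$alt]),
    AF = af, stringsAsFactors = FALSE))
}

test_that("subject tallies aggregate calls once per mode, ignoring the SNP", {
  subjects <- data.frame(id = c("X1", "X2", "X3"), group = "pdac",
                         stringsAsFactors = FALSE)
  calls <- make_call(c("X1", "X1", "X2"),
                     c("c.35G>A", "c.14A>G", "c.24A>G"),
                     c(0.02, 0.004, 0.46))
  st <- tally_subjects(calls, subjects)
  x1 <- st[st$id == "X1", ]
  expect_equal(x1$n_mutations, 2L)            # multiple: hotspot and other
  expect_true(x1$has_hotspot && x1$has_other)
  expect_equal(x1$max_af, 0.02)
  x2 <- st[st$id == "X2", ]
  expect_equal(x2$n_mutations, 0L)            # SNP-only subject: nothing
  expect_false(x2$pos_any_cosmic)
  x3 <- st[st$id == "X3", ]
  expect_false(any(x3$has_hotspot, x3$has_other, x3$pos_missense_only))
  expect_error(tally_subjects(make_call("nope", "c.35G>A", 0.1), subjects),
               "unknown subject")
})

test_that("silent non-SNP calls count for any-codon positivity but not missense", {
  subjects <- data.frame(id = "Y1", group = "healthy", stringsAsFactors = FALSE)
  # c.21G>A is synonymous (V7V) and not on the SNP list
  st <- tally_subjects(make_call("Y1", "c.21G>A", 0.02), subjects)
  expect_true(st$has_silent_only)
  expect_true(st$pos_any_cosmic)
  expect_false(st$pos_missense_only)
})

test_that("pilot fixture margins reproduce the published cross-tabulation", {
  fx <- pilot_fixture()
  expect_equal(as.vector(table(fx$subjects$group)[c("pdac", "healthy",
                                                    "pancreatitis", "benign")]),
               c(40L, 20L, 9L, 27L))
  ca <- ca199_test(fx$subjects)
  expect_equal(sum(is.na(ca)), 2L)  # two benign subjects lack a measurement
  expect_equal(sum(ca[fx$subjects$group == "pdac"]), 36L)
  st <- tally_subjects(fx$calls, fx$subjects)
  g <- fx$subjects$group
  # hotspot / any-codon counts per cell of the published table
  expect_equal(sum(st$pos_hotspot_only[g == "pdac" & ca]), 5L)
  expect_equal(sum(st$pos_any_cosmic[g == "pdac" & ca]), 7L)
  expect_equal(sum(st$pos_hotspot_only[g == "pdac" & !ca]), 2L)
  expect_equal(sum(st$pos_hotspot_only[g == "benign"], na.rm = TRUE), 1L)
  expect_equal(sum(st$pos_any_cosmic[g == "benign"], na.rm = TRUE), 2L)
  expect_equal(sum(st$pos_any_cosmic[g %in% c("healthy", "pancreatitis")]), 0L)
})

test_that("diagnostic performance is permutation-invariant and denominator-aware", {
  fx <- pilot_fixture()
  st <- tally_subjects(fx$calls, fx$subjects)
  perf <- diagnostic_performance(st$pos_hotspot_only, fx$subjects, "all")
  set.seed(2)
  perm <- sample(nrow(fx$subjects))
  st2 <- tally_subjects(fx$calls, fx$subjects[perm, ])
  perf2 <- diagnostic_performance(st2$pos_hotspot_only, fx$subjects[perm, ], "all")
  expect_equal(perf, perf2)
  expect_equal(perf$denominator, c(40L, 56L, 20L))
  ca <- ca199_test(fx$subjects)
  perf_ca <- diagnostic_performance(ca, fx$subjects, "marker_available")
  expect_equal(perf_ca$denominator, c(40L, 54L, 20L))
})

test_that("all-negative flags give zero sensitivity, full specificity", {
  s <- data.frame(id = c("a", "b"), group = c("pdac", "healthy"))
  pf <- diagnostic_performance(c(FALSE, FALSE), s)
  expect_equal(pf$percent, c(0, 100, 100))
  # zero denominator stays NA, never a division error
  s2 <- data.frame(id = "a", group = "pdac")
  pf2 <- diagnostic_performance(TRUE, s2)
  expect_true(is.na(pf2$percent[2]))
})

test_that("CA19-9 cutoff is inclusive at 37 kU/l and rejects negatives", {
  s <- data.frame(ca199 = c(36.9, 37.0, NA))
  expect_equal(ca199_test(s), c(FALSE, TRUE, NA))
  expect_error(ca199_test(data.frame(ca199 = -1)), "negative")
})

test_that("the combined test is an OR with the expected monotonicity", {
  expect_true(combined_test(TRUE, FALSE))
  expect_false(combined_test(FALSE, FALSE))
  expect_true(is.na(combined_test(TRUE, NA)))
  fx <- pilot_fixture()
  st <- tally_subjects(fx$calls, fx$subjects)
  ca <- ca199_test(fx$subjects)
  for (kras in list(st$pos_hotspot_only, st$pos_any_cosmic)) {
    comb <- combined_test(kras, ca)
    p_k <- diagnostic_performance(ifelse(is.na(ca), NA, kras), fx$subjects,
                                  "marker_available")
    p_c <- diagnostic_performance(ca, fx$subjects, "marker_available")
    p_b <- diagnostic_performance(comb, fx$subjects, "marker_available")
    expect_gte(p_b$percent[1], max(p_k$percent[1], p_c$percent[1]))
    expect_lte(p_b$percent[2], min(p_k$percent[2], p_c$percent[2]))
  }
})

test_that("stage trend handles uniform, extreme and empty-stratum inputs", {
  det <- rep(c(TRUE, FALSE), each = 30)
  stg <- rep(c("local", "regional", "systemic"), 20)
  tr <- stage_trend(det, stg)
  expect_lt(tr$statistic, 1e-10)  # identical proportions
  det2 <- rep(c(TRUE, FALSE), each = 50)
  stg2 <- rep(c("local", "regional"), each = 50)
  tr2 <- stage_trend(det2, stg2, stages = c("local", "regional"))
  expect_lt(tr2$p_value, 1e-10)   # all detected vs none
  expect_warning(
    stage_trend(c(TRUE, FALSE, TRUE, FALSE), rep(c("local", "regional"), 2),
                stages = c("local", "regional", "systemic")),
    "zero subjects")
  expect_error(suppressWarnings(stage_trend(c(TRUE, FALSE), c("local", "local"))),
               "two stage")
})

test_that("AF group tests: degenerate identity, calibration and power", {
  mk <- function(af, grp, stage = NA) {
    list(status = data.frame(id = seq_along(af), n_mutations = 1L,
                             max_af = af),
         subjects = data.frame(id = seq_along(af), group = grp, stage = stage))
  }
  idn <- mk(rep(0.01, 10), rep(c("pdac", "healthy"), each = 5))
  r <- af_group_tests(idn$status, idn$subjects)
  expect_equal(r$pairwise$p_value, 1)

  # type-I calibration at alpha = 0.05 over many seeds
  rej <- vapply(1:500, function(s) {
    set.seed(s)
    af <- rlnorm(80, log(0.01), 1)
    d <- mk(af, rep(c("pdac", "healthy"), each = 40))
    af_group_tests(d$status, d$subjects)$pairwise$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)

  # one log10 unit of separation at n = 50 is essentially always detected
  pows <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    af <- c(rlnorm(50, log(0.05), 0.9), rlnorm(50, log(0.005), 0.9))
    d <- mk(af, rep(c("pdac", "healthy"), each = 50))
    af_group_tests(d$status, d$subjects)$pairwise$p_value < 0.001
  }, logical(1))
  expect_gte(mean(pows), 0.95)

  # stage slope among detected cases
  set.seed(4)
  af <- rlnorm(60, log(0.01), 0.5)
  d <- mk(af, rep("pdac", 60), rep(c("local", "regional", "systemic"), 20))
  r2 <- af_group_tests(d$status, d$subjects)
  expect_true(is.numeric(r2$stage_slope$p_value))
  # a group with < 2 detected subjects is skipped, flagged
  d3 <- mk(c(0.01, 0.02, 0.03), c("pdac", "pdac", "healthy"))
  r3 <- af_group_tests(d3$status, d3$subjects)
  expect_true(r3$pairwise$skipped)
  expect_true(is.na(r3$pairwise$p_value))
})

test_that("cfDNA ANOVA: constant response, center offset, missing-stage stratum", {
  s <- data.frame(cfdna_conc = rep(50, 40), group = rep(c("pdac", "healthy"), 20),
                  stage = NA, sex = "F")
  a <- cfdna_anova(s, "group")
  expect_equal(a$F, 0)
  set.seed(5)
  s2 <- data.frame(cfdna_conc = 10^c(rnorm(100, 1.7, 0.3), rnorm(100, 2.2, 0.3)),
                   center = rep(c("A", "B"), each = 100))
  a2 <- cfdna_anova(s2, "center")
  expect_lt(a2$p_value, 1e-6)
  s3 <- data.frame(cfdna_conc = 10^rnorm(60, 2, 0.5),
                   stage = c(rep("local", 20), rep(NA, 40)))
  s3$cfdna_conc[is.na(s3$stage)] <- s3$cfdna_conc[is.na(s3$stage)] * 10
  a3 <- cfdna_anova(s3, "stage")  # missing stage forms its own stratum
  expect_lt(a3$p_value, 1e-4)
  a4 <- cfdna_anova(data.frame(cfdna_conc = 10^rnorm(10), sex = "F"), "sex")
  expect_true(is.na(a4$F))  # single-level factor skipped
})

test_that("AUC comparison: identity, perfect separation, and mutation uplift", {
  set.seed(6)
  s <- data.frame(group = rep(c("pdac", "healthy", "benign"), each = 50),
                  ca199 = c(rlnorm(50, log(150), 1), rlnorm(100, log(12), 1)))
  none <- rep(FALSE, 150)
  r0 <- auc_compare(s, none)
  expect_equal(r0$delta_auc, rep(0, 3))
  expect_equal(r0$p_value, rep(1, 3))
  # perfectly separating marker
  s2 <- data.frame(group = rep(c("pdac", "healthy"), each = 30),
                   ca199 = c(rep(100, 30), rep(1, 30)))
  r2 <- auc_compare(s2, rep(FALSE, 60))
  expect_equal(r2$auc_ca199[r2$contrast == "vs_healthy"], 1)
  # mutation positivity in CA19-9-negative cases lifts the AUC slightly
  kras <- s$group == "pdac" & s$ca199 < 37
  kras[s$group == "pdac"][1:3] <- TRUE
  r3 <- auc_compare(s, kras)
  expect_true(all(r3$delta_auc >= 0))
  expect_true(all(r3$delta_auc < 0.15))
  # degenerate one-class contrast flagged
  s4 <- data.frame(group = rep("pdac", 10), ca199 = rlnorm(10, 4, 1))
  r4 <- auc_compare(s4, rep(FALSE, 10))
  expect_true(all(is.na(r4$auc_ca199)))
})
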