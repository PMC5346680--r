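#!/usr/bin/env Rscript
# Serial-dilution limit of detection.
#
# Simulates the SW480 p.G12V dilution ladder (100% -> 0.01% mutant DNA,
# 4 PCR replicates per point, 6 wild-type samples, depth ~2693), runs the
# robust negative-binomial caller at QVAL > 30 and summarises, per abundance,
# how many replicates are called. A second pass at depth 2500 and error rate
# 4.2e-4 (the pilot-chip conditions) repeats the exercise over 20 ladders to
# give a median detection limit.

suppressPackageStartupMessages(library(plasmakras))
dir.create("results", showWarnings = FALSE)
seed <- 1L

sim <- simulate_dilution(dilution_design(seed = seed))
calls <- suppressWarnings(call_variants(sim$counts))
write_vcf(calls, "results/dilution_calls.vcf",
          samples = unique(sim$counts$sample))
write.table(as.data.frame(calls), "results/dilution_calls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

per_rung <- merge(sim$truth,
                  data.frame(sample = calls$sample, called = TRUE),
                  all.x = TRUE)
per_rung$called[is.na(per_rung$called)] <- FALSE
tab <- aggregate(called ~ af_true, per_rung, sum)
tab$n <- aggregate(called ~ af_true, per_rung, length)$called
names(tab) <- c("abundance", "replicates_called", "replicates")
tab <- tab[order(-tab$abundance), ]
write.table(tab, "results/dilution_by_rung.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Replicates called per dilution point (depth ~2693, e = 4.2e-4):\n")
print(tab, row.names = FALSE)

fit <- attr(calls, "fits")[[1]]
cat(sprintf("\nFitted background error rate at the G12V position: e = %.3g (overdispersion %.3g)\n",
            fit$e, fit$alpha))

lowest <- vapply(1:20, function(k) {
  s <- simulate_dilution(dilution_design(depth_mean = 2500, depth_sd = 650,
                                         error_rate = 4.2e-4, seed = 1000 + k))
  cl <- suppressWarnings(call_variants(s$counts))
  called <- s$truth$sample %in% cl$sample
  pr <- tapply(called, s$truth$af_true, sum)
  r <- as.numeric(names(pr))
  ok <- r > 0 & pr >= 3
  if (any(ok)) min(r[ok]) else Inf
}, numeric(1))
cat(sprintf("\nMedian detection limit over 20 ladders at depth 2500: %g%% AF\n",
            100 * median(lowest)))
cat(sprintf("Ladders resolving 0.2%%: %d/20; resolving 0.5%% or better: %d/20\n",
            sum(lowest <= 0.002), sum(lowest <= 0.005)))
writeLines(sprintf("median_detection_limit_pct\t%g", 100 * median(lowest)),
           "results/dilution_limit.tsv")
cat("\nNote: at depth 2500 a 0.2% AF replicate carries ~6 expected variant\n")
cat("reads against ~1 background read; the QVAL>30 boundary sits at 7-8\n")
cat("reads, so 0.2% detection is intrinsically borderline at this depth.\n")
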