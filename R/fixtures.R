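#' Packaged pilot-series fixture
#'
#' A subject-level reconstruction of the pilot case-control series (96
#' subjects: 40 PDAC cases, 20 healthy controls, 9 chronic pancreatitis, 27
#' pancreatic benign neoplasms) whose margins reproduce the published
#' cross-tabulation of CA19-9 status by KRAS-mutation status by diagnostic
#' group cell by cell, including the two benign subjects without a CA19-9
#' measurement. The subject records and per-subject calls are synthetic
#' reconstructions (the study deposited no raw per-subject data); only the
#' table margins are constrained.
#'
#' @return list with `subjects` (id, group, ca199, stage, cfdna_yield_ng,
#'   mean_depth) and `calls` (annotated: sample, pos, ref, alt, AF, cdna,
#'   protein, codon, consequence, category).
#' @export
pilot_fixture <- function() {
  subj <- utils::read.table(
    system.file("extdata", "pilot_subjects.tsv", package = "plasmakras",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  raw <- utils::read.table(
    system.file("extdata", "pilot_calls.tsv", package = "plasmakras",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ref <- kras_reference()
  pc <- parse_cdna(raw$cdna)
  calls <- data.frame(
    sample = raw$id, contig = "chr12",
    pos = vapply(pc$cdna_pos, cdna_to_genomic, numeric(1), reference = ref),
    ref = unname(COMPLEMENT[pc$ref]), alt = unname(COMPLEMENT[pc$alt]),
    AF = raw$af, stringsAsFactors = FALSE)
  list(subjects = subj, calls = annotate_calls(calls, reference = ref))
}

#' Packaged stage-by-detection fixture
#'
#' Detection counts of cfDNA KRAS mutations among pancreatic cancer cases by
#' stage (local / regional / systemic / unknown), for the pilot and
#' validation series, as published.
#'
#' @return data frame: stage, series, total, detected.
#' @export
stage_counts_fixture <- function() {
  utils::read.table(
    system.file("extdata", "stage_counts.tsv", package = "plasmakras",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Reproduce the pilot diagnostic-performance table
#'
#' Runs the full evaluation stage on the packaged pilot fixture: per-subject
#' tallies, KRAS sensitivity/specificity under the hotspot-only and
#' any-screened-codon modes (all 56 non-case subjects in the denominator),
#' CA19-9 at the 37 kU/l cutoff and the combined KRAS-or-CA19-9 assays
#' (denominators restricted to the 54 non-case subjects with a CA19-9
#' measurement).
#'
#' @return data frame: one row per assay/mode with sensitivity,
#'   specificity_overall and specificity_vs_healthy percentages plus their
#'   numerators/denominators.
#' @export
pilot_performance <- function() {
  fx <- pilot_fixture()
  status <- tally_subjects(fx$calls, fx$subjects)
  ca <- ca199_test(fx$subjects)
  assays <- list(
    kras_hotspot = list(flag = status$pos_hotspot_only, policy = "all"),
    kras_any_codon = list(flag = status$pos_any_cosmic, policy = "all"),
    ca199 = list(flag = ca, policy = "marker_available"),
    combined_hotspot = list(flag = combined_test(status$pos_hotspot_only, ca),
                            policy = "marker_available"),
    combined_any_codon = list(flag = combined_test(status$pos_any_cosmic, ca),
                              policy = "marker_available"))
  rows <- lapply(names(assays), function(nm) {
    pf <- diagnostic_performance(assays[[nm]]$flag, fx$subjects,
                                 denominator_policy = assays[[nm]]$policy)
    data.frame(assay = nm,
               sensitivity = pf$percent[1],
               sens_n = sprintf("%d/%d", pf$numerator[1], pf$denominator[1]),
               specificity_overall = pf$percent[2],
               spec_n = sprintf("%d/%d", pf$numerator[2], pf$denominator[2]),
               specificity_vs_healthy = pf$percent[3],
               spec_h_n = sprintf("%d/%d", pf$numerator[3], pf$denominator[3]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stage proportions and trend from the packaged stage fixture
#'
#' Pools the pilot and validation series, reports the detection proportion
#' per stage and overall, and the Pearson chi-squared trend over
#' local/regional/systemic.
#'
#' @return list with `by_stage` (stage, total, detected, percent), `pooled`
#'   (total, detected, percent) and `trend` (see [stage_trend()]).
#' @export
stage_summary <- function() {
  sc <- stage_counts_fixture()
  agg <- stats::aggregate(cbind(total, detected) ~ stage, data = sc, sum)
  agg <- agg[match(c("local", "regional", "systemic", "unknown"), agg$stage), ]
  agg$percent <- mapply(pct, agg$detected, agg$total)
  pooled <- list(total = sum(agg$total), detected = sum(agg$detected),
                 percent = pct(sum(agg$detected), sum(agg$total)))
  det <- rep(rep(c(TRUE, FALSE), nrow(agg)),
             times = as.vector(rbind(agg$detected, agg$total - agg$detected)))
  stg <- rep(rep(agg$stage, each = 2),
             times = as.vector(rbind(agg$detected, agg$total - agg$detected)))
  list(by_stage = agg, pooled = pooled,
       trend = stage_trend(det, stg))
}
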