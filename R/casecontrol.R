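# Percentages in the reports are rounded half-up to one decimal, matching
# the convention of the published tables (round() would round half to even).
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

pct <- function(num, den, digits = 1) {
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den, digits))
}

#' Apply the study inclusion criteria
#'
#' A sample enters the analysis when its total cfDNA yield is at least 4 ng
#' (inclusive) and its mean read depth is above 1000 (strict). Exclusions are
#' logged with a reason; missing yield excludes with reason "missing-yield".
#'
#' @param subjects data frame with `cfdna_yield_ng` and `mean_depth`.
#' @param min_yield_ng,min_depth thresholds.
#' @return list with `included` (subset of `subjects`) and `excluded`
#'   (data frame id/reason).
#' @export
apply_inclusion <- function(subjects, min_yield_ng = 4, min_depth = 1000) {
  reason <- rep(NA_character_, nrow(subjects))
  reason[!is.na(subjects$mean_depth) & subjects$mean_depth <= min_depth] <- "low-depth"
  reason[is.na(subjects$mean_depth)] <- "missing-depth"
  reason[!is.na(subjects$cfdna_yield_ng) & subjects$cfdna_yield_ng < min_yield_ng] <- "low-yield"
  reason[is.na(subjects$cfdna_yield_ng)] <- "missing-yield"
  keep <- is.na(reason)
  list(included = subjects[keep, , drop = FALSE],
       excluded = data.frame(id = subjects$id[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Per-subject mutation tallies
#'
#' Aggregates annotated calls to one row per subject: number of retained
#' mutations (SNP-excluded calls contribute nothing), hotspot/other/silent
#' flags, the maximum allelic fraction across the subject's calls, and
#' positivity under each reporting mode: `hotspot_only` (missense at codons
#' 12/13/61), `any_cosmic` (any non-SNP, non-silent reportable change — the
#' "any screened codon" convention), `missense_only` (any missense).
#'
#' @param calls annotated calls (see [annotate_calls()]) with a `sample`
#'   column naming the subject and an `AF` column.
#' @param subjects subject table with `id`; every call must reference a known
#'   subject.
#' @return data frame, one row per subject: `id`, `n_mutations`,
#'   `has_hotspot`, `has_other`, `has_silent_only`, `max_af`,
#'   `pos_hotspot_only`, `pos_any_cosmic`, `pos_missense_only`.
#' @export
tally_subjects <- function(calls, subjects) {
  unknown <- setdiff(unique(calls$sample), subjects$id)
  if (length(unknown) > 0) {
    stop("calls reference unknown subject(s): ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(id = subjects$id, n_mutations = 0L, has_hotspot = FALSE,
                    has_other = FALSE, has_silent_only = FALSE, max_af = 0,
                    stringsAsFactors = FALSE)
  keep <- calls[calls$category != "snp_excluded", , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    cc <- keep[keep$sample == out$id[i], , drop = FALSE]
    if (nrow(cc) == 0) next
    reportable <- cc$category %in% c("hotspot_pdac", "other_cosmic_codon", "silent")
    cc <- cc[reportable, , drop = FALSE]
    if (nrow(cc) == 0) next
    out$n_mutations[i] <- nrow(cc)
    out$has_hotspot[i] <- any(cc$category == "hotspot_pdac")
    out$has_other[i] <- any(cc$category == "other_cosmic_codon")
    out$has_silent_only[i] <- all(cc$category == "silent")
    out$max_af[i] <- max(cc$AF)
  }
  out$pos_hotspot_only <- out$has_hotspot
  out$pos_any_cosmic <- out$n_mutations > 0L
  out$pos_missense_only <- out$has_hotspot | out$has_other
  out
}

#' Diagnostic performance with explicit denominators
#'
#' Sensitivity is positive cases over all cases. Overall specificity is
#' negative non-cases over non-cases, where the denominator is controlled by
#' `denominator_policy`: `"all"` uses every non-case subject (the KRAS-assay
#' convention), `"marker_available"` restricts to subjects with a CA19-9
#' measurement (the convention forced by the published CA19-9 and combined
#' rows, where unmeasured subjects cannot be scored). Specificity against
#' healthy controls restricts to the healthy group. Every proportion carries
#' its numerator and denominator.
#'
#' @param positive logical vector, one entry per subject (NA = untestable,
#'   e.g. missing CA19-9; untestable non-cases leave the denominator under
#'   either policy).
#' @param subjects subject table with `group` (cases are `"pdac"`).
#' @param denominator_policy see above.
#' @param case_groups groups counted as cases.
#' @return data frame of class `performance_table` with rows sensitivity /
#'   specificity_overall / specificity_vs_healthy and columns measure,
#'   numerator, denominator, percent.
#' @export
diagnostic_performance <- function(positive, subjects,
                                   denominator_policy = c("all", "marker_available"),
                                   case_groups = "pdac") {
  denominator_policy <- match.arg(denominator_policy)
  stopifnot(length(positive) == nrow(subjects))
  is_case <- subjects$group %in% case_groups
  testable <- !is.na(positive)
  sens_num <- sum(positive[is_case], na.rm = TRUE)
  sens_den <- sum(is_case)
  noncase <- !is_case & (denominator_policy == "all" | testable)
  spec_num <- sum(!positive[noncase], na.rm = TRUE)
  spec_den <- sum(noncase)
  healthy <- subjects$group == "healthy" & (denominator_policy == "all" | testable)
  h_num <- sum(!positive[healthy], na.rm = TRUE)
  h_den <- sum(healthy)
  out <- data.frame(
    measure = c("sensitivity", "specificity_overall", "specificity_vs_healthy"),
    numerator = c(sens_num, spec_num, h_num),
    denominator = c(sens_den, spec_den, h_den),
    percent = c(pct(sens_num, sens_den), pct(spec_num, spec_den),
                pct(h_num, h_den)),
    stringsAsFactors = FALSE)
  class(out) <- c("performance_table", "data.frame")
  out
}

#' CA19-9 positivity at the clinical cutoff
#'
#' Positive at level >= 37 kU/l; missing levels return NA so the subject
#' drops out of CA19-9-based denominators.
#'
#' @param subjects table with `ca199` (kU/l).
#' @param cutoff clinical positivity cutoff.
#' @export
ca199_test <- function(subjects, cutoff = 37) {
  lvl <- subjects$ca199
  if (any(!is.na(lvl) & lvl < 0)) stop("negative CA19-9 level")
  ifelse(is.na(lvl), NA, lvl >= cutoff)
}

#' Combined KRAS-or-CA19-9 test
#'
#' Positive if a KRAS mutation was found (under the chosen reporting mode) or
#' the CA19-9 level is positive; NA CA19-9 keeps the subject untestable for
#' the combined assay.
#'
#' @param kras_positive,ca199_positive logical vectors.
#' @export
combined_test <- function(kras_positive, ca199_positive) {
  ifelse(is.na(ca199_positive), NA, kras_positive | ca199_positive)
}

#' Detection-by-stage trend
#'
#' Pearson chi-squared (no continuity correction) on the detected/undetected
#' by stage contingency table; unknown-stage subjects are excluded, and
#' stages with zero subjects are dropped with a warning.
#'
#' @param detected logical per subject.
#' @param stage factor/character per subject (`local`, `regional`,
#'   `systemic`, `unknown`/NA).
#' @param stages stages entering the trend, in order.
#' @return list with `table`, `statistic`, `df`, `p_value`, `proportions`.
#' @export
stage_trend <- function(detected, stage, stages = c("local", "regional", "systemic")) {
  keep <- stage %in% stages
  st <- factor(stage[keep], levels = stages)
  det <- detected[keep]
  tab <- table(det = factor(det, levels = c(TRUE, FALSE)), stage = st)
  empty <- colSums(tab) == 0
  if (any(empty)) {
    warning("dropping stage group(s) with zero subjects: ",
            paste(colnames(tab)[empty], collapse = ", "))
    tab <- tab[, !empty, drop = FALSE]
  }
  if (ncol(tab) < 2) stop("need at least two stage groups with subjects")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value,
       proportions = pct(tab[1, ], colSums(tab)))
}

#' Allelic-fraction group comparisons
#'
#' Two-sample Welch t-tests on log10 of the per-subject maximum allelic
#' fraction between detected subjects of different groups, plus a linear
#' regression of log10(AF) on ordered stage (slope t-test) among detected
#' cases.
#'
#' @param status a [tally_subjects()] table (detected = `n_mutations > 0`).
#' @param subjects subject table with `group` and `stage`.
#' @param min_n minimum detected subjects per group for a test.
#' @return list with `pairwise` (data frame: group1, group2, n1, n2, p_value)
#'   and `stage_slope` (list: estimate, p_value, n) or NULL if unavailable.
#' @export
af_group_tests <- function(status, subjects, min_n = 2) {
  det <- status$n_mutations > 0 & status$max_af > 0
  lg <- log10(status$max_af[det])
  grp <- subjects$group[det]
  stage <- subjects$stage[det]
  groups <- unique(grp)
  pairs <- if (length(groups) >= 2) utils::combn(groups, 2, simplify = FALSE) else list()
  empty_pw <- data.frame(group1 = character(0), group2 = character(0),
                         n1 = integer(0), n2 = integer(0),
                         p_value = numeric(0), skipped = logical(0))
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    x <- lg[grp == pr[1]]; y <- lg[grp == pr[2]]
    ok <- length(x) >= min_n && length(y) >= min_n
    p <- NA_real_
    if (ok) {
      if (stats::var(x) + stats::var(y) == 0) {
        # degenerate: constant data; equal means carry no evidence at all
        p <- if (mean(x) == mean(y)) 1 else 0
      } else {
        p <- stats::t.test(x, y)$p.value
      }
    }
    data.frame(group1 = pr[1], group2 = pr[2], n1 = length(x), n2 = length(y),
               p_value = p, skipped = !ok, stringsAsFactors = FALSE)
  }))
  if (is.null(pw)) pw <- empty_pw
  slope <- NULL
  sc <- grp == "pdac" & stage %in% c("local", "regional", "systemic")
  if (sum(sc) >= 3) {
    ord <- as.integer(factor(stage[sc], levels = c("local", "regional", "systemic")))
    fit <- summary(stats::lm(lg[sc] ~ ord))
    slope <- list(estimate = fit$coefficients["ord", "Estimate"],
                  p_value = fit$coefficients["ord", "Pr(>|t|)"], n = sum(sc))
  }
  list(pairwise = pw, stage_slope = slope)
}

#' cfDNA concentration ANOVA
#'
#' One-way F-tests of log10 cfDNA concentration (ng/mL) against each
#' covariate; for `stage`, missing values form their own stratum (the study
#' contrasts missing against reported stages). Single-level factors are
#' skipped.
#'
#' @param subjects table with `cfdna_conc` and the covariates.
#' @param covariates column names to test.
#' @return data frame: covariate, df, F, p_value (NA where skipped).
#' @export
cfdna_anova <- function(subjects, covariates = c("group", "stage", "sex")) {
  stopifnot(all(subjects$cfdna_conc > 0, na.rm = TRUE))
  y <- log10(subjects$cfdna_conc)
  rows <- lapply(covariates, function(cv) {
    x <- subjects[[cv]]
    if (cv == "stage") {
      x <- ifelse(is.na(x), "missing", x)
    }
    x <- factor(x)
    if (nlevels(droplevels(x[!is.na(x)])) < 2) {
      return(data.frame(covariate = cv, df = NA, F = NA, p_value = NA))
    }
    a <- suppressWarnings(stats::anova(stats::aov(y ~ x)))
    Fv <- a$`F value`[1]; pv <- a$`Pr(>F)`[1]
    if (stats::var(y) == 0) { Fv <- 0; pv <- 1 }  # constant response
    data.frame(covariate = cv, df = a$Df[1], F = Fv,
               p_value = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired AUC comparison: combined assay versus CA19-9 alone
#'
#' The combined score is the CA19-9 level with KRAS-mutation-positive
#' subjects promoted above the maximum observed level (a binary override —
#' the mutation call has no natural continuous scale). AUCs are rank
#' statistics; the paired difference is tested by DeLong's method. Three
#' case/non-case contrasts are reported: cases vs healthy controls, cases vs
#' all other conditions, cases vs benign conditions (non-healthy non-cases).
#'
#' @param subjects table with `group` and `ca199`.
#' @param kras_positive logical per subject.
#' @param case_groups,benign_groups group labels.
#' @return data frame: contrast, n_case, n_control, auc_ca199, auc_combined,
#'   delta_auc, p_value.
#' @export
auc_compare <- function(subjects, kras_positive, case_groups = "pdac",
                        benign_groups = c("benign", "pancreatitis")) {
  ok <- !is.na(subjects$ca199)
  s <- subjects[ok, , drop = FALSE]
  kp <- kras_positive[ok]
  score1 <- s$ca199
  score2 <- ifelse(kp, max(s$ca199) + 1, s$ca199)
  is_case <- s$group %in% case_groups
  contrasts <- list(
    vs_healthy = s$group == "healthy",
    vs_all_others = !is_case,
    vs_benign = s$group %in% benign_groups)
  rows <- lapply(names(contrasts), function(nm) {
    ctrl <- contrasts[[nm]]
    use <- is_case | ctrl
    lab <- is_case[use]
    if (length(unique(lab)) < 2) {
      return(data.frame(contrast = nm, n_case = sum(lab), n_control = sum(!lab),
                        auc_ca199 = NA, auc_combined = NA, delta_auc = NA,
                        p_value = NA))
    }
    r1 <- pROC::roc(lab, score1[use], quiet = TRUE, direction = "<",
                    levels = c(FALSE, TRUE))
    r2 <- pROC::roc(lab, score2[use], quiet = TRUE, direction = "<",
                    levels = c(FALSE, TRUE))
    if (identical(score1[use], score2[use])) {
      pv <- 1  # identical scores: no difference to test
    } else {
      pv <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)$p.value
    }
    data.frame(contrast = nm, n_case = sum(lab), n_control = sum(!lab),
               auc_ca199 = as.numeric(pROC::auc(r1)),
               auc_combined = as.numeric(pROC::auc(r2)),
               delta_auc = as.numeric(pROC::auc(r2)) - as.numeric(pROC::auc(r1)),
               p_value = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
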