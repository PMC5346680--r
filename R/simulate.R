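# Per-sample seeds derived from one master seed so that any subject's counts
# are reproducible independently of cohort size (stable subsets on resizing).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

# Depth model: negative binomial around the stated mean (keeps counts
# integral); size from mean/sd. Floor guards against zero/absurd depths.
rdepth <- function(n, mean, sd, floor = 100L) {
  if (sd <= sqrt(mean)) return(pmax(floor, stats::rpois(n, mean)))
  size <- mean^2 / (sd^2 - mean)
  pmax(floor, stats::rnbinom(n, mu = mean, size = size))
}

# Background error reads: NB2(e*dp, alpha), Poisson when alpha = 0.
rerrors <- function(dp, e, alpha) {
  if (alpha > 0) stats::rnbinom(length(dp), mu = e * dp, size = 1 / alpha)
  else stats::rpois(length(dp), e * dp)
}

# Split total DP and AO across strands: depth binomially at the strand
# probability, variant reads hypergeometrically given the depth split (so
# AO_p <= DP_p always holds and variant reads follow depth unless a
# strand-bias scenario is requested via p_strand_variant).
split_strands <- function(dp, ao, p_strand = 0.5, p_strand_variant = NULL) {
  dp_p <- stats::rbinom(length(dp), dp, p_strand)
  if (is.null(p_strand_variant)) {
    ao_p <- suppressWarnings(stats::rhyper(length(dp), m = dp_p, n = dp - dp_p, k = ao))
  } else {
    ao_p <- pmin(stats::rbinom(length(dp), ao, p_strand_variant), dp_p)
  }
  # guard the degenerate all-one-strand case
  ao_m <- ao - ao_p
  fix <- ao_m > (dp - dp_p)
  ao_p[fix] <- ao[fix] - (dp[fix] - dp_p[fix])
  data.frame(DP_p = dp_p, DP_m = dp - dp_p, AO_p = ao_p, AO_m = ao - ao_p)
}

#' Serial-dilution design
#'
#' The SW480 limit-of-detection experiment: genomic DNA carrying a
#' hemizygous KRAS p.G12V (c.35G>T) serially diluted into wild-type DNA at
#' abundances 100% down to 0.01%, four independent PCR replicates per
#' dilution point plus six wild-type samples, sequenced to a mean depth of
#' about 2693 reads (observed replicate depths spanned roughly 1000-4200,
#' captured here as an SD of 650).
#'
#' @param abundances mutant DNA fractions, strictly decreasing in (0, 1].
#' @param replicates PCR replicates per abundance.
#' @param wildtype_n wild-type samples.
#' @param depth_mean,depth_sd read-depth distribution.
#' @param error_rate per-site background error rate e.
#' @param overdispersion NB2 alpha of the background errors.
#' @param seed master seed.
#' @export
dilution_design <- function(abundances = c(1, 0.5, 0.2, 0.1, 0.05, 0.02, 0.01,
                                           0.005, 0.002, 0.001, 5e-4, 2e-4, 1e-4),
                            replicates = 4, wildtype_n = 6,
                            depth_mean = 2693, depth_sd = 650,
                            error_rate = 4.2e-4, overdispersion = 0.1,
                            seed = 1) {
  stopifnot(all(diff(abundances) < 0), all(abundances > 0), all(abundances <= 1))
  structure(list(abundances = abundances, replicates = replicates,
                 wildtype_n = wildtype_n, depth_mean = depth_mean,
                 depth_sd = depth_sd, error_rate = error_rate,
                 overdispersion = overdispersion, seed = seed),
            class = "dilution_design")
}

#' Simulate the serial-dilution ladder
#'
#' Per sample, depth is drawn around `depth_mean`; variant reads are the sum
#' of binomial sampling at the true allelic fraction and NB2 background
#' errors at the design error rate, truncated at the depth (error reads and
#' mutant reads are indistinguishable in counts). The true AF of each rung
#' equals the mutant DNA abundance (the SW480 mutation is hemizygous).
#'
#' @param design a [dilution_design()].
#' @param site target substitution as a list with `contig`, `pos`, `ref`,
#'   `alt`; defaults to the genomic coordinates of KRAS c.35G>T (p.G12V).
#' @return list with `counts` (a [site_count_matrix]) and `truth` (data
#'   frame: sample, af_true).
#' @export
simulate_dilution <- function(design = dilution_design(),
                              site = list(contig = "chr12", pos = 25398284L,
                                          ref = "C", alt = "A")) {
  af <- c(rep(design$abundances, each = design$replicates),
          rep(0, design$wildtype_n))
  n <- length(af)
  sample_ids <- sprintf("D%02d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(design$seed, i))
    dp <- rdepth(1, design$depth_mean, design$depth_sd)
    mut <- stats::rbinom(1, dp, af[i])
    err <- rerrors(dp, design$error_rate, design$overdispersion)
    ao <- min(dp, mut + err)
    st <- split_strands(dp, ao)
    rows[[i]] <- data.frame(contig = site$contig, pos = site$pos,
                            ref = site$ref, alt = site$alt,
                            sample = sample_ids[i], st,
                            stringsAsFactors = FALSE)
  }
  counts <- validate_site_count_matrix(do.call(rbind, rows))
  list(counts = counts,
       truth = data.frame(sample = sample_ids, af_true = af,
                          stringsAsFactors = FALSE))
}

#' Simulate a background-only count matrix
#'
#' Wild-type samples: variant reads are pure NB2 sequencing noise at rate `e`
#' with dispersion `alpha`. Used for null calibration of the caller.
#'
#' @param n_samples samples.
#' @param depth_mean,depth_sd depth distribution.
#' @param e error rate; 0 gives all-zero AO.
#' @param alpha NB2 overdispersion.
#' @param seed master seed.
#' @param site target substitution (as in [simulate_dilution()]).
#' @export
simulate_null <- function(n_samples, depth_mean = 2500, depth_sd = 650,
                          e = 4.2e-4, alpha = 0.1, seed = 1,
                          site = list(contig = "chr12", pos = 25398284L,
                                      ref = "C", alt = "A")) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  dp <- rdepth(n_samples, depth_mean, depth_sd)
  ao <- pmin(dp, rerrors(dp, e, alpha))
  st <- split_strands(dp, ao)
  validate_site_count_matrix(data.frame(
    contig = site$contig, pos = site$pos, ref = site$ref, alt = site$alt,
    sample = sprintf("N%04d", seq_len(n_samples)), st,
    stringsAsFactors = FALSE))
}

# The assay's substitution panel: the recurrent hotspot changes plus the
# non-hotspot changes observed in plasma, as HGVS c. strings with draw
# weights for carriers (hotspot mix follows the tumour spectrum: G12D and
# G12V dominate, then G12R/G12C, then codon 61, then codon 13).
kras_panel <- function() {
  data.frame(
    cdna = c("c.35G>A", "c.35G>T", "c.34G>C", "c.34G>T", "c.38G>A", "c.37G>C",
             "c.183A>C", "c.182A>G", "c.182A>T",
             "c.14A>G", "c.28G>A", "c.31G>C", "c.176C>G", "c.179G>A",
             "c.186G>T", "c.190T>G", "c.199A>T", "c.209A>C", "c.214A>G"),
    protein = c("p.G12D", "p.G12V", "p.G12R", "p.G12C", "p.G13D", "p.G13R",
                "p.Q61H", "p.Q61R", "p.Q61L",
                "p.K5R", "p.G10R", "p.A11P", "p.A59G", "p.G60D",
                "p.E62D", "p.Y64D", "p.M67L", "p.Q70P", "p.M72V"),
    hotspot = c(rep(TRUE, 9), rep(FALSE, 10)),
    weight = c(0.32, 0.28, 0.10, 0.09, 0.02, 0.02, 0.07, 0.06, 0.04,
               rep(0.1, 10)),
    stringsAsFactors = FALSE)
}

#' Case-control cohort design
#'
#' Defaults mirror the full study: 437 pancreatic cancer cases, 141 chronic
#' pancreatitis subjects and 394 healthy controls; stage mix and
#' stage-specific detection prevalences from the pooled stage table (local
#' 10.3%, regional 17.5%, systemic 33.3%, unknown 15.0%); control carrier
#' prevalences 3.6% (healthy) and 4.3% (pancreatitis); carrier allelic
#' fractions drawn from the reported per-group AF-bin occupancies
#' (bins <0.2, 0.2-1, 1.01-10, 10.01-50, 50.01-79, in %AF, uniform within
#' bin, lower edge 0.08% — the lowest AF the assay detected); depth around
#' 2888 (SD 1259); CA19-9 lognormal components giving ~90% positivity at the
#' 37 kU/l cutoff in cases and ~15% in healthy controls; log10 cfDNA
#' concentration (ng/mL) normal per group as reported.
#'
#' @param n named vector: cases, pancreatitis, healthy.
#' @param stage_probs case stage distribution.
#' @param prevalence named list: `case_by_stage`, `pancreatitis`, `healthy`.
#' @param af_bins bin edges as AF proportions.
#' @param af_bin_probs per-group bin occupancy (rows = groups).
#' @param hotspot_prob per-group probability that a carrier's substitution
#'   is at a hotspot codon.
#' @param depth_mean,depth_sd sequencing depth distribution.
#' @param error_rate,overdispersion background error model (per site).
#' @param ca199_meanlog,ca199_sdlog lognormal CA19-9 components (case,
#'   control).
#' @param conc_mean,conc_sd per-group mean/sd of log10 cfDNA concentration.
#' @param plasma_ml plasma volume used to convert concentration to total
#'   yield.
#' @param seed master seed.
#' @export
cohort_design <- function(n = c(cases = 437, pancreatitis = 141, healthy = 394),
                          stage_probs = c(local = 39, regional = 143,
                                          systemic = 135, unknown = 120) / 437,
                          prevalence = list(
                            case_by_stage = c(local = 0.103, regional = 0.175,
                                              systemic = 0.333, unknown = 0.150),
                            pancreatitis = 0.043, healthy = 0.036),
                          af_bins = c(0.0008, 0.002, 0.01, 0.10, 0.50, 0.79),
                          af_bin_probs = rbind(
                            cases = c(4, 35, 40, 11, 3) / 93,
                            pancreatitis = c(1, 4, 0, 1, 0) / 6,
                            healthy = c(4, 7, 2, 1, 0) / 14),
                          hotspot_prob = c(cases = 82 / 92,
                                           pancreatitis = 4 / 6,
                                           healthy = 9 / 14),
                          depth_mean = 2888, depth_sd = 1259,
                          error_rate = 1.4e-4, overdispersion = 0.1,
                          ca199_meanlog = c(case = log(150), control = log(12)),
                          ca199_sdlog = c(case = 1.2, control = 1.0),
                          conc_mean = c(cases = 2.0, pancreatitis = 1.8,
                                        healthy = 1.7),
                          conc_sd = c(cases = 0.7, pancreatitis = 0.7,
                                      healthy = 0.6),
                          plasma_ml = 0.9, seed = 1) {
  stopifnot(all(abs(rowSums(af_bin_probs) - 1) < 1e-8))
  structure(as.list(environment()), class = "cohort_design")
}

#' Simulate a case-control cohort
#'
#' Each subject is assigned carrier status by group (and, for cases, stage)
#' prevalence; carriers draw one panel substitution (hotspot vs other per the
#' group's location mix) and an allelic fraction from the group's bin
#' distribution; counts at every panel site are background noise plus, at
#' the carried site, binomial mutant reads. CA19-9 and cfDNA yield are drawn
#' per group so the combined marker analyses are exercisable.
#'
#' @param design a [cohort_design()].
#' @return list with `counts` (a [site_count_matrix] over all panel sites),
#'   `subjects` (one row per subject: id, group, stage, ca199, cfdna_conc,
#'   cfdna_yield_ng, mean_depth, sex, age), and `truth` (per-subject carrier
#'   status, substitution and true AF).
#' @export
simulate_cohort <- function(design = cohort_design()) {
  panel <- kras_panel()
  ref <- kras_reference()
  pc <- parse_cdna(panel$cdna)
  panel$pos <- vapply(pc$cdna_pos, cdna_to_genomic, numeric(1), reference = ref)
  panel$gref <- unname(COMPLEMENT[pc$ref])
  panel$galt <- unname(COMPLEMENT[pc$alt])

  groups <- rep(names(design$n), design$n)
  n_tot <- length(groups)
  ids <- sprintf("S%04d", seq_len(n_tot))
  subjects <- vector("list", n_tot)
  truth <- vector("list", n_tot)
  count_rows <- vector("list", n_tot)

  for (i in seq_len(n_tot)) {
    set.seed(derive_seed(design$seed, i))
    grp <- groups[i]
    stage <- if (grp == "cases") {
      sample(names(design$stage_probs), 1, prob = design$stage_probs)
    } else NA_character_
    prev <- if (grp == "cases") design$prevalence$case_by_stage[[stage]]
            else design$prevalence[[grp]]
    carrier <- stats::runif(1) < prev
    sub_cdna <- NA_character_
    af <- 0
    if (carrier) {
      hot <- stats::runif(1) < design$hotspot_prob[[grp]]
      pool <- panel[panel$hotspot == hot, ]
      j <- sample(nrow(pool), 1, prob = pool$weight)
      sub_cdna <- pool$cdna[j]
      bp <- design$af_bin_probs[grp, ]
      b <- sample(length(bp), 1, prob = bp)
      af <- stats::runif(1, design$af_bins[b], design$af_bins[b + 1])
    }
    dp <- rdepth(nrow(panel), design$depth_mean, design$depth_sd)
    ao <- pmin(dp, rerrors(dp, design$error_rate, design$overdispersion) +
                 ifelse(panel$cdna == sub_cdna & !is.na(sub_cdna),
                        stats::rbinom(nrow(panel), dp, af), 0L))
    st <- split_strands(dp, ao)
    count_rows[[i]] <- data.frame(contig = "chr12", pos = panel$pos,
                                  ref = panel$gref, alt = panel$galt,
                                  sample = ids[i], st, stringsAsFactors = FALSE)
    is_case <- grp == "cases"
    ca <- stats::rlnorm(1,
      meanlog = design$ca199_meanlog[[if (is_case) "case" else "control"]],
      sdlog = design$ca199_sdlog[[if (is_case) "case" else "control"]])
    conc <- 10^stats::rnorm(1, design$conc_mean[[grp]], design$conc_sd[[grp]])
    subjects[[i]] <- data.frame(
      id = ids[i], group = if (is_case) "pdac" else grp, stage = stage,
      ca199 = ca, cfdna_conc = conc,
      cfdna_yield_ng = conc * design$plasma_ml,
      mean_depth = mean(dp),
      sex = sample(c("M", "F"), 1), age = round(stats::rnorm(1, 62, 11)),
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(id = ids[i], group = grp, stage = stage,
                             carrier = carrier, cdna = sub_cdna, af_true = af,
                             stringsAsFactors = FALSE)
  }
  list(counts = validate_site_count_matrix(do.call(rbind, count_rows)),
       subjects = do.call(rbind, subjects),
       truth = do.call(rbind, truth))
}
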