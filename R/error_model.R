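#' Fit the per-site sequencing-error model
#'
#' For one (site, alternate base), models the variant-read count of sample
#' \eqn{i} as negative binomial with mean \eqn{e \cdot DP_i} — a regression
#' of variant reads on depth with a linear link and zero intercept — and a
#' single NB2 overdispersion \eqn{\alpha} shared across samples
#' (\eqn{Var = \mu + \alpha \mu^2}). The error rate \eqn{e} is the slope.
#'
#' The fit is robust to the presence of genuine mutations: samples that are
#' outliers from the regression must not inflate \eqn{e} or \eqn{\alpha}.
#' The scheme is iterative outlier masking with re-inclusion:
#' \enumerate{
#'   \item The slope is initialised from the lowest-AF stratum: the Poisson
#'     slope `sum(AO)/sum(DP)` over samples with `AO/DP` at or below the
#'     `init_quantile` AF quantile. This reflects the model's premise that
#'     the sequencing error rate is the floor of the allelic-fraction
#'     distribution, and keeps the start uncontaminated even when most
#'     samples carry the variant (as in a serial-dilution ladder).
#'   \item Every sample's outlier p-value is computed under the provisional
#'     fit and adjusted by Benjamini-Hochberg across samples; samples with
#'     `q < mask_fdr` *and* at least `min_ao_mask` variant reads are masked.
#'     The FDR screen is deliberately liberal (default 5%) compared with the
#'     stringent calling rule: fitting wants high sensitivity to
#'     contamination so that sub-threshold variants cannot inflate the
#'     dispersion, while calling wants high specificity. The `min_ao_mask`
#'     floor stops a degenerate low start from masking samples whose one or
#'     two variant reads are unremarkable at any plausible error rate.
#'   \item Refit by maximum likelihood on the unmasked samples
#'     (an intercept-only log-link fit with `offset(log(DP))`, which is
#'     exactly the linear-link zero-intercept model). The mask is recomputed
#'     from scratch each round, so samples masked under a poor early fit
#'     re-enter once the fit improves.
#'   \item Iterate to a fixed point (at most `max_rounds` rounds).
#' }
#' Masked samples get robustness weight 0 and do not influence the estimates.
#' The fit is deterministic given its inputs.
#'
#' @param dp,ao equal-length vectors of depth and variant-read counts; samples
#'   with `dp == 0` are dropped (with a message).
#' @param min_samples minimum usable samples; fewer signals an
#'   `insufficient_cohort` error.
#' @param e_floor error rate reported when all usable AO are zero (keeps
#'   downstream p-values defined).
#' @param mask_fdr BH false-discovery-rate level at which a sample is treated
#'   as a candidate variant and masked during fitting.
#' @param min_ao_mask minimum variant reads for a sample to be maskable.
#' @param max_rounds cap on masking iterations.
#' @param init_quantile AF quantile defining the initial slope stratum.
#' @return An object of class `error_model_fit`: list with `e`, `alpha`
#'   (overdispersion), `weights` (0/1 per input sample, NA for dropped
#'   zero-depth samples), `n_used`, `converged`, `rounds`.
#' @export
fit_robust_nb <- function(dp, ao, min_samples = 20, e_floor = 1e-6,
                          mask_fdr = 0.05, min_ao_mask = 3, max_rounds = 10,
                          init_quantile = 0.25) {
  stopifnot(length(dp) == length(ao))
  if (any(ao > dp)) stop("AO exceeds DP")
  usable <- which(dp > 0)
  if (length(usable) < length(dp)) {
    message(length(dp) - length(usable), " zero-depth sample(s) dropped from fit")
  }
  weights <- rep(NA_real_, length(dp))
  if (length(usable) < min_samples) {
    stop(structure(class = c("insufficient_cohort", "error", "condition"),
                   list(message = sprintf(
                     "insufficient cohort: %d usable samples < min_samples = %d",
                     length(usable), min_samples), call = sys.call(-1))))
  }
  dpu <- dp[usable]; aou <- ao[usable]
  if (all(aou == 0)) {
    weights[usable] <- 1
    return(structure(list(e = e_floor, alpha = 0, weights = weights,
                          n_used = length(usable), converged = TRUE, rounds = 0L),
                     class = "error_model_fit"))
  }
  af <- aou / dpu
  stratum <- af <= stats::quantile(af, init_quantile, names = FALSE)
  if (sum(stratum) < 2) stratum <- af <= stats::median(af)
  fit <- list(e = max(sum(aou[stratum]) / sum(dpu[stratum]), e_floor), alpha = 0)
  inlier <- rep(TRUE, length(aou))
  converged <- FALSE
  rounds <- 0L
  for (r in seq_len(max_rounds)) {
    rounds <- r
    q <- qvalues(nb_tail_pvalue(aou, dpu, fit$e, fit$alpha))
    new_inlier <- !(aou >= min_ao_mask & q < mask_fdr)
    if (sum(new_inlier) < 2) new_inlier <- inlier  # refuse to mask everything
    refit <- fit_nb_ml(dpu[new_inlier], aou[new_inlier], e_floor)
    done <- identical(new_inlier, inlier) && abs(log(refit$e / fit$e)) < 1e-6
    inlier <- new_inlier
    fit <- refit
    if (done) {
      converged <- TRUE
      break
    }
  }
  weights[usable] <- as.numeric(inlier)
  structure(list(e = fit$e, alpha = fit$alpha, weights = weights,
                 n_used = sum(inlier), converged = converged, rounds = rounds),
            class = "error_model_fit")
}

#' @export
print.error_model_fit <- function(x, ...) {
  cat(sprintf("error_model_fit: e = %.3g, overdispersion = %.3g, %d/%d samples used, %s\n",
              x$e, x$alpha, x$n_used, sum(!is.na(x$weights)),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# Maximum-likelihood NB2 fit of mean e*DP. glm.nb with an intercept-only
# log-link model and offset(log(dp)) is the same model; falls back to the
# Poisson MLE e = sum(ao)/sum(dp) when the NB fit degenerates (theta -> Inf
# or numerical failure).
fit_nb_ml <- function(dp, ao, e_floor) {
  if (length(ao) == 0 || all(ao == 0)) return(list(e = e_floor, alpha = 0))
  e_pois <- sum(ao) / sum(dp)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(ao ~ 1 + offset(log(dp)))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$theta) || fit$theta > 1e4) {
    return(list(e = max(e_pois, e_floor), alpha = 0))
  }
  list(e = max(exp(unname(stats::coef(fit)[1])), e_floor),
       alpha = 1 / fit$theta)
}

# Upper-tail P(X >= ao) under NB2(mean = e*dp, dispersion = alpha); exact
# Poisson tail in the alpha -> 0 limit.
nb_tail_pvalue <- function(ao, dp, e, alpha) {
  mu <- e * dp
  p <- if (alpha <= 0) {
    stats::ppois(ao - 1, mu, lower.tail = FALSE)
  } else {
    stats::pnbinom(ao - 1, mu = mu, size = 1 / alpha, lower.tail = FALSE)
  }
  pmin(pmax(p, 1e-320), 1)
}

#' Outlier p-value for one sample under a fitted error model
#'
#' Upper-tail probability `P(X >= ao)` under the fitted negative-binomial
#' error model with mean `e * dp`; reduces to the exact Poisson upper tail as
#' the overdispersion goes to zero. `ao = 0` gives p = 1.
#'
#' @param fit an `error_model_fit`.
#' @param dp depth (> 0).
#' @param ao variant reads (`ao <= dp`).
#' @return p-value(s) in (0, 1].
#' @export
variant_pvalue <- function(fit, dp, ao) {
  stopifnot(inherits(fit, "error_model_fit"))
  if (any(dp <= 0)) stop("dp must be positive")
  if (any(ao > dp)) stop("ao exceeds dp")
  nb_tail_pvalue(ao, dp, fit$e, fit$alpha)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjusted p-values with enforced monotonicity;
#' `q >= p` elementwise. The adjustment family is the set of samples tested at
#' one (site, alternate base).
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values, same length.
#' @export
qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Phred-scaled q-value
#'
#' `QVAL = -10 log10(q)`, capped (default 255, VCF-friendly); `q = 1` maps
#' to 0.
#'
#' @param q q-value(s) in \[0, 1\].
#' @param cap upper bound for the Phred scale.
#' @export
phred <- function(q, cap = 255) {
  if (any(is.na(q)) || any(q < 0) || any(q > 1)) stop("q must lie in [0, 1]")
  pmin(-10 * log10(pmax(q, 10^(-cap / 10))), cap)
}

#' Relative variant strand bias
#'
#' `RVSB = max(AO_p * DP_m, AO_m * DP_p) / (AO_p * DP_m + AO_m * DP_p)`,
#' in \[0.5, 1\]: 0.5 when variant reads distribute across strands in
#' proportion to depth, 1 when fully strand-restricted. A zero denominator
#' (all depth on one strand) returns 1 by convention, with attribute
#' `degenerate = TRUE`.
#'
#' @param ao_p,ao_m,dp_p,dp_m strand-resolved counts; `ao_p + ao_m` must be
#'   positive.
#' @export
rvsb <- function(ao_p, ao_m, dp_p, dp_m) {
  if (any(ao_p + ao_m <= 0)) stop("no variant reads: RVSB undefined")
  a <- as.numeric(ao_p) * as.numeric(dp_m)
  b <- as.numeric(ao_m) * as.numeric(dp_p)
  out <- ifelse(a + b == 0, 1, pmax(a, b) / (a + b))
  if (any(a + b == 0)) attr(out, "degenerate") <- TRUE
  out
}

#' Call variants from a count matrix
#'
#' The full caller: for each (site, alternate base) in the matrix, fit the
#' robust negative-binomial error model on combined-strand counts across all
#' samples, compute each sample's outlier p-value, adjust by
#' Benjamini-Hochberg across the samples of that (site, alt), and emit a call
#' for every sample whose Phred-scaled q-value exceeds `qval_threshold`.
#' RVSB is attached to every call; if `rvsb_max` is set, calls exceeding it
#' are flagged `strand_bias` in the `filter` column, never dropped.
#' Zero-depth samples are excluded from fitting and testing and reported in
#' the `no_coverage` attribute rather than as negatives.
#'
#' @param x a [site_count_matrix].
#' @param qval_threshold Phred threshold; a call requires `QVAL` strictly
#'   above it (default 30, i.e. q < 1e-3).
#' @param rvsb_max optional strand-bias ceiling for the filter flag.
#' @param min_samples minimum samples per (site, alt) fit; unfittable sites
#'   are skipped with a warning.
#' @param ... passed to [fit_robust_nb()].
#' @return A data frame of class `variant_calls` with columns `sample`,
#'   `contig`, `pos`, `ref`, `alt`, `DP`, `AO`, `AF`, `p`, `q`, `QVAL`,
#'   `RVSB`, `filter`; fitted models are attached as attribute `fits`.
#' @export
call_variants <- function(x, qval_threshold = 30, rvsb_max = NULL,
                          min_samples = 20, ...) {
  stopifnot(inherits(x, "site_count_matrix"))
  key <- paste(x$contig, x$pos, x$ref, x$alt, sep = "|")
  fits <- list()
  no_cov <- list()
  calls <- list()
  for (k in unique(key)) {
    g <- x[key == k, , drop = FALSE]
    dp <- g$DP_p + g$DP_m
    ao <- g$AO_p + g$AO_m
    usable <- dp > 0
    if (any(!usable)) {
      no_cov[[k]] <- g$sample[!usable]
    }
    fit <- tryCatch(
      suppressMessages(fit_robust_nb(dp[usable], ao[usable],
                                     min_samples = min_samples, ...)),
      insufficient_cohort = function(e) {
        warning("site ", k, " skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    fits[[k]] <- fit
    gu <- g[usable, , drop = FALSE]
    p <- variant_pvalue(fit, dp[usable], ao[usable])
    q <- qvalues(p)
    qv <- phred(q)
    hit <- which(qv > qval_threshold & ao[usable] > 0)
    if (length(hit) == 0) next
    h <- gu[hit, , drop = FALSE]
    sb <- rvsb(h$AO_p, h$AO_m, h$DP_p, h$DP_m)
    filt <- rep("PASS", length(hit))
    if (!is.null(rvsb_max)) filt[sb > rvsb_max] <- "strand_bias"
    calls[[k]] <- data.frame(
      sample = h$sample, contig = h$contig, pos = h$pos, ref = h$ref,
      alt = h$alt, DP = (h$DP_p + h$DP_m), AO = (h$AO_p + h$AO_m),
      AF = (h$AO_p + h$AO_m) / (h$DP_p + h$DP_m),
      p = p[hit], q = q[hit], QVAL = qv[hit], RVSB = as.numeric(sb),
      filter = filt, stringsAsFactors = FALSE)
  }
  out <- if (length(calls) > 0) {
    do.call(rbind, c(calls, list(make.row.names = FALSE)))
  } else {
    data.frame(sample = character(0), contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0), DP = integer(0),
               AO = integer(0), AF = numeric(0), p = numeric(0), q = numeric(0),
               QVAL = numeric(0), RVSB = numeric(0), filter = character(0),
               stringsAsFactors = FALSE)
  }
  attr(out, "fits") <- fits
  attr(out, "no_coverage") <- no_cov
  class(out) <- c("variant_calls", "data.frame")
  out
}
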