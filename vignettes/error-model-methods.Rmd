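---
title: "A multi-sample negative-binomial error model for low-abundance KRAS mutations in plasma cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-sample negative-binomial error model for low-abundance KRAS mutations in plasma cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmakras)
```

## The problem

Circulating tumour DNA carries somatic mutations at allelic fractions (AF)
that routinely fall below 1% of the cell-free DNA at a locus. At an amplicon
depth of ~2500 reads, a 0.5% variant contributes ~12 reads — the same order
as the platform's substitution-error background. A caller therefore cannot
use a fixed AF threshold; it must know, per position and per base change,
what the error background actually is, and it can learn that only by
looking across many samples sequenced under the same conditions.

## The model

For one (position, alternate base), let `DP_i` and `AO_i` be the total and
variant-supporting read counts of sample `i`. Errors are modelled as

\[
AO_i \sim \mathrm{NB}(\mu_i,\ \alpha), \qquad \mu_i = e \cdot DP_i,
\qquad \mathrm{Var}(AO_i) = \mu_i + \alpha\,\mu_i^2 ,
\]

a negative-binomial (NB2) regression with a **linear link and zero
intercept**: expected error reads are proportional to depth, with slope `e`
(the per-site error rate) and one overdispersion `alpha` shared across
samples. Fitting uses the exact reformulation as an intercept-only log-link
model with `offset(log(DP))`, so the maximum-likelihood machinery of
`MASS::glm.nb` applies unchanged; when the NB fit degenerates
(`theta -> Inf`), the Poisson MLE `e = sum(AO)/sum(DP)` with `alpha = 0` is
used. Strand-resolved counts enter the model combined; strands are used
only by the strand-bias statistic RVSB.

A sample's evidence of being a variant is its upper tail under the fitted
error model, `p_i = P(X >= AO_i)` (exactly the Poisson tail as
`alpha -> 0`). Within the test family of one (position, alt base), p-values
are adjusted across samples by Benjamini–Hochberg, reported as
`QVAL = -10 log10(q)` (capped at 255, VCF-friendly), and a variant is
called when `QVAL > 30`, i.e. `q < 1e-3`. BH is applied per (site, alt)
family — matching the per-position, per-base-change structure of the error
model — not across positions.

## Robust fitting

The regression must not be biased by the very mutations it is meant to
detect. The estimator here is an iterative masking scheme:

1. **Initial slope** from the bottom-quartile-AF stratum (Poisson slope
   `sum(AO)/sum(DP)` over samples with AF at or below the 25% quantile).
   The premise — sequencing error is the floor of the AF distribution —
   keeps this start uncontaminated even when most samples are mutant, as in
   a serial-dilution ladder.
2. **Mask** every sample with BH `q < 0.05` under the provisional fit,
   provided it has at least 3 variant reads. The screen is deliberately
   *liberal* compared with the stringent calling rule: fitting wants high
   sensitivity to contamination (a sub-threshold variant that stays in the
   fit inflates `alpha` and fattens every tail), while calling wants high
   specificity. The 3-read floor prevents a degenerate low start from
   masking samples whose one or two variant reads are unremarkable at any
   plausible error rate.
3. **Refit** by full maximum likelihood on the unmasked samples, recompute
   the mask from scratch (samples masked under a poor early fit re-enter
   once the fit improves), and iterate to a fixed point (at most 10
   rounds). Masked samples carry robustness weight 0.

An earlier design masked at the calling threshold itself (`QVAL >= 30`)
with a median-of-ratios initial slope. It fails on exactly the data the
assay is validated on: in a dilution ladder, 52 of 58 samples are mutant,
the first fit absorbs the mutant gradient into a huge overdispersion, no
sample is ever an outlier, and the fixed point calls nothing. The
FDR-masked scheme was adopted instead; in development simulations it
recovered `e` within ~1% on clean cohorts (with `alpha` essentially
unbiased at 0, 0.1 and 0.5), stayed within 10% of the truth with 10% of
samples contaminated at 5% AF, produced no family-wise false call in 400
null matrices at either of the assay's per-chip error rates, and on
ladder-only data kept the fit near the wild-type background.

Zero-depth samples are excluded from fitting and testing and reported as
no-coverage. If every usable sample has `AO = 0`, the error rate is
reported at a configurable floor (`1e-6`) so that downstream p-values stay
defined; fewer than 20 usable samples refuses to fit, since the error rate
cannot be learned from a small cohort.

## Strand bias

Each call carries

\[
\mathrm{RVSB} = \frac{\max(AO_p DP_m,\ AO_m DP_p)}{AO_p DP_m + AO_m DP_p}
\in [0.5, 1],
\]

0.5 when variant reads follow the depth split and 1 when fully
strand-restricted. No default cutoff is applied — the statistic is
computed and reported, and an opt-in `rvsb_max` flags (never drops) calls
above it, because a hard threshold is a platform-specific choice the
analyst should own.

## Annotation

The assay covers two amplicons on the minus strand of chromosome 12
(hg19): 25,398,271–25,398,309 (codons 4–16) and 25,380,228–25,380,307
(codons 51 onward), 119 bp in all. Genomic substitutions are
reverse-complemented and mapped linearly to cDNA coordinates; a packaged
CDS segment (codons 1–77 of the canonical KRAS transcript) supplies the
reference for HGVS c./p. naming and the missense/silent consequence.
Categories: hotspot (missense at codons 12/13/61), other-codon missense,
silent, and SNP-excluded — the packaged exclusion list ships with c.24A>G
(rs147406419, p.V8V), a rare germline variant that would otherwise appear
as a recurrent high-AF "somatic" call. The other-codon category does not
consult a live mutation database (membership is version-dependent); an
optional allow-list restricts it when needed.

## Synthetic data: what it emulates

No raw sequencing data are deposited for this assay, so every downstream
stage is exercised on generators whose defaults are the study's own
conditions.

**Dilution ladder** (`simulate_dilution`): abundances 100%, 50%, 20%, 10%,
5%, 2%, 1%, 0.5%, 0.2%, 0.1%, 0.05%, 0.02%, 0.01%; 4 replicates each plus 6
wild-type samples; depth NB with mean 2693 and SD 650 (the published
replicate depths ranged ~1000–4200 around that mean; the NB keeps counts
integral, and the SD is a reading of that range, not a fitted value);
background error rate 4.2e-4 (the pilot-chip estimate; the validation chips
ran at 1.4e-4) with overdispersion 0.1 — a mild extra-Poisson allowance; no
per-site dispersion is published, and 0.1 is a middle ground between the
pure-Poisson ideal and the heavy overdispersion of error-prone contexts.
`AO` is binomial mutant sampling plus NB background, truncated at `DP`
(mutant and error reads are indistinguishable in counts). Strands split
binomially at 0.5 with variant reads hypergeometric given the split, so
per-strand invariants hold by construction. One master seed derives one
seed per sample, so any subsample is reproducible under resizing.

**Case-control cohort** (`simulate_cohort`): 437 cases / 141 pancreatitis /
394 healthy; the cases' stage mix (39/143/135/120) and the stage-specific
carrier prevalences (10.3% / 17.5% / 33.3% / 15.0%), the control
prevalences (4.3%, 3.6%), the per-group hotspot-vs-other location mix, and
the per-group AF-bin occupancies are the study's published proportions,
with AF uniform within bin and the lowest bin edge at 0.08% — the smallest
AF the assay ever detected. Depth is NB(2888, SD 1259). CA19-9 is a
two-component lognormal chosen to give ~90% positivity at 37 kU/l in cases
and ~15% in healthy controls; log10 cfDNA concentration is normal per
group (means 2.0/1.8/1.7, SDs 0.7/0.7/0.6 ng/mL).

What the generators do **not** emulate: PCR-cycle error accumulation and
polymerase-specific error spectra (error reads are exchangeable across
cycles here), molecule-level bottlenecks at very low input (at 0.01%
abundance, 2 ng of DNA carries <1 mutant molecule per reaction — real
replicates at the bottom rungs are dominated by sampling the input, which
the binomial-at-depth model understates), batch structure between
sequencing runs, and germline contamination other than the packaged SNP.
Passing tests on these generators therefore show the *statistical* pipeline
is correct under its stated model, not that the wet-lab assay achieves the
simulated performance.

## The detection limit at depth 2500

A point the package is explicit about: at depth 2500 and error rate
4.2e-4, a 0.2% AF replicate carries ~6 expected variant reads against ~1
expected error read, while the `QVAL > 30` boundary (after BH adjustment
across the ladder's 58 samples) sits at 7–8 reads. Detection of a 0.2%
replicate is therefore close to a coin flip *even if the error model is
known exactly*, and "at least 3 of 4 replicates" at 0.2% is the lucky side
of that flip. The package's dilution analysis
(`analysis/01_dilution_limit.R`, `scripts/acceptance.R`) reports the median
detection limit over 20 simulated ladders, which lands at 0.5% AF; single
ladders do resolve 0.2% occasionally, and consistently once depth or input
rises. The structural lesson — the limit is set by absolute read counts at
the BH/QVAL boundary, not by the error rate alone — holds throughout.

## The evaluation stage

Inclusion requires total cfDNA yield >= 4 ng (inclusive — "at least") and
mean depth > 1000 (strict — "above"). Per-subject tallies count each
subject once per reporting mode: hotspot-only, any-screened-codon (any
retained mutation, silent included), and missense-only; SNP-excluded calls
contribute nothing; a subject's AF is the maximum over their calls (the
aggregation is not pinned down by the published analysis; the maximum is
the natural choice for a detection-oriented marker and affects only the
handful of multi-mutation subjects).

Specificity denominators are explicit, because the published arithmetic
forces two conventions: KRAS-only specificities use all non-case subjects
(55/56 = 98.2%), while CA19-9 and combined specificities use only subjects
with a CA19-9 measurement (35/54 = 64.8%) — two benign-neoplasm subjects
were never measured. `diagnostic_performance` exposes this as
`denominator_policy` and every proportion carries its numerator and
denominator. Percentages are rounded half-up to one decimal, matching the
published tables.

The combined test is a logical OR (KRAS-positive or CA19-9 >= 37 kU/l).
For the ROC comparison the combined assay needs a score: the convention
here promotes mutation-positive subjects above the maximum observed CA19-9
level (a binary override), since the mutation call has no natural
continuous scale. Note the override promotes mutation-positive *controls*
too: on cohorts where controls carry mutations at a few percent, the
combined AUC can fall slightly below CA19-9 alone — visible in the
synthetic-cohort driver, and a real property of the OR-rule, not a bug.
AUCs are compared by DeLong's paired test (`pROC`). Stage trends use
Pearson chi-squared without continuity correction on the detected-by-stage
table; group AF comparisons are Welch t-tests on log10(max AF) among
detected subjects; cfDNA yield is analysed as one-way ANOVAs of log10
concentration with missing stage kept as its own stratum.

## Numerical choices and degenerate inputs

* Tail p-values are floored at 1e-320 (QVAL is capped at 255 anyway);
  `AO = 0` gives p = 1 exactly.
* `phred(0)` returns the cap; q outside [0, 1] is a domain error.
* RVSB with a zero denominator (all depth on one strand) returns 1 with a
  `degenerate` flag; zero variant reads is an error, not a value.
* Identical AF vectors in a group test give p = 1 (no evidence) rather
  than an error; a constant-response ANOVA reports F = 0; identical ROC
  scores report a delta of 0 with p = 1.
* BH ties resolve by stable ordering; determinism is absolute given inputs.
* Problem sizes in the test-suite simulations (cohorts of ~150–2000,
  40–60 null matrices per error rate, 9–20 ladders) were chosen as the
  smallest sizes at which the asserted tolerances are comfortably
  non-flaky under the fixed seeds.

## Known limitations

* The robust scheme is a designed stand-in for the bounded-influence
  robust NB estimators of the literature; it is validated by its measured
  operating characteristics (bias, breakdown, calibration), not by
  equivalence to any published estimator.
* One overdispersion per (site, alt) is shared across samples; run- or
  batch-specific dispersion is not modelled.
* Only substitutions are handled; indel symbols in pileups are skipped by
  design.
* The cohort generator draws one mutation per carrier; multi-mutation
  subjects (a few per thousand in the study) arise only in the packaged
  pilot fixture.
* Whether q-values should additionally be adjusted across positions is an
  open modelling question; the package adjusts within (site, alt) families
  only.
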