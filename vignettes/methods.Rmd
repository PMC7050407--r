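---
title: "Models and methods in aseglmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in aseglmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseglmm)
```

# The problem

Allele-specific expression (ASE) compares the RNA-seq read counts of the
two alleles at a heterozygous SNP within the same sample. Because both
alleles share one cellular environment, an imbalance indicates
*cis*-acting regulation, and a *difference* in imbalance between two
subject groups (here, subjects with alcohol use disorder versus
social/non-drinking controls) points to regulatory variation associated
with the phenotype. `aseglmm` implements three coupled analyses around
this idea:

1. **Differential ASE in brain tissue** — per-SNP tests of whether
   allelic imbalance differs between groups, across brain regions.
2. **Pooled 3'UTR reporter screening** — counting and testing of a
   barcoded, UMI-tagged reporter assay that compares each variant's
   expressed RNA against its input plasmid DNA in transfected cell
   lines.
3. **Ethanol dose response** — testing whether a SNP's allelic ratio in
   cultured cells shifts with ethanol dose.

A synthetic-data generator reproduces the statistical structure of all
three experiments so that the pipelines can be calibrated and validated
without access to the original (restricted) human data.

# The core model

For one SNP, each heterozygous subject contributes two counts: reads
supporting the reference allele and reads supporting the alternative
allele. The model for the expected count \(\mu\) is a negative binomial
GLMM with a log link:

\[
\log(\mu) = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_{12} X_1 X_2 + b_s,
\qquad b_s \sim N(0, \sigma_b^2),
\]

where \(X_1\) is the allele (0 = reference, 1 = alternative), \(X_2\)
the group (0 = control, 1 = case), and \(b_s\) a per-subject random
intercept that absorbs each subject's overall expression level — the
device that makes the two counts of one subject serve as each other's
internal control. Counts are NB2: \(\mathrm{Var}(y) = \mu + \mu^2 /
\theta\), with one dispersion \(\theta\) per SNP shared across
observations.

The quantity of interest is the allele-by-group interaction
\(\beta_{12}\): the difference, between groups, in the log ratio of
alternative to reference expression. The null hypothesis is
\(\beta_{12} = 0\). Results are reported both on the natural-log scale
and as the **adjusted log2 fold change** \(\beta_{12}/\log 2\), the
group difference in log2 allelic odds.

The same engine serves the other two analyses with different designs:
the reporter assay uses a fixed-effects NB GLM on (allele, source,
replicate) observations with a log library-size offset and an
allele-by-source interaction (RNA versus plasmid DNA); the ethanol
analysis uses allele, continuous dose (mM), their interaction, and a
random intercept per library.

# Fitting

`fit_nb_glmm()` maximizes the Laplace-approximate marginal likelihood
over \((\beta, \log\theta, \log\sigma_b)\). For each evaluation, every
subject's random-intercept mode is found by a damped inner Newton solve
(the joint density is strictly concave in the intercept), and the
integral is replaced by its Laplace approximation **plus the standard
fourth-order correction** (the Gaussian expectation of the cubic and
quartic remainder at the mode). The correction matters: at read depths
around 50–100 the plain first-order Laplace term is off by about
\(10^{-3}\) per subject relative to exact quadrature, while the
corrected objective agrees with a 32-node adaptive Gauss–Hermite
evaluation to ~\(10^{-5}\) on full datasets. The outer problem is
solved by bounded quasi-Newton (`nlminb`) with a compiled objective and
gradient, followed by a few damped Newton polishing steps that reuse the
numeric Hessian; polishing restores exact model invariances (sign flips
under allele or group relabelling) to ~\(10^{-8}\), where the
optimizer's stopping rule alone leaves ~\(10^{-4}\) slop in flat
directions.

Numerical choices worth knowing:

* **NB log-density.** Computed via R's saddle-point `dnbinom_mu`; the
  textbook lgamma expression loses about seven digits to cancellation
  once \(\theta \gtrsim 10^6\) and corrupts finite-difference
  derivatives.
* **Design standardization.** Non-indicator design columns are
  internally scaled to max-abs 1 and the coefficients and covariance
  transformed back, so fits are exactly invariant to covariate units
  (dose in mM or M) and the optimizer is well conditioned.
* **Boundary handling.** \(\sigma_b\) is optimized on the log scale,
  where the likelihood flattens as \(\sigma_b \to 0\); the optimizer
  stops anywhere on the numerically-zero plateau (empirically
  \(\sigma_b \lesssim 10^{-4}\) when the true variance is zero), so
  boundary detection uses \(\sigma_b < 10^{-3}\) (configurable via
  `nb_fit_control()`). A boundary fit is refitted as the fixed-effects
  GLM and flagged `status = "boundary"`. A stalled joint fit whose
  \(\sigma_b = 0\) profile attains the same likelihood is likewise
  resolved to the boundary rather than reported as a failure.
* **Dispersion.** \(\theta\) is capped at \(10^8\) (the Poisson limit).
  The fixed-effects GLM uses a profile strategy — exact IRLS for
  \(\beta\) at each \(\theta\), one-dimensional search over
  \(\log\theta\) — so saturated designs (where \(\theta\) is
  unidentified but the means are) still return exact coefficient
  estimates.
* **Separation.** Coefficients are boxed at \(\pm 30\) on the
  standardized scale; estimates pinned at the box (e.g. an all-zero
  design cell) flag the fit `degenerate`, and no pseudocounts are ever
  added, since they would bias the interaction.

Inference on \(\beta_{12}\) is a two-sided normal Wald test,
\(z = \hat\beta_{12}/\mathrm{SE}\). The covariance of the fixed effects
is the \(\beta\) block of the inverse of the full joint numeric Hessian
(parameters at their bounds dropped), which propagates uncertainty in
\(\theta\) and \(\sigma_b\) into the SEs; this matches what glmmTMB
reports for the same model. Multiple testing uses Benjamini–Hochberg,
applied within each brain region (and within each cell line for the
reporter assay), because the source study reports per-region counts; a
pooled analysis is a trivial variation the user can perform on the
combined table.

## An independent oracle

`loglik_oracle()` evaluates the same marginal likelihood by adaptive
Gauss–Hermite quadrature, centered and scaled at each subject's mode. It
shares no code with the fitting path: the NB density comes from
`stats::dnbinom`, mode finding from `stats::optimize`, nodes from
`pracma::gaussHermite`, and it matches direct numerical integration to
machine precision. Doubling nodes from 32 to 64 changes the result by
less than \(10^{-8}\) on realistic data, so 32-node AGH serves as the
ground truth against which the Laplace objective is tested.

# Decision rules

* **Testability filter (brain ASE).** A subject contributes to a SNP
  only if genotyped heterozygous there *and* its total count exceeds 10
  reads (strict, read as the per-sample total at the SNP); a SNP is
  testable only with at least 5 qualifying heterozygotes in *both*
  groups. Every excluded record is written to an audit table with its
  reason. Heterozygosity comes from the genotype table (subjects were
  array-genotyped); a count-based heuristic (both alleles observed) is
  available but off by default.
* **Significance (brain ASE).** FDR < 0.05 *and* |adjusted log2 FC| >
  1. Whether the effect-size threshold is meant on the log2 or the
  natural-log scale is ambiguous in the source description; the default
  applies it to the adjusted log2 fold change, with `scale = "ln"`
  thresholding the raw interaction instead.
* **Cross-region consistency.** SNPs passing FDR in a primary region
  (FDR only — no effect-size filter) are looked up in every other
  region at nominal p < 0.05, and concordance is the agreement of the
  interaction's sign. SNPs untested in a secondary region are skipped,
  not counted as discordant.
* **Reporter assay.** A SNP is "detected" when both alleles have
  non-zero UMI counts in both sources (per cell line for testing) or in
  both cell lines (for the detection-rate summary). Demultiplexing
  requires a unique barcode within the mismatch tolerance — equidistant
  ties are always unassigned. UMI deduplication defaults to distinct-UMI
  counting, which exactly recovers the truth in error-free simulation;
  the `directional` mode implements the count-adjacency rule
  (collapse B into A when the Hamming distance is 1 and
  \(c_A \ge 2 c_B - 1\)) for data with UMI sequencing errors. Allele
  assignment is exact substring matching against the designed inserts —
  the constructs are short, known sequences, so alignment heuristics
  would only add nondeterminism; reads covering only shared flank are
  `ambiguous`.
* **Ethanol.** SNPs need a mean per-library depth strictly above 15
  reads and a pooled minor-allele fraction of at least 10% in the
  treated or the untreated pool. Dose enters the GLMM as a continuous
  covariate in mM; the Wald test is on the allele-by-dose interaction,
  the per-mM change in log allelic ratio.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions. `sim_config()` encodes a cohort of 30 + 30 subjects across
four brain regions (240 samples), heterozygosity probability 0.3, NB
dispersion \(\theta = 10\) and random-intercept SD \(\sigma_b = 0.3\)
(the real per-SNP values are unreported; these are stated placeholders,
not estimates), and read depth 100 per heterozygous sample. The
intercept is calibrated per group as
\(\beta_0 = \log(\text{depth}) - \log(1 + e^{\beta_1 + \beta_{12} g}) -
\sigma_b^2/2\) so the *expected total* equals the nominal depth in both
groups — including the \(e^{\sigma_b^2/2}\) lognormal inflation, which
the naive calibration would miss by ~4.6% at \(\sigma_b = 0.3\) — and
the testability filters stay group-neutral.

The reporter-read generator emits `barcode (8 nt) + UMI (10 nt) +
insert` reads (the real protocol's exact layout lives in an unavailable
supplement, so the layout is configurable and documented rather than
inferred), with NB molecule counts per construct and library, planted
RNA-only activity effects on the alternative allele, and PCR duplicates
drawn per molecule as Geometric(1 − duplication rate), support ≥ 1. The
truth table records molecules, distinct UMIs and reads, so the pipeline
can be held to exact recovery. The ethanol generator plants a per-mM
slope on the log allelic ratio with a per-library lognormal depth
effect; the replicate effect is placed on the library mean — matching
the fitted model's random intercept — with an optional
allele-asymmetric `sigma_ratio` nuisance (default 0) for stress
testing, since ratio-level replicate noise that the model does not
represent would by construction break null calibration.

What the generator does *not* emulate: reference-mapping bias (the
group-contrast design cancels alignment bias shared between groups,
which is also why no per-allele bias correction is applied),
sequencing-error substitutions in reads, alignment artifacts, linkage
between SNPs, and any real allele-frequency spectrum. Passing tests on
synthetic data therefore demonstrate the statistical machinery, not
robustness to those real-data phenomena.

# Operating characteristics, honestly

With all seeds fixed, the package's own acceptance checks measure the
pipeline's operating characteristics at the study's design points
(problem sizes chosen to keep the full suite within a few minutes on one
CPU: 500–2000 simulated SNPs per Monte-Carlo check, 20 replicate runs
for the mixture experiment):

* The planted interaction \(\beta_{12} = \log 2\) is recovered with
  absolute bias below 0.01 at 15 + 15 heterozygotes and depth 100; the
  ethanol slope is recovered within a few percent; the reporter
  round trip is exact.
* The normal-reference Wald test is **anti-conservative at the minimal
  testable design**: at 5 + 5 heterozygotes and depth 50 the null
  rejection rate at \(\alpha = 0.05\) is ≈ 0.10–0.12, falling to
  ≈ 0.06 at 15–20 subjects per group. This is a property of ML-based
  Wald tests with 20 observations and 6 parameters, not of the
  implementation: on shared simulated datasets the p-values coincide
  with glmmTMB's to five digits and the rejection sets are identical,
  and the likelihood-ratio variant is only marginally better (≈ 0.09).
  Consequently BH's empirical FDR on a planted mixture at 10 + 10
  subjects runs above its nominal level. Users testing SNPs near the
  5-heterozygote floor should treat borderline q-values with
  correspondingly more caution — or demand deeper designs, which is
  precisely the trade-off the power grid (`power_grid()`) quantifies.

# Known limitations

* Biallelic SNPs only; multi-allelic sites are rejected at input.
* One sample per subject per region; no repeated-measures designs.
* No beta-binomial alternative, random slopes, or haplotype models.
* The ethanol GLMM is this package's stated reconstruction (continuous
  dose, allele-by-dose interaction, random intercept per library); the
  original study's exact supplementary specification is unavailable,
  and the 24 h/42 h timepoints are pooled by default with the label
  kept in the records.
* The real study's headline counts (e.g. 88 differential-ASE SNPs)
  require controlled-access genotypes and are not reproducible from
  synthetic data; nothing in this package claims otherwise.
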