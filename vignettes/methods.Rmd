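---
title: "Models and methods behind mstquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mstquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mstquant` turns raw qPCR quantification cycles (Cq) and membrane-filtration
colony counts into comparable concentrations of fecal-indicator and
source-tracking targets across environmental matrices, and fits Bayesian
risk-factor models to the result. This vignette is the package's account of
the statistical machinery: the models, the priors, the numerical choices,
and what the synthetic-data studies do and do not demonstrate.

## Detection cutoffs from host-labeled panels

A reaction detects its target when its Cq is numeric and **strictly below**
an assay-specific integer cutoff; nondetects never count as detections, and
a Cq exactly at the cutoff is negative. Cutoffs are chosen by sweeping
integer values from 10 Cq to the assay's cycle ceiling over a validation
panel of reactions from known fecal sources (extraction blanks included as
non-targets), computing reaction-level sensitivity and specificity at each
cutoff, and selecting the **highest** cutoff that maximizes the Youden index
$J = \text{sensitivity} + \text{specificity} - 1$. The high tie-break
matters: $J$ is frequently flat over a range of late cutoffs, and choosing
the highest preserves sensitivity to weak positives. Reported diagnostics
are then computed at the **sample** level (a sample is positive when any of
its reactions is positive), over fecal samples only — blanks inform the
sweep but not the sample-level table, whose denominators are the labeled
panels. For general fecal assays every fecal sample is a target, so
specificity and accuracy are undefined and reported as missing.

## Multilevel calibration curves

Standard dilution series (triplicate reactions of $10^5$–$10^1$ copies in
routine runs) are fit with

$$\mathrm{Cq}_i \sim \mathcal N\big((\beta_0 + b_{0,\mathrm{run}(i)} +
b_{0,\mathrm{batch}(i)}) + (\beta_1 + b_{1,\mathrm{run}(i)} +
b_{1,\mathrm{batch}(i)})\, x_i,\ \sigma\big),$$

with $x$ the known log₁₀ copy number. Both intercept and slope vary by
instrument run and by extraction batch, absorbing day-to-day instrument
drift and extraction efficiency differences. Population coefficients get
effectively flat priors (Normal with SD 1000).

**Group-SD priors.** The offsets' SDs get weakly informative
half-Student-t(3, 0, scale) priors with scales on each parameter's natural
units: 2.5 Cq for intercept offsets and the residual SD (a functioning
assay does not shift by more than a few Cq between runs), and 0.5 Cq per
log₁₀ copy for slope offsets (usable curves have slopes near −3.3; run-to-run
slope variation beyond half a unit would indicate a broken assay, not noise).
A single scale proportional to sd(Cq) — which is ~5 across a dilution series,
giving a ~12-unit scale — is far too weak for slope offsets when only a
handful of runs and batches inform them, and visibly inflates and biases the
population-slope marginal.

**Sampling.** Models run in JAGS with the `glm` module loaded: its block
samplers are essential here, because single-site updating mixes
pathologically along the ridge between the population intercept and its
group offsets (split-R̂ near 3 at production settings; ~1.00 with blocking).
Chains are additionally initialized at the pooled OLS fit. Production
settings are 4 chains × 2000 warmup / 2000 sampling iterations; fits gate on
split-R̂ ≤ 1.01 and bulk effective sample size ≥ 400 for the population
parameters, attaching a warning (never silently discarding a fit) when the
gate fails.

With one run and one batch the population intercept is confounded with the
offsets; the identified quantity is the effective per-group curve, which is
what `curve_draws()` exposes and what the test suite compares against OLS.

## Concentrations with propagated uncertainty

For each posterior draw $d$ and amplifying replicate reaction, the
reaction's content is inverted through the draw's group-specific curve,
$\hat x_d = (\mathrm{Cq} - a_d)/b_d$, and normalized by the **sampling
effort** — the amount of original matrix the reaction represents, in the
unit concentrations are reported in (100 mL water, 100 cm² surface, dry g
soil). Effort arithmetic: a reaction carries 1/20 of the filtered volume
(5 µL of a 100 µL extract); 1 mL of eluate represents 0.01 g wet soil or
8.33 cm² of swabbed surface; soil efforts convert to dry mass via the
moisture fraction $m = (\text{wet} - \text{dry})/\text{wet}$; five-fold
template dilution of an inhibited sample (specimen-processing-control Cq
more than 3 cycles above its extraction controls, strictly) divides effort
by 5.

The per-replicate draw vectors are **pooled** (concatenated) to form the
sample's concentration posterior, summarized as mean, SD, and 2.5/97.5
percentiles. Pooling treats replicates as repeated measurements of the same
quantity and reproduces the natural reading of combining transformed
posterior draws; a per-draw average across replicates is available via
`combine = "average"`. Draws with nonnegative slope cannot be inverted and
are excluded with a count (the posterior is not re-weighted). Nondetect
replicates are excluded from quantification — detection is a separate
any-positive call — and a sample with no amplifying reactions returns a
left-censored record at its limit of detection rather than a posterior.

## Process detection limits

Limits are per sample, because effort is. For culture, a plate can detect 1
cfu and count at most 400, so LLoD = 1/effort at the **largest** volume
filtered and ULoQ = 400/effort at the **smallest** — including the re-filter
volume used when all initial plates saturate (1 mL water, 0.01 mL eluate);
that convention is what makes the water ULoQ 4.6 rather than 3.6 log₁₀. For
molecular targets, the LLoD is the concentration whose expected Cq equals
the detection cutoff, computed per calibration draw:
$(\text{cutoff} - a_d)/b_d - \log_{10}(\text{effort})$, summarized as a mean
and SD. Both the across-draw SD (assay uncertainty) and across-sample SD
(effort heterogeneity) are informative; the workflow reports them labeled.

## Censored inference

Concentration distributions per target × matrix are summarized by maximum
likelihood under a normal model for log₁₀ concentration with left-censoring
at per-sample LLoDs and right-censoring at ULoQs: density for observed
records, CDF at the limit for left-censored, survival for right-censored.
Optimization is L-BFGS-B on $(\mu, \log\sigma)$ initialized at the naive
estimates treating censored records as observed at their limits; standard
errors come from the numerically differentiated observed information at the
optimum. The fit requires at least one uncensored record (all-censored data
are not identifiable) and errors on degenerate $\sigma \to 0$. The installed
`fitdistrplus::fitdistcens` serves as an independent cross-check in the test
suite, never as the implementation.

Censored records can be imputed by the truncated-normal expectation,
$\mu - \sigma\,\phi(\alpha)/\Phi(\alpha)$ (left) with
$\alpha = (\text{limit} - \mu)/\sigma$, computed via log-space Mills ratios
so extreme limits give finite values on the correct side of the limit rather
than NaN.

## Risk-factor models

Each model is univariable: one predictor plus intercept(s), fitted per
target × matrix. The response is the (censored) log₁₀ concentration when
the target was detected in at least 75% of the stratum's samples —
a detection fraction of exactly 0.75 keeps the concentration response,
since only strictly lower fractions are degraded to binary — and detection
status otherwise. Continuous predictors other than cumulative precipitation
are mean-centered and scaled, by SD or by a stated unit (the wealth index
by 10 points of its 0–100 scale); precipitation enters as uncentered 7- and
30-day cumulative sums and rain-day counts.

Censored linear models use the censored-normal likelihood with mean
$\alpha + \beta x (+ u_{\text{compound}})$, priors Normal(0, 10) on the
intercept, Normal(0, 2) on the slope, and half-Student-t(3, 0, 2.5) on the
residual and compound-intercept SDs. Logistic models use Student-t priors
with 5 degrees of freedom (scale 10 intercept, 2.5 predictor) and report
the odds ratio $e^\beta$. Compound-varying intercepts are included for
household-level sample types (stored water, food surfaces, household soil);
compound-level types contribute one sample per compound and get none.
Production settings are 4 chains × 1500 warmup / 1000 sampling iterations.
Under quasi-separation the regularizing priors keep estimates finite; such
fits are flagged (binary predictors with an outcome cell of ≤ 1
observation, or posterior-mean |log OR| > 5). No multiplicity adjustment is
applied; the effect table records the number of models fitted so readers
can calibrate expectations for false-positive null exclusions.

## The synthetic-data generator

Because the pipeline's field data are not distributable, the generator
produces every input with known ground truth: standard series with
run/batch curve offsets drawn once per group; host-labeled validation
panels with per-reaction sensitivity and cross-reaction rates; and an
environmental campaign — compounds containing households, five sample
types, true log₁₀ concentrations built from matrix means, compound
intercepts (SD 0.5), covariate effects, and matrix-level noise. Reactions
are generated through the inverse calibration relation with a nondetect
whenever the realized Cq exceeds the assay ceiling; plates are Poisson in
(concentration × effort) with counts above 400 flagged too-numerous-to-count
and a protocol-style re-filter plate added when the smallest initial plate
saturates. Default conditions: calibration intercept 38 Cq, slope −3.4
(≈97% efficiency), residual SD 0.3 Cq, run/batch offset SDs 0.5 Cq
(intercept) and 0.1 (slope); matrix concentration means 2.5 (source water)
to 6.7 (household soil) log₁₀ for the general indicator, with a
host-associated target 3 logs lower so both the concentration and the
detection modeling branches are exercised downstream.

What the generator does **not** emulate: separate culture and molecular
organisms (one latent concentration drives both, so culturable counts track
the molecular target exactly up to Poisson noise, which real samples do
not); inhibition; background contamination of reagents; assay-specific
amplification chemistry (the intercept-38 default gives lower process LLoDs
than probe assays achieve in practice); and spatial or temporal correlation
beyond compound clustering. Passing recovery tests therefore demonstrates
the inferential machinery is correct under its own assumptions, not that
those assumptions hold in any particular field setting.

## Simulation studies and problem sizes

The test suite and `scripts/acceptance.R` run the recovery studies at sizes
chosen to give stable rates while keeping a full run in minutes on one CPU:
calibration coverage over 50 replicate fits of 180 standards at production
MCMC settings; censored-MLE recovery over 100 replicates of n = 500 (truth
μ = 4.26, σ = 0.83, left-censored at 3.36 — the regime of a heavily
contaminated stored-water indicator); null calibration of the censored
linear model over 200 replicates of n = 60 with 30% censoring at reduced
MCMC settings (2 × 400/400), and slope/odds-ratio recovery over 50
replicates each. Reduced MCMC settings are adequate for interval endpoints
at these sample sizes; the calibration coverage study uses full settings
because short chains visibly under-explore the intercept ridge and produce
anti-conservative intervals.

## Known limitations

- The calibration model assumes a common residual SD across runs and
  batches and linearity over the full dilution range; saturation at very
  high copy numbers is not modeled.
- Nondetect standards are dropped from calibration rather than treated as
  censored; at the simulated regimes standards essentially always amplify.
- The censored MLE treats per-sample posterior means as data, ignoring
  their posterior SDs; a full joint model would propagate both.
- Moisture imputation uses predictive mean matching with moisture as the
  only incomplete variable, so the chained-equations cycle reduces to a
  single imputation model; auxiliaries must be complete.
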