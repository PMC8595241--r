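---
title: "Models and methods behind mechtrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mechtrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechtrial)
```

mechtrial assembles a mechanistic in silico clinical trial from four model
layers: virtual populations, individualized pharmacokinetics, a
network-based mechanism-of-action layer scored with the tSignal statistic,
and a statistical analysis suite. This vignette explains each model, its
assumptions, the tunable parameters that matter, and the design choices
made where the methodology was genuinely open. Everything shown here is
computed by the package; the test suite exercises the same code paths on
the same synthetic generators.

## Virtual populations

A trial population is described by a `DemographicReference`: per-variable
mean and SD for age (years), height (cm), weight (kg) and BMI (kg/m²),
plus the female fraction. The package ships the two references of its
ADHD case study: adults (age 36.58 ± 10.10, height 171.7 ± 9.4, weight
78.75 ± 17.20, 41.6% female, n = 511; BMI unreported) and
children-adolescents (age 10.90 ± 2.80, weight 43.60 ± 15.10, BMI 19.1 ±
3.4, 20% female, n = 111; height unreported). Variables a reference does
not report are filled from a standard-population table
(`standardFillTable()`), mirroring the use of survey data to complete
trial summaries.

**Adults.** `generateAdultVpop()` samples (age, height, weight) from a
multivariate normal whose marginals carry the reference moments,
truncated to adult ages (> 18 y) and positive anthropometry. The
reference tables print no covariances, so the height–weight correlation
defaults to 0.5 (configurable); other pairs are uncorrelated. BMI is
never sampled — it is the physical identity weight/(height/100)², which
every emitted patient satisfies to 1 part in 10⁶. A simulated-annealing
refinement (200 iterations, geometric cooling at 0.95, proposal =
replace one patient with a fresh draw) minimizes the standardized moment
mismatch Σ((x̄−μ)/σ)² + ((s−σ)/σ)² over the targeted variables. The hard
guarantee is the acceptance rule: a candidate population is returned only
if every reference-reported variable passes a one-sample z-test
(z = (x̄−μ)/(σ/√n), two-sided, p > 0.05); otherwise the generator restarts
(up to 20 times) and errors with the best cost achieved if it never
passes. Sex is a quota variable (round-half-up), not part of the joint —
the case-study references report exact sex matches.

**Children and adolescents (6–17 y).** Growth makes the morphometric
variables strongly age- and sex-dependent, so the adult recipe does not
apply. The generator takes a `GrowthReference` — a WHO-style grid of
height/weight mean and SD per integer age and sex — and samples height
and weight with parallel Metropolis–Hastings chains (one per patient,
vectorized; Gaussian random-walk proposals with step 0.5 SD, burn-in
1,000, thinning 10). The conditional target multiplies the reference
marginals of the reported variables (weight, and derived BMI) with the
growth-conditional height density (height is unreported in the packaged
reference), and constrains height and weight to ±4 SD of their age–sex
growth cell. Ages are drawn exactly from the reference age marginal
truncated to 6–17. We deliberately do *not* let age move inside the MH
state: the growth windows would then act as an unnormalized modifier of
the age marginal and bias it upward by roughly half a year at n = 500 —
enough to fail the generator's own z-test gate systematically. Drawing
age from its (truncated) marginal and sampling the other variables
conditionally keeps every targeted moment honest. The same z-test
acceptance loop applies.

The packaged growth grid is synthetic: smooth, realistically shaped
curves whose SDs and slopes are of WHO order, calibrated so that the
grid's age-aggregated implied joint (mean height ≈ 149 cm at the
reference age distribution, BMI rising from ~17 to ~21 kg/m²) is
coherent with the packaged pediatric reference. It is not measured
percentile data and is labeled as such; substitute a real growth table
via `readGrowthReference()` for production work.

**Arms.** `assignArms()` randomly partitions a population into arms
without replacement and copies comorbidity tags from the arm specs.
`nineArmDesign()` encodes the case-study design: one disease-only arm of
500 plus eight comorbidity arms of 100 per population — 1,300 patients
per population, 2,600 in the two-population trial.

## PBPK exposure

The whole-body model has 14 compartments (blood, gut, liver, kidneys,
brain, heart, lungs, muscle, adipose, skin, bone, spleen, pancreas,
rest-of-body) in a hub-and-spoke topology: blood is the unique central
compartment; every organ exchanges with blood only. Dosing enters at the
gut (oral), blood (IV) or skin (SC); oral and subcutaneous doses pass
through a first-order absorption depot scaled by bioavailability F.

Organ volumes scale linearly with body weight through a configurable
allometric table (adipose additionally scales with BMI/24); flows are
fractions of cardiac output, computed as an age- and sex-banded heart
rate times a weight-proportional stroke volume (1 mL/kg). The table
values are standard-order physiological fractions shipped as data —
swap in your own table to change the anthropometric model.

Transport is flow-limited with unit partition coefficients by default
(none are published for the case-study drugs; set `partition` per drug to
change this). Clearance is restricted to gut, liver and kidneys and is
modeled as first-order extraction of blood-borne drug: the flux at site
s is k_s · A_blood (k_s in 1/h), bookkept per site. This "well-stirred,
blood-side" simplification keeps the system linear and makes the
one-compartment limit exact: with all organ flows and non-renal
clearance zeroed, blood concentration collapses to the closed-form
Bateman curve F·D·k_a(e^(−k_e t) − e^(−k_a t))/(V(k_a − k_e)), which the
test suite verifies to 0.5%. The price is that clearance does not depend
on the clearing organ's local concentration — acceptable for the
flow-limited, unit-partitioning defaults, and stated here so nobody
mistakes it for an organ-extraction model.

Extended-release products are approximated by repeated lower doses:
two administrations of half the dose for the modified-release capsule,
three of one third for the osmotic-release system, 4 h apart (the
interval is configurable; the case study's own description mixes
"twice a day" with 4-hourly sampling figures, and we default to 4 h).

Integration uses `deSolve::lsoda` with rtol 1e-8 / atol 1e-10 on a 0.1 h
output grid; bolus doses are solver events. Mass balance —
depot + Σ compartment amounts + Σ cleared = F · administered — holds to
integration tolerance at every output time and is exposed via
`massBalanceError()`. `fitAbsorptionClearance()` estimates (k_a, renal
clearance, blood-volume adjustment) by Levenberg–Marquardt least squares
on log-parameters from observed blood concentrations; the blood-volume
multiplier is how the model absorbs a compound's volume of distribution,
which is otherwise unidentifiable from the fixed anatomical volumes.

## Mechanism of action and tSignal

Drug exposure reaches the molecular layer through the Emax link:
for each target, modulation = effect · mean over brain-concentration
timepoints of c/(c + EC50) (Hill coefficient 1 by default; `hill` and
the `max` aggregate are configurable). EC50 values are user inputs —
how the original technology derives them from clinical efficacy
observations is not published.

Protein activities are produced by damped signed propagation over a
protein functional network: x ← tanh(λ·(W·x) + s), with W the
row-normalized signed adjacency (absolute row sums ≤ 1, so λ < 1 makes
the map a contraction and the iteration provably converges), s the
stimulus (target modulations plus comorbidity definitions as weak
persistent inputs, weight 0.25), λ = 0.9, tolerance 1e-6, at most 200
iterations. tanh keeps every activity strictly inside (−1, 1).

This propagation is a transparent surrogate for a proprietary
supervised-trained modeling technology. It reproduces the published
*interface and constraints* — bounded activities, ensembles of ≥ 50
solutions per patient, a training-set accuracy floor of 85% — not the
proprietary training, and no fidelity to the original published protein
lists is claimed.

One *solution* is one perturbed parametrization of the model: a Gaussian
perturbation vector added to the stimulus. Because the iteration is a
contraction with a unique fixed point, perturbing only the initial state
would wash out — persistent stimulus perturbation is what creates
genuine intra-patient variability, so that is what `sampleEnsemble()`
perturbs (SD 0.05 by default). Each candidate solution's accuracy is the
percentage of training relationships (drug, condition, expected tSignal
direction) its perturbed model reproduces; candidates below the floor
are rejected and counted, and sampling errors out with the best accuracy
seen if the budget (40 × ensemble size by default) is exhausted.

Efficacy is scored with tSignal = −(1/n)·Σ v_i y_i over a signed disease
definition (v_i = pathological sign, y_i = modeled activity): +1 means
complete reversion of the disease signature, −1 a fully expressed one.
Definition proteins absent from a solution contribute y_i = 0 and are
reported, keeping n fixed rather than silently renormalizing.

## Clinical outcome mapping

`trimDefinition()` optimizes a disease definition against clinical
efficacy records (ADHD-RS-IV change from baseline, pooled per drug by
plain averaging) by greedy backward elimination: repeatedly remove the
single protein whose removal most increases |Pearson ρ| between per-drug
mean tSignal and efficacy, stopping at an improvement below 1e-4 or at a
floor of 50% of the original definition. The original methodology does
not state its trimming algorithm; greedy elimination with a logged,
deterministically replayable trace (lexicographic tie-breaks) is this
package's choice — exhaustive subset search is exponential. Correlation
is computed on per-drug means, not per-trial points. Since improvement
is a negative score change and higher tSignal means more reversion, the
expected ρ is negative; a positive ρ raises a warning, not an error.
`fitEfficacyMapping()` then maps tSignal to the clinical scale by OLS.

## Analysis suite

**Sensitivity.** `localSensitivity()` is a one-at-a-time local sweep (the
original description invokes Sobol terminology but describes exactly
this): clamp one protein's activity to each of 21 grid points on
(−0.99, 0.99), re-propagate with the clamp held, and report the mean
absolute tSignal change as a percentage of the maximal possible
variation, taken as 2 minus the baseline tSignal. Proteins above 15% are
flagged as having real impact.

**Clustering.** Feature rows (final activities of the definition's
effector proteins, drugs pooled) are projected on 5 principal
components; k-means (25 restarts) runs for k = 2..7; candidates whose
smallest/largest cluster-size ratio falls below 0.05 are discarded (the
original "Silhouette index ratio" filter for unbalanced groups is
undefined in print; this size-ratio rule is our declared substitute);
the k maximizing mean silhouette wins, with mean bootstrap-Jaccard
stability (B = 100, greedy best-match over distinct resampled rows) as
the tie-break. Hopkins (power-d form, whose null distribution on
spatially uniform data is centered at 0.5) measures cluster tendency.

**Comparison.** `compareClusters()` runs a one-way ANOVA per variable
across clusters plus per-cluster two-sided t-tests against the pooled
rest, switching to Kruskal–Wallis/Mann–Whitney whenever any group has
fewer than 30 members, with Benjamini–Hochberg adjustment within each
variable's family.

## Sample-size estimation

`normalizeExpression()` applies TMM library-size normalization and a
log2-CPM transform (prior count 0.5) via edgeR — a declared stand-in for
the full published normalization workflow it abbreviates. The classifier
is a two-feature linear discriminant; features are chosen by a
univariate-t screen (6 candidates) followed by a best-pair search, both
re-run inside every cross-validation training fold so accuracy estimates
are not selection-biased. `maxAccuracy()` gives the ceiling on the full
data; `progressiveCurve()` draws, for every even total n from 8 to twice
the smallest cohort, 100 balanced subsets without replacement, estimates
accuracy by stratified 10-fold CV, fits a normal to the per-n
accuracies, and reports the one-sided lower quantiles (mean − 1.645·SD
at 95% power, mean − 2.326·SD at 99%) as a percentage of the ceiling.
`requiredSampleSize()` returns the smallest n whose power quantile
reaches the 85% threshold. Note the grid runs to twice the smallest
cohort: the published worked example (142 of 2 × 76 available samples at
99% power) requires per-cohort draws up to the full smallest cohort, so
"sample size" is the total across both cohorts.

## Synthetic data, and what passing tests do not show

Every generator in `synth*()` is a pure function of its arguments and
seed. `synthExpression()` plants a mean-shift effect in log-normal
counts; `synthNetworkWithDefinitions()` builds a connected random signed
network and chooses the disease definition so that drug 1 provably
reverses it (training accuracy 100 for the noiseless solution, positive
tSignal) with drug 2 its sign-mirror; `synthPKObservations()` generates
Bateman-curve datapoints with log-normal noise. These fixtures make
every pipeline stage testable offline, and the packaged demographic
references embed only published summary values.

What they do not emulate: real transcriptome covariance structure (the
expression generator is gene-independent), the topology and curation of
a real protein functional network, true growth-percentile data, or
published disease protein lists. Consequently the tests demonstrate that
the machinery is correct and its guarantees hold under controlled
conditions — not that the packaged defaults reproduce any published
molecular result (cluster counts, correlation values, model accuracies),
which depended on proprietary models and unprinted inputs.

## Numerical choices and problem sizes

Degenerate inputs are first-class: zero-variance references produce
populations pinned at the means; zero dose gives an all-zero profile;
flat PK observations, empty definitions, single-cluster labelings and
identical-row matrices raise typed errors rather than NaNs. Tie-breaks
are deterministic everywhere (lexicographic on protein ids; fixed
optimizer starting points), so identical inputs and seed reproduce every
result byte-for-byte, and a single trial seed fans out to per-stage
substreams.

The test suite and worked examples run at desk scale by design:
populations of 500 for the demographic checks, 50 patients for the
ensemble-gate check, networks of 40 proteins, expression fixtures of
about 30–40 samples per cohort, 100 progressive-sampling repetitions,
20–30 seeds for the Monte-Carlo properties. These sizes keep the full
suite in a few minutes while leaving every statistical check adequately
powered.

## Known limitations

- The propagation surrogate shares only its interface with the original
  supervised technology; ensemble tSignals have no claim to molecular
  fidelity.
- Clearance is blood-side; organ-extraction kinetics, enterohepatic
  recirculation, metabolites and transporter saturation are out of scope.
- EC50 values and disease definitions are user inputs; the package ships
  only synthetic stand-ins.
- The expression generator's independence across genes makes the
  sample-size module's task easier than real cohorts would be; treat the
  packaged curves as procedure demonstrations, not biological estimates.
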