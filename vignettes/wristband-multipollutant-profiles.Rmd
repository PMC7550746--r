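---
title: "Multipollutant exposure profiling from silicone wristband samplers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipollutant exposure profiling from silicone wristband samplers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposband)
```

## The measurement problem

Silicone wristbands are passive personal samplers: worn for about a week,
the silicone absorbs a broad range of organic chemicals from the wearer's
environment, and a GC-MS screen reports one concentration per chemical in
ng/g silicone. A single deployment yields a wide participant-by-chemical
matrix with three awkward properties that drive every design decision in
this package:

* **heavy left-censoring** — most of the >1,500 screened chemicals are
  below the quantitation limit in most wristbands, and non-detects arrive
  coded as concentration 0, not as a flagged missing value;
* **analytical batch effects** — wristbands are extracted and quantified
  in batches, and between-batch shifts are comparable in size to the
  biological signal for some chemicals;
* **skewness** — detected concentrations span orders of magnitude and are
  approximately lognormal.

`exposband` implements the analysis pipeline such a deployment needs:
detection-frequency screening, batch-median standardization, Spearman
correlation structure, repeated-measures reliability (ICC with bootstrap
intervals), multiply-imputed regression for exposure predictors, and
discovery of multipollutant exposure profiles with a batch
self-organizing map (SOM) whose size is chosen by a cluster-validity
consensus. A synthetic cohort generator with a recorded truth ledger
makes every stage testable by parameter recovery.

## Non-detects, screening, and standardization

Non-detects are kept as 0 throughout — in detection fractions, medians,
quartiles, standardization and all downstream models. We deliberately do
not substitute LOQ/√2 or fit censored likelihoods: the pipeline's summary
statistics then reproduce what a laboratory report with zero-coded
non-detects implies, and the (0, q3) interquartile ranges seen for
chemicals detected in 60–70% of samples are a faithful description, not
an artifact. Censored-likelihood modelling is out of scope by design.

Detection is `concentration > 0`. The screen retains chemicals whose
detection fraction **strictly exceeds** the threshold (default 0.60); a
chemical detected in exactly 58% of samples is excluded. The strictness
matters for reproducing published chemical counts and is tested at the
boundary.

Standardization removes batch effects before any multivariate analysis:
for chemical $c$ in batch $b$,

$$ v' = v - \mathrm{median}_b(c), \qquad
   z = \frac{v' - \bar{v'}}{\mathrm{sd}(v')} $$

with the mean and SD pooled over all samples in the fit. We use the
sample SD (denominator $n-1$), the convention of `scale()`; with a single
batch and values (1, 2, 3) the result is exactly (−1, 0, 1). The fitted
transform (per-batch medians, center, scale) is stored in the returned
`std_matrix`, and `apply_standardization()` reapplies it to later
samples, so a second-timepoint wristband can be expressed on the
first-timepoint scale. A chemical that is constant after batch
adjustment has no defined z-score and is refused by name rather than
silently dropped. Zeros participate in the batch medians: for a chemical
detected in under half of a batch the batch median is 0 and the
subtraction is a no-op, which is the intended behaviour.

Two properties pin the implementation down: per-chemical means within
1e-9 of 0 and SDs within 1e-9 of 1 after fitting, and exact invariance
(to 1e-9) when any constant is added to every sample of one batch.

## Repeated-measures reliability

A subsample wears a second wristband later in pregnancy. Per chemical we
fit the variance-components model

$$ y_{it} = \mu + \beta \cdot \mathrm{week}_t + u_i + e_{it}, \qquad
   u_i \sim (0, \sigma^2_b), \quad e_{it} \sim (0, \sigma^2_w), $$

with week fixed (so a cohort-wide shift between timepoints does not
count against reliability) and participant random. For the balanced
two-occasion design the REML solution has a closed form: with
within-pair differences $d_i$ and participant means $m_i$,

$$ \hat\sigma^2_w = \tfrac{1}{2}\mathrm{Var}(d_i), \qquad
   \hat\sigma^2_b = \mathrm{Var}(m_i) - \tfrac{1}{2}\hat\sigma^2_w, $$

truncated at 0, and
$\mathrm{ICC} = \hat\sigma^2_b / (\hat\sigma^2_b + \hat\sigma^2_w)$
(0 when both components vanish; the fit is flagged degenerate). The test
suite verifies the closed form against an iterative REML fit
(`nlme::lme`) to 1e-6 on balanced data; truncation means the two agree
whenever the iterative estimate is interior.

Confidence intervals are percentile bootstrap over participants —
resampling keeps both timepoints of a participant together, preserving
the within-person dependence, with 1000 resamples by default. Degenerate
resamples contribute ICC 0, and the interval is clamped to [0, 1]. We
chose percentile over BCa as the simplest method consistent with a
resampling description that names no refinement. Calibration is tested:
for true ICC 0.5 at 50 pairs, empirical 95% coverage over 200 simulated
cohorts must land in [90%, 98%].

Reliability classes use the conventional cutpoints: ICC ≤ 0.4 poor,
strictly between 0.4 and 0.75 fair to good, ≥ 0.75 excellent (the
boundary 0.75 belongs to excellent). Participants missing either
timepoint are excluded from the ICC rather than imputed.

## Missing covariates: chained equations and Rubin pooling

Questionnaire covariates arrive with appreciable missingness (the
bundled summary's reduced denominators imply roughly 30% for education,
28% for marital status, 31% for smoke exposure, and the generator
reproduces those rates). We impute with chained equations: predictive
mean matching (Bayesian parameter draw, 5 donors) for continuous
variables, a Bayesian logistic draw for binary factors, and polytomous
regression refit on a bootstrap resample (for parameter uncertainty) for
factors with more than two levels; 10 sweeps per dataset, m = 25
datasets by default. Observed cells are never altered, and a variable
more than 95% missing is refused rather than imputed from almost
nothing.

Per-imputation OLS fits are combined by Rubin's rules: pooled estimate
$\bar\beta$, within-variance $W$, between-variance $B$, total
$T = W + (1 + 1/m)B$, with Barnard–Rubin small-sample degrees of freedom
and t-based intervals. With zero missingness the whole machinery
collapses, exactly, onto the complete-data OLS (tested to 1e-10) — a
useful end-to-end identity because it rules out silent scale or df
errors anywhere in the chain.

One economy matters for the model suite: the covariates are imputed
**once per cohort** and the m completed tables are shared by every model
in the suite, with the (complete) total detection count included as an
auxiliary predictor. Since only covariates are ever missing here, this
is distributionally identical to imputing within each model and roughly
20 times cheaper. The suite fits, all with the same core adjustment set
(age, BMI, education, marital status, race/ethnicity, parity, smoke
exposure, gestational age at start, season of wear; references: lowest
education, married, White non-Hispanic, parity 0, no smoke exposure,
fall): the total-detects predictor model, the six a-priori
exposure-chemical hypotheses (nail polish, handwashing, gardening,
parity, season), and a per-chemical season model for every retained
chemical. Concentration outcomes are the standardized values, so those
betas are in SD units. A hypothesis whose target chemical fell below the
detection screen is skipped with a warning rather than silently fit to
noise, mirroring how such hypotheses become untestable in practice. No
multiplicity adjustment is applied; the output is a table of individual
estimates with intervals, to be read as such.

## SOM exposure profiles

Participants are clustered on their standardized concentration vectors
with a batch self-organizing map on a rectangular grid: each epoch
assigns every sample to its best-matching unit (nearest codebook vector,
Euclidean distance) and replaces every codebook vector by the
Gaussian-neighborhood-weighted mean of the samples, the radius decaying
linearly from `max(rows, cols)/2` to 0 over 100 epochs. Batch (rather
than online) training makes the fit deterministic given a seed and
order-invariant: the initial codebook is drawn from the
lexicographically sorted data rows, so permuting the input changes
nothing but the order of the assignment vector (a tested invariant). At
radius 0 the update is exactly Lloyd's k-means step on the grid nodes,
and the final fit's within-cluster sum of squares is required (tested)
to be within 5% of a multi-start k-means on the planted benchmark.

Two numerical behaviours are worth knowing. Ties in the best-matching
unit go to the lowest node index (distances are rounded at 1e-12 so
floating-point noise cannot hide an exact tie). And a map with as many
nodes as well-separated points reproduces the points exactly only when
the neighborhood starts tight; with a wide initial radius the
mid-training smoothing can collapse two codebooks onto one cluster and
strand a dead unit — ordinary SOM behaviour, which is why empty nodes
are tolerated everywhere downstream and statistics are computed on
occupied profiles only.

Map size is chosen by consensus over five internal validity statistics,
computed on the occupied-profile assignment of one fit per candidate
grid (all shapes $r \le c$ with $4 \le rc \le 25$, sharing one seed):

* WSS/BSS — within- over between-cluster sum of squares (lower better);
* Calinski–Harabasz, $\dfrac{\mathrm{BSS}/(k-1)}{\mathrm{WSS}/(n-k)}$;
* Dunn — minimum single-linkage inter-cluster distance over maximum
  intra-cluster diameter (0 when two clusters touch);
* mean silhouette, singletons contributing 0;
* Pearson Gamma — correlation between the pairwise-distance vector and
  the different-cluster indicator.

Each statistic ranks the candidates; the minimum mean rank wins, ties
preferring fewer profiles and then the shape closest to square.
"Most agreement across cluster statistics" admits several readings;
minimum mean rank is this package's operationalization, the full
statistic-by-statistic table is always reported so any other rule can be
applied to it, and both the nominal node count and the occupied count
are reported because a map's advertised size and its effective number of
profiles can differ. All five statistics are verified against
brute-force pairwise oracles to 1e-9, including a four-point instance
whose values (WSS/BSS = 0.01, CH = 200, Dunn = 9) can be checked by
hand.

Profiles are characterized by membership count, per-chemical median
standardized concentration, and "exceptional" chemicals — profile median
at least 1 SD above the cohort mean, a reporting convention of this
package, not an inferential claim. Profiles with fewer than 10 members
are listed as rare and excluded from the covariate panel.

## The synthetic cohort generator

`sim_config()` defaults encode the deployment the package was written
around: 255 participants, 40 chemicals of which the 17 most frequently
detected carry the published names, detection percentages, concentration
medians and ICCs bundled in `frequent_chemicals()`, 3 batches, and a
20-participant two-timepoint subsample. Log10 concentrations are
Gaussian around a per-chemical mean with SD 0.6 (consistent with the
published interquartile ratios), shifted by latent profile membership, a
per-(batch, chemical) effect (SD 0.1), and planted covariate effects;
the quantitation limit is back-computed as
$\mathrm{loq} = 10^{\mu - \sigma \Phi^{-1}(\mathrm{det})}$ so each
chemical's expected detection fraction equals its published target, and
values below it are recorded as 0. The default latent structure is one
dominant low-exposure profile (62%) plus four small profiles elevated
0.9 log10 units on one or two named chemicals, mirroring the shape of
the published profile map; default planted effects include a positive
nail-polish shift on triphenyl phosphate and diethyl phthalate, a summer
elevation of benzophenone, and seasonal/education deficits spread across
the background chemicals so the total-detects model has signal to find.
The repeated-measures generator uses the variance-components model above
with per-chemical $(\sigma^2_b, \sigma^2_w)$ splitting the log-scale
variance according to the published ICCs, plus a +0.2 log10 week effect
(second-timepoint medians run higher). The truth ledger records profile
labels, true ICCs and planted effects, and everything is byte-identical
under a fixed config and seed.

What the generator does **not** emulate — and therefore what passing
recovery tests do not certify about real data: chemicals are
conditionally independent given profile and batch (no shared-source
correlation beyond the planted structure, whereas real wristband
chemicals show correlated fragrance/phthalate blocks); missingness is
MCAR at fixed rates, not behaviourally patterned; quantitation limits
are fixed per chemical rather than varying by batch; and noise is
i.i.d. lognormal with a common spread.

One scale subtlety deserves emphasis. Effects are planted on the log10
scale, but the pipeline (like the published analysis) standardizes
**raw** concentrations. For the default spread (0.6 log10 units) the raw
scale is heavy-tailed, so a planted log-scale effect appears attenuated
and noisy in raw-SD units; recovery tests for regression effects
therefore check sign and coverage rather than exact magnitude, and the
SOM planted-profile benchmark uses a modest spread (0.15 log10 units) so
that its "±3 SD" separation survives into the analyzed feature space.
This is the package's own benchmark design choice; with wide lognormal
spread, profile structure planted on the log scale is genuinely not
recoverable from raw-scale z-scores, which is worth knowing when
interpreting profile analyses of skewed concentration data.

## Problem sizes and runtimes

The test suite and the acceptance script size their simulations to run
comfortably on a single CPU: the full default pipeline (255 × 40, 25
imputations, 43 candidate SOM grids, 1000-resample bootstrap) completes
in well under a minute; the planted-profile recovery study uses 20
cohorts of 200 participants; ICC recovery uses 20 cohorts of 500 pairs
plus 200 bootstrap-calibration cohorts of 50 pairs. Determinism is
checked by running the full default pipeline twice and comparing every
output file byte for byte.

## Open decisions, resolved

* **Season of wear** is not defined in the source material; we use
  meteorological seasons (Dec–Feb winter, and so on) of the wristband
  **start** date. Wear periods are ~7 days, so start-date versus
  majority-of-days changes at most a sliver of boundary cases; the
  `season` column can be supplied explicitly to override.
* **Standardization fit set**: the transform is fit on first-timepoint
  samples and reapplied to later samples via the stored parameters; a
  batch unseen in the fit falls back to the cross-batch median with a
  warning.
* **ICC input scale**: batch-standardized concentrations, with no
  additional log step, matching the stated transform of the reliability
  table the package reproduces.
* **SOM consensus rule** and **occupied-versus-nominal profile counts**:
  both interpretations are surfaced in the `som_selection` report rather
  than hidden.

## Limitations

The package analyzes zero-coded concentrations as given: it does not
model the censoring mechanism, does not background-correct (assumed done
upstream), and treats detection counts as continuous outcomes in OLS
rather than count GLMs — deliberate fidelity choices, each of which a
methodological successor might revisit. Profile discovery is
descriptive, and the validity consensus should be read with care on weak
structure: when real clusters are planted and separated, the consensus
recovers them sharply (the benchmark selects 4 occupied profiles with
adjusted Rand index 1), but on structureless data the five statistics
disagree systematically — WSS/BSS and Pearson Gamma improve
monotonically with more clusters while Calinski–Harabasz and Dunn prefer
coarse partitions — so the minimum mean rank drifts to mid-sized or
large maps rather than collapsing to the smallest candidate. A small
selected map is therefore evidence of structure; a large one is not, by
itself, and the per-statistic report should be consulted. Profile
membership carries no uncertainty quantification.
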