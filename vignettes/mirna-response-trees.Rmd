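---
title: "Blood miRNA decision trees for FCR response in B-CLL: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood miRNA decision trees for FCR response in B-CLL: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtree)
```

## The problem

Fludarabine–cyclophosphamide–rituximab (FCR) chemo-immunotherapy cures a
fraction of B-cell chronic lymphocytic leukemia (B-CLL) patients in the
sense that matters clinically: complete remission (CR) with minimal
residual disease undetectable in bone marrow (BM uMRD, fewer than one CLL
cell per 10,000 leukocytes by flow cytometry). Whether a treatment-naive
patient will reach that state is unknown at diagnosis, yet it is exactly
the information a clinician needs before exposing a patient to
chemotherapy toxicity. `mirtree` implements a blood-based prediction
pipeline built around circulating microRNA (miRNA) levels measured by
qPCR before treatment:

1. a **discovery screen** comparing a 384-assay TaqMan low-density array
   (TLDA) between a handful of responders and non-responders;
2. **univariate association** of a validated miRNA panel with four
   response outcomes (CR, blood uMRD, BM uMRD, CR + BM uMRD), plus
   backward-selection logistic regression for the multivariate view;
3. a **recursive decision tree** that dichotomises miRNAs at
   Youden-optimal ROC cutpoints and splits on the most significant
   variable until nothing is significant;
4. **survival analysis** (Kaplan–Meier, log-rank, Cox, landmark) of the
   tree-defined prognostic groups;
5. **cohort accounting** that reproduces printed-style response rates
   with outcome-specific evaluable denominators.

Because the underlying patient-level data are not publicly deposited,
every algorithmic stage is verified against a synthetic cohort generator
with planted ground truth rather than against the original measurements.

## Screening statistics

Raw threshold cycles $Ct$ are normalised per sample. The default is
global-mean normalisation, $\Delta Ct_{ij} = Ct_{ij} - \overline{Ct}_{i\cdot}$
(mean over the sample's detected assays), the standard choice for TLDA
cards where no single endogenous control is trusted; a reference-assay
mode is available. Relative expression is $2^{-\Delta Ct}$.

The group contrast per assay is the **geometric-mean fold change**
$\mathrm{FC} = \mathrm{geo}(x_R)/\mathrm{geo}(x_N) = 2^{\overline{\Delta Ct}_N - \overline{\Delta Ct}_R}$,
reported responder-over-other, with a two-sample Student $t$ test on
$\Delta Ct$ (the log domain) by default. Assays are categorised *up*
($\mathrm{FC} \ge 2.5$, $p < 0.05$), *down*
($\mathrm{FC} \le 1/2.5$, $p < 0.05$) or *not significant*; raw p-values
drive the categories, as in the original discovery design, and a
Benjamini–Hochberg column is carried along for users who want it. The
detection filter marks assays whose mean raw Ct is not strictly below 30
cycles in **both** arms: one-sided undetectability would otherwise
inflate a fold change, and the strict inequality follows the stated
"<30 cycles" rule. Note that with global-mean normalisation a planted
shift is slightly attenuated (by `shift/n_assays` cycles, spread over the
normaliser); the reference-assay mode has no such attenuation.

Whether the original screen tested $\Delta Ct$ or $2^{-\Delta Ct}$ is
not documented; we test $\Delta Ct$, where the $t$ test's normality
assumption is far more plausible. `test = "auto"` replaces the fixed $t$
test with the Shapiro–Wilk-gated rule below.

## Univariate and multivariate association

`compare_groups()` applies the Shapiro–Wilk test per group at
$\alpha = 0.05$; Student's $t$ (pooled variance) is used only when both
groups pass, otherwise Mann–Whitney. Groups of fewer than three fall
through to Mann–Whitney, and groups larger than the Shapiro–Wilk ceiling
of 5000 are gated on a deterministic evenly-spaced subsample.
Categorical associations use Fisher's exact test when any expected cell
count is 5 or less, else the uncorrected chi-square; Spearman's
correlation handles numeric pairs.

`backward_logistic()` fits a binomial GLM and removes the least
significant term (Wald; single-coefficient $z$, multi-level factors as a
joint Wald chi-square) until all retained terms satisfy $p <$
`alpha_stay`. Odds ratios carry Wald 95% intervals. Quasi-separated
coefficients are flagged instead of reported: a fitted number from a
divergent likelihood is worse than an honest marker. `alpha_stay = 1`
returns the full model and `alpha_stay = 0` the empty model, which the
test suite checks as boundary identities.

## ROC construction and the Youden cutpoint

`roc_curve()` enumerates thresholds at the midpoints between consecutive
sorted unique marker values, plus $\pm\infty$ sentinels. Under the
default *high-positive* orientation a value strictly greater than the
threshold is called positive, so sensitivity is non-increasing in the
threshold; AUC is the trapezoidal area, which equals the tie-corrected
Mann–Whitney statistic. The Youden cutpoint maximises
$J = Se + Sp - 1$; ties are broken towards the smallest threshold, which
favours sensitivity for high-predicts-response markers. This tie rule,
like the strictly-greater routing rule, exists because determinism is
mandatory, not because the choice is scientifically forced.

Orientation matters more than it may appear: one of the five tree
miRNAs (miR-412) predicts response when *low* (its screening fold change
is 0.3). Node-local cutpoints in the tree are therefore selected with
`orientation = "auto"` (the direction with AUC at least 0.5), while the
split itself always routes by expression level so that the H/L letters
in group labels keep their meaning of high/low expression.

## The decision tree

The root variable is fixed by the user (default miR-125b, the
rationale-driven choice in the motivating study: it was the only panel
miRNA predictive of blood uMRD, and blood-MRD-detectable patients with
BM uMRD do not occur); an `"auto"` mode picks the most significant
candidate instead. The root always splits at its cohort-level Youden
cutpoint. At every other node, each candidate miRNA unused on the path
is scored by the `compare_groups()` p-value of its expression between
responders and others *within the node*; if the smallest p-value is
below `alpha` (default 0.05) and both prospective children would keep at
least `min_leaf` patients (default 5), the node splits on the arg-min
variable at its node-local Youden threshold. Otherwise the node becomes
a leaf whose empirical responder fraction is the reported response
probability. Ties on p go to the larger AUC, then the lexicographically
smaller id. `max_depth` (default 4) guards against degenerate recursion
that a 100-patient cohort would never reach.

Thresholds are node-local by design: the procedure recomputes the ROC on
each node's patients, and since a variable is consumed along its path,
each miRNA still ends up with a single threshold, consistent with a
one-threshold-per-miRNA published table.

Two consequences of the $\alpha$-level stopping rule deserve honesty.
First, under the null it will split spuriously at rate $\approx \alpha$
per candidate per node, so on large synthetic cohorts the builder
sometimes grows an extra level below the planted leaves; the
recovery metric in the tests therefore asks whether every planted split
variable appears at its planted position with an accurate threshold, not
whether the tree stops exactly there. Second, leaf probabilities are
training-cohort empirical fractions with no shrinkage or
cross-validation — exactly what the original procedure reports, and
exactly why they should be read as descriptive, not as calibrated
out-of-sample probabilities.

`published_tree()` ships the reported tree as a fixture: topology
(root miR-125b; high branch miR-15b then miR-181c / miR-412; low branch
miR-193b), the five thresholds (0.0005, 0.1710, 0.0019, 0.0003, 0.0113
relative expression), and the two published leaf probabilities
(HHH 0.72, LL 0.04). The four remaining leaf probabilities were
published only graphically; the fixture stores artifact placeholders
(HHL 0.50, HLL 0.35, LH 0.20, HLH 0.10) marked
`prob_source = "placeholder"`, ordered consistently with the published
PFS tiers. Cohort counts per node were never published, so the
fixture's count fields are `NA` and count-conservation checks skip them.

## Survival analysis

Kaplan–Meier, log-rank and Cox estimation are delegated to the
`survival` package behind this module's interface, with Breslow tie
handling so that the test suite's grid-search partial-likelihood oracle
is an exact check. The median is the smallest $t$ with
$S(t) \le 0.5$ and is reported as a distinguished "not reached" value,
never as a number. Fixed-time readouts use the $S(t^-)$ step value with
Greenwood standard errors available. `landmark_filter()` drops subjects
whose follow-up ends before the landmark and resets the clock; the
motivating study's landmark is the MRD assessment time (9 months from
treatment start, equivalently 3 months after treatment end), and the
code takes the number explicitly. The published three-tier grouping
maps HHH to the high-PFS tier, HHL/HLL/LH to the intermediate tier and
HLH/LL to the low tier.

## Cohort accounting

`classify_response()` encodes the evaluable-denominator logic: a
responder is CR with BM uMRD; a no-CR patient is a non-responder even
with missing BM data (no-CR suffices); a CR patient with missing BM data
is unclassifiable. One denominator subtlety is reproduced deliberately:
printed CR percentages in the reference cohort use the full cohort as
denominator (65/123 = 52.85%) even though five patients have missing CR
status, while MRD percentages use evaluable counts (69/108, 40/95) and
responder percentages use classifiable counts (27/107). The package
follows the printed arithmetic and `reference_clinical_table()` ships a
synthetic 123-patient table whose margins reproduce every printed count;
only the margins are faithful — the patient-level rows are a
deterministic reconstruction. Percentages round half-up to two decimals
(`rate()`), the rule under which every printed percentage reproduces
exactly; quartiles use type-7 linear interpolation, configurable because
printed IQRs cannot adjudicate the method.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with full planted truth:

* **Expression** is log-normal per miRNA. The five tree miRNAs are
  centred so that their marginal medians equal the published thresholds
  (`sdlog` 1.5, a realistic qPCR spread of about two orders of magnitude
  across patients), which makes median-quantile planted splits
  recoverable at the published values. Panel miRNAs outside the tree
  default to independent noise; optional per-leaf log-scale shifts let
  tests plant associations on them.
* **True leaf** is each patient's own expression routed through the
  planted tree — the tree is the data-generating truth, not a label
  applied afterwards.
* **Outcome** is Bernoulli with the leaf probability (0.72 and 0.04 for
  HHH/LL as published; 0.50/0.35/0.20/0.10 artifact defaults for the
  figure-only leaves). CR / blood-MRD / BM-MRD labels are derived so
  that responder is exactly CR with BM uMRD, and the configuration never
  produces a blood-detectable, BM-undetectable patient. Non-responder
  label frequencies (BM uMRD 0.16, CR-given-BM-detectable 0.40, blood
  uMRD 0.43) are chosen once to approximate the printed marginal rates.
* **Survival** is exponential per leaf with administrative censoring at
  42.4 months (the median follow-up); hazards derive from the published
  42.4-month PFS per group (HHL 72%, HLH 71%, HLL 90%, LH 87%, LL 52%),
  with the no-relapse HHH group at 99% so its hazard stays positive.
* **Missingness** is independent per outcome (CR 0.04, blood MRD 0.12,
  BM MRD 0.23), approximating the distinct evaluable denominators
  118/108/95 out of 123.
* One RNG stream is consumed in a documented order (expression, then
  outcomes, then survival, then covariates, then missingness), so equal
  seeds give identical cohorts.

What the generator does **not** emulate: correlated miRNAs (real qPCR
panels are strongly co-regulated), measurement error and batch effects,
informative censoring, covariate–outcome associations (baseline
covariates are independent of response by default, so the generator
cannot be used to validate the multivariate covariate findings), and
non-exponential hazards. Passing tests therefore demonstrate that the
*algorithms* are correct under the assumed structure, not that the
clinical findings generalise.

`generate_screen()` plants the 25 published screening fold changes (or
any user set) as cycle shifts in the responder arm of a 2x8-sample,
384-assay Ct matrix with within-group SD 0.5 cycles, baseline locations
N(26, 2), and undetermined wells stored at the 40-cycle ceiling.

## Verification scale and numerical choices

The test suite verifies each stage against an independent oracle:
exhaustive cutpoint enumeration for ROC/Youden (1000 random instances,
n at most 12), hand product-limit and O-E/V computations for KM and
log-rank, a grid-search Breslow partial-likelihood maximiser for Cox
(agreement to 1e-4), an exact permutation oracle for Spearman (n = 6),
and hypergeometric enumeration for Fisher. Simulation-based checks use
the planted-truth generator: topology recovery over 20 seeds at
n = 2000, screening calibration over 100 null seeds of 384 assays at
8 vs 8, hazard-ratio recovery at n = 2000, and logistic selection
consistency at n = 500. These sizes were chosen to keep each
simulation's Monte-Carlo error well inside the asserted tolerance while
the whole suite runs in a few minutes on one core. Fold-change oracle
agreement is asserted at 1e-12 relative; JSON tree round-trips at 1e-12
(serialisation is one ulp short of bit-exact).

## Known limitations

* The published thresholds and leaf probabilities cannot be recomputed
  (no deposited patient-level qPCR data); they live in a clearly-marked
  fixture, and four of six leaf probabilities in it are placeholders.
* The screening module does not model amplification efficiency or
  undetermined-well imputation beyond the 40-cycle convention.
* The tree has no pruning or cross-validation by design fidelity;
  out-of-sample probability calibration is out of scope.
* Clinical covariates can compete as tree candidates only through their
  expression-like numeric encoding; the motivating analysis offered
  covariates to the tree but selected only miRNAs.
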