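---
title: "Phenotype risk scores with phescore: model, evaluation, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype risk scores with phescore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phescore)
```

## The problem

A phenotype risk score (PheRS) asks how closely a patient's diagnosis
history matches the clinical signature of a Mendelian disease, using only
ICD-coded EHR data. The founding intuition is that Mendelian
manifestations are rare in the general patient population, so their
co-occurrence is informative. That intuition strains for adult-onset
cardiovascular conditions such as variant transthyretin amyloidosis:
their manifestations — heart failure, atrial fibrillation, carpal tunnel
syndrome, polyneuropathy — are individually common, the causal variants
are incompletely penetrant, and penetrance concentrates late in life.
`phescore` is built for that regime. It separates three concerns that are
often conflated: the *feature definition* (an expert-curated map from
phenotypes to ICD code groups, swappable for a phecode-style map), the
*weighting scheme* (log inverse frequency in an independent reference
population), and the *evaluation target* (top-k prioritization yield
rather than population-wide separation).

## The score

Feature $p$ is present for patient $i$ ($x_{ip} = 1$) iff at least one of
its (version, code) pairs occurs anywhere in the record. Presence is
lifetime: the rule is "at least one occurrence", with no time window, so
duplicate and repeated diagnoses collapse. With presence count $c_p$
among $n$ training patients and symmetric pseudocount $a$,

$$f_p = \frac{c_p + a}{n + 2a}, \qquad w_p = \log\frac{1}{f_p}, \qquad
\mathrm{PheRS}_i = \sum_p w_p\, x_{ip}.$$

Assumptions worth stating: features contribute additively (no
interactions); the training population's feature frequencies are the
relevant reference for rarity; and the code groups are clinically
meaningful partitions (by default the package enforces that no code
belongs to two features, with an explicit override that logs overlaps,
since curated maps occasionally overlap on purpose).

Three variants share the arithmetic:

* **standard** — the sum above; a patient with no present features scores
  exactly 0.
* **negative_weights** — adds $\log(1 - f_p)$ for every absent feature.
  The absence of a *common* disease feature is stronger evidence against
  the disease than the absence of a rare one, and this is the natural
  frequency-based penalty with that shape. It is documented as an
  interpretation: external PheRS implementations offer a negative-weight
  mode without a published formula, and no bit-compatibility with them is
  claimed. It requires $f_p < 1$ and therefore a frequency column.
* **precomputed** — identical arithmetic with an imported weight table,
  for testing cross-health-system generalizability. Frequencies are
  optional on import; without them the negative-weights variant is
  refused with an explicit error rather than silently approximated.

Any feature can be excluded at scoring time; excluded features contribute
nothing under any variant. This powers the anti-circularity analysis:
deploy among heart-failure patients, but score without the heart-failure
feature. A property test verifies the exclusion is leak-proof: permuting
all diagnosis events of an excluded feature across patients changes no
score.

### Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pseudocount` | 0.5 | patients | Keeps zero-count features finite. Rare curated features are exactly the informative ones, so dropping them would be self-defeating; the symmetric Jeffreys-style correction biases $f_p$ toward $1/2$ by at most $a/n$. With `pseudocount = 0` a zero-count feature is an error, not an `Inf`. |
| `log_base` | $e$ | — | The base rescales all weights by one constant, so rankings, AUC and precision-at-k are invariant to it; natural log is the analysis-friendly default. |
| `variant` | standard | — | See above. |
| `excluded_features` | none | feature ids | Anti-circularity / sensitivity analyses. |

Weights are fit on the training cohort only — the patients whose genotype
is *unknown* — never on the genotyped cases and controls that will be
scored. This mirrors the genotype-first cohort design and prevents label
leakage through the frequencies.

## Cohorts and deployment strata

`assign_roles()` maps genotype status to roles: carrier → case,
confirmed non-carrier → control, unknown → training. Stratification
restricts deployment to where the score should work: minimum age at last
diagnosis (calendar-year arithmetic, because only year of birth is
ingested; patients with no diagnoses fail age strata rather than
erroring, since genotyped patients without ICD data are a normal
biobank occurrence), exact-match race/ethnicity labels (verbatim EHR
strings; the package does not guess at label normalization), and feature
history (at least one occurrence of a sentinel feature, read from the
presence matrix). Filters are independent set restrictions, so they
compose as intersections, are order-independent, and are idempotent —
each of which is property-tested. `subsample_training()` supports
training-size sweeps with a fixed seed.

## Evaluation

* **Wilcoxon rank-sum** (two-sided by default; sidedness is
  configurable): exact null when the pooled sample has at most 12
  untied observations, tie-corrected normal approximation with
  continuity correction otherwise. When every pooled score is identical
  the test statistic has zero variance; the package returns $p = 1$ (no
  separation) rather than `NaN`. Caveat baked into the report: with
  ~1:75 case-control imbalance, tiny p-values coexist with nearly
  overlapping score distributions, which is precisely why the package
  does not stop here.
* **AUC** via the Mann–Whitney rank identity, ties counted one half;
  tested to agree with brute-force pair counting to $10^{-12}$.
* **Precision-at-k** with deterministic tie handling. With $A$ the
  patients strictly above the $k$-th order statistic, $T$ the tie group
  at it, and $m = k - |A|$ slots to fill: the default *expected* policy
  returns $(\mathrm{cases}(A) + m\,\mathrm{cases}(T)/|T|)/k$, the exact
  mean over all tie-break orders (verified against enumeration), so
  results are reproducible without a tie-breaking seed. *pessimistic*
  and *optimistic* bracket it, and the bracketing is property-tested.
  At $k = n$ every policy returns the case prevalence exactly — the
  curve's anchored endpoint.
* **k grid**: steps of 10 in [10, 100], steps of 100 in [100, 1000],
  then three points per decade ($10^{1/3}$ spacing) up to the cohort
  size, which always terminates the grid. The sub-1000 region is where
  prioritization is actionable; the log tail exists to show convergence
  to the prevalence baseline cheaply.
* **Random baseline**: the expected precision of prevalence-based random
  assignment at any k is the case fraction; every curve is reported
  against it.

## The synthetic cohort generator

The generator produces the *statistical structure* the analysis assumes,
not realistic medicine. Per patient: carrier $\sim$
Bernoulli($\pi$); age $\sim$ Normal(`age_mean`, `age_sd`) truncated to
[18, 100] by resampling; feature presence $\sim$ Bernoulli with
$\mathrm{odds} = \mathrm{baseline\ odds} \times \mathrm{OR}_p$ when the
patient is a carrier *and* the age gate is open, baseline odds otherwise;
each present feature emits $1 + \mathrm{Poisson}(\lambda)$ events with
codes uniform over the feature's group and dates uniform over the
patient's adult years. Everything is deterministic given the seed.

Design choices made once:

* **Hard age gate at the onset age** (default 60): the simplest model
  consistent with a variant that manifests predominantly in older
  adults. A smooth alternative is available (`onset_ramp_years > 0`
  replaces the step with a logistic ramp on the log odds ratio) but the
  step is the default because no empirical ramp shape is available to
  calibrate against.
* **Fixed reference year** (2024) converts simulated age to birth year,
  so `age_at_last_diagnosis()` round-trips through the demographics
  table.
* **Race/ethnicity labels** are sampled from a configurable categorical
  distribution purely so stratification code paths execute; no
  demographic realism is claimed, and the labels deliberately reuse the
  coarse verbatim style of EHR extracts.
* **The ATTRv-like preset** fixes carrier prevalence 0.013 and onset 60
  (the magnitudes of the motivating disease), cohort age 65 ± 17 years,
  a 50% confirmed-non-carrier fraction among non-carriers (so roughly
  half the cohort forms the training pool, echoing a biobank whose
  genotyped case/control set and leftover training cohort are of the
  same order), and 21 features over 292 fabricated codes — common
  nonspecific features (heart-failure-like baseline 0.20) down to rare
  specific ones (baseline 0.01), with carrier odds ratios of 3–8,
  larger for the more specific features. Codes are synthetic strings
  with no ICD semantics; the preset is a structural stand-in for a
  curated clinical map, not a clinical artifact.

What the simulator does **not** model — and therefore what passing tests
do not demonstrate about real data: coding-intensity and utilization
confounding (sicker patients accumulate more codes of every kind),
longitudinal disease progression, correlated features, informative
missingness beyond never-present features, miscoding, and secular drift
between ICD-9 and ICD-10 eras. Results on real cohorts will be worse and
differently shaped; the simulator's job is to make the machinery
falsifiable, not to forecast clinical yield.

## Numerical and degenerate-input conventions

ICD codes are compared only as (trimmed, uppercased, dot-stripped
string, version) pairs; hierarchy descent is string-prefix match within
a version against a user-supplied code catalog, reproducing dot-hierarchy
semantics without bundling licensed ICD tables. Empty-after-trim codes,
non-{9,10} versions, unparseable dates, duplicate patient ids and
out-of-range birth years are validation errors naming the offending rows.
Duplicate diagnosis rows are legal and retained at ingestion (lossless),
collapsing only in the presence rule. A seed code absent from the catalog
contributes only its descendants, with a warning when it contributes
nothing. Exclusion of codes not present in a map is a no-op; a feature
whose every code is excluded is dropped with a warning.

## Test scale

The suite exercises the estimators at sizes chosen to make the
statistical assertions sharp while keeping a laptop run comfortable:
oracle equivalences at pooled $n \le 200$ (AUC), tie groups $\le 6$
(precision enumeration) and $n \le 10$ (Wilcoxon permutation); null
calibration over 1,000 zero-effect cohorts of 200 patients (rejection
rate within the 99% binomial interval of 0.05, mean AUC in
[0.48, 0.52]); signal recovery on five 35,000-patient preset cohorts
(AUC > 0.5 and precision-at-100 above the 0.013 baseline in every seed,
with and without the heart-failure-like feature); and weight recovery at
$n_{\mathrm{train}} = 50{,}000$, where the batch-mean fitted weight over
ten seeds must sit within 0.05 of $\ln(1/f^*)$ for all features with
$f^* \ge 0.01$ (the batch mean is the right unit because the single-draw
sampling SD at $f^* = 0.01$ is itself $\approx 0.045$).

## Known limitations

No ICD-9↔ICD-10 crosswalk (codes are identifiers within a version); no
FHIR/OMOP connectors; no phecode-map construction (supply one as a
feature map); no regression-based reweighting or per-code weights; no
DeLong confidence intervals for AUC; and the negative-weights penalty is
one defensible formula among several, configurable but not canonical.
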