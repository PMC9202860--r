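---
title: "Methods: nomogram decision support and adherence auditing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nomogram decision support and adherence auditing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilinorm)
```

This vignette documents the models, conventions and design choices behind
`bilinorm`: what is computed, which parameters matter, what the synthetic
cohorts do and do not emulate, and where the design was genuinely open.

## The decision model

Treatment of neonatal hyperbilirubinemia hinges on whether the total serum
bilirubin (TSB) crosses an age-dependent threshold. The package represents
each threshold as a piecewise-linear curve of TSB (mg/dL) against postnatal
age in hours, with two curves (phototherapy, exchange transfusion) per risk
class (with/without risk factors) per stratum. There are five strata: a
term/near-term nomogram for gestational age (GA) ≥ 35 weeks, and four
birth-weight bands for preterm infants (≤1000, 1001–1499, 1500–1999,
>1999 g). Birth weight, not GA, stratifies the preterm curves because GA
dating is frequently unreliable in the settings this workflow targets.

The advice rule is a three-tier threshold comparison at the infant's exact
postnatal age: TSB at or above the exchange threshold advises immediate
intensive phototherapy with exchange transfusion considered; at or above
the phototherapy threshold, phototherapy; otherwise no treatment.

Three boundary conventions are deliberate and documented:

- **Threshold equality triggers treatment** (`TSB ≥ threshold`). The
  clinical sources are silent on exact equality; treating at the boundary
  is the conservative reading, and it is applied consistently in both the
  decision engine and the audit.
- **GA exactly 35.0 weeks uses the term nomogram.** Descriptions phrased as
  ">35 weeks" versus "<35 weeks" leave 35.0 ambiguous; assigning it to the
  term curve keeps the strata a partition.
- **No extrapolation beyond the knot range** — queries clamp to the
  terminal knot values. Clamping is deterministic and avoids inventing
  thresholds outside the curves' support; the shipped curves span 0–120 h
  and older infants are assessed at the 120-h plateau.

Bilirubin in µmol/L is converted by division by 17.1 (molar mass of
bilirubin); this factor is fixed, not configurable, because it is a
physical constant.

### The shipped threshold table is a placeholder

The national guideline that motivates this workflow does not publish its
numeric curves in citable form, so threshold tables live in versioned YAML
files and the packaged default (`guideline_default.yaml`, version
`0.1.0-synthetic`) is a synthetic stand-in: a term curve shaped like the
AAP-2004-style nomogram such guidelines adapt, and age-ramped preterm band
curves that decrease with birth weight and with risk factors. The file and
its documentation label it as synthetic. Every structural invariant is
enforced at load time on a dense age grid: the exchange curve never falls
below the phototherapy curve within a risk class, and with-risk thresholds
never exceed no-risk thresholds. One functional constraint was imposed on
the placeholder: the package's clinical worked example (33-week, 2100-g
infant at 48 h with ABO incompatibility and TSB 17.2 mg/dL) must route to
the intensive tier, so the `gt_1999` with-risk exchange threshold at 48 h
(15 mg/dL) sits below 17.2. Conclusions about the decision logic transfer
to any valid table; conclusions about specific thresholds do not.

An open question in the sources is whether the preterm curves differ by
risk class or merely shift; the package gives every stratum four
independent curves, which subsumes both readings.

### Risk factors

The named risk factors are ABO/Rh incompatibility, haemolysis (G6PD
deficiency, spherocytosis), other illness (asphyxia, infection) and
hypoalbuminemia. An explicit "no risk factors" declaration selects the
no-risk curves; *unknown* risk status is treated as having risk factors —
when the factors cannot be checked, the lower (safer) thresholds apply.
The hypoalbuminemia cut-off is stored verbatim from the source material as
30 mg/L (`hypoalbuminemia_cutoff`); the conventional unit for such a
cut-off is g/L and the printed unit is very likely a typo, but the package
does not silently correct source values — the constant is documented and
the engine itself only consumes a boolean flag.

## Neurology scores

The BIND-M score sums four examination items; the KSD risk score sums
seven components. The category bands (BIND-M: 0 / 1–4 / 5–6 / >6; KSD:
0–2 / 3–5 / 6–9 / 10–14) are fixed, published cut-offs and are hard-coded.
The per-item point rubrics, by contrast, vary between site adaptations and
are configurable: the defaults (BIND-M maxima 3/3/2/1; KSD maxima
3/1/3/3/1/1/2, summing to 14) are package conventions chosen to match the
published score ranges, and classification depends only on the total, so
any rubric with the same totals yields the same bands.

## The adherence audit

Each chart record carries the administered treatment; the audit recomputes
the indicated treatment and classifies:

1. phototherapy given without any TSB measurement → **inappropriate**
   (checked first: without a measurement the threshold comparison is
   meaningless);
2. no measurement and no phototherapy → **unevaluable** — excluded from
   the four-way table and reported separately. The source tabulations imply
   every included record fell into one of four groups, so exclusion, not a
   fifth column, mirrors the method;
3. otherwise: agreement with the indication in *either* direction is
   **correct** (treating when indicated, or withholding when not);
   phototherapy below threshold is **over-treatment**; none above it is
   **under-treatment**.

Exchange transfusions are recorded and reported but do not enter the
classification, which is defined purely on the phototherapy threshold.
Multiple records from the same infant are audited per record; the package
does not attempt per-infant deduplication because record-level audit is
what the chart-review design supports.

Epochs are compared with the uncorrected Pearson chi-square test
(`stats::chisq.test(correct = FALSE)` internally; the test suite checks it
against an explicit O/E summation to 1e-10). No Yates correction is
applied: the packaged epoch-comparison fixtures reproduce their published
p-values (0.006, 0.024, 0.566, 0.234, 0.016, 0.348, 0.786, 0.614) only
without it. p-values are reported to three decimals and display
percentages use half-up integer rounding, mirroring the source tables. The
demographic comparisons use the display bands of those tables (birth
weight <1000 / 1000–1499 / 1500–2499 / ≥2500 g), which differ from the
nomogram's treatment bands — both band systems appear in the sources and
they serve different purposes. Sparse rows (a risk category with one
count) are tested as-is with the approximation warning suppressed; rows
with zero total are dropped before testing, and a single-epoch tabulation
is permitted (the degenerate column then fails at test time, not at
tabulation time).

## Questionnaire summaries

Likert items are summarised per item (counts, half-up percentages), per
section (pooled counts) and as agreement rates, with agreement defined as
levels 6–7 of the seven-point scale. This definition reproduces the
headline percentages of the packaged acceptance-questionnaire fixture (84%
and 72%) and is configurable. The packaged fixture's printed percentage
grid is itself internally inconsistent in a handful of cells (the same
count of 43 rounding differently in different rows); the regression test
asserts exact half-up agreement everywhere except those enumerated cells,
where it asserts agreement within one point.

## Synthetic cohorts

`generate_cohort()` is classification-first: it draws each record's
intended audit category from the configured per-epoch rates and then
constructs a TSB and treatment flags guaranteed to audit to that category
(e.g. over-treatment sets phototherapy given and a TSB a positive noise
margin below the phototherapy threshold). The alternative — simulating
bilirubin kinetics and letting classifications emerge — would require a
physiological model the audit methodology neither contains nor needs, and
would make expected classification rates analytically intractable.
Construction guarantees make the generator a usable oracle: configured
rates are recovered exactly in expectation, so recovery tests are pure
binomial checks.

Default calibration matches the published two-epoch chart review: 255 and
181 records; P(GA < 35 wk) = 226/436; birth-weight display-band
probabilities (3, 42, 248, 143)/436; risk-category probabilities
(3, 1, 250, 139, 43)/436; per-epoch classification rates (97, 87, 35,
36)/255 and (93, 57, 18, 13)/181. Postnatal age is a truncated normal in
days (mean 4.1, SD 2.7, truncated to 0.25–14 d — the cohort's summary
statistics with clinically plausible support); the noise margin is
|N(1.5, 1)| + 0.1 mg/dL. GA within bands is uniform (28–34.9 and 35–41
weeks), as is birth weight within its band; these uniforms are simplicity
choices, not empirical fits. Correct records split 50/50 between correctly
treating and correctly withholding, a neutral choice in the absence of
published direction-specific counts.

What the cohorts do **not** emulate: bilirubin trajectories over time,
repeated measurements per infant, correlation between demographics and
classification (a real effect — the published subgroup analysis shows
larger improvements in preterm infants), seasonal admission patterns, and
outcome events. Passing recovery tests therefore demonstrates that the
audit pipeline is self-consistent and unbiased at configured rates — not
that it would reproduce any particular hospital's case mix.

## Problem sizes and numerical choices

The test suite checks the chi-square implementation against its oracle on
1,000 random tables (tolerance 1e-10), interpolation against an explicit
piecewise evaluator at 1,000 random ages per stratum (1e-9), advice
monotonicity on 10,000 randomly generated patients, and cohort rate
recovery at the published calibration averaged over 200 seeds with a
3-standard-error criterion; these sizes give the property checks power
while keeping a full run to a few minutes. Ties in interpolation cannot
arise (knot ages are strictly increasing by construction). All internal
TSB arithmetic is in mg/dL; unit conversion happens once at record entry.

## Known limitations

- The shipped thresholds are structural placeholders; clinical use
  requires loading a site's validated table.
- The audit is record-level; infants contributing multiple records are
  weighted by record count.
- Chi-square p-values on sparse tables rely on the asymptotic
  approximation, as in the methodology the package reproduces; no exact
  test is substituted.
- The decision engine encodes exactly three advice tiers; if an underlying
  guideline distinguishes intensive phototherapy as a separate tier below
  the exchange threshold, that distinction is not represented.
- No clinical-judgement inputs (appearance, feeding, social context) enter
  the recommendation; the tool is decision support, not a decision.
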