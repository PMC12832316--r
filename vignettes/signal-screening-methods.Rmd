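---
title: "Disproportionality screening of spontaneous adverse event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous adverse event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous reporting systems such as FAERS collect voluntary post-marketing
safety reports. They have no exposure denominators, so they cannot estimate
incidence or comparative risk; what they support is *disproportionality
analysis* — asking whether a drug–event pair is reported more often than the
rest of the database would predict. pvsignal implements that workflow end to
end: quarterly ASCII ingestion, case assembly, deduplication and cleaning,
drug/indication cohort selection with preferred-term (PT) to system organ
class (SOC) coding, descriptive comparison of report cohorts, and a
four-algorithm signal screen with subgroup stratification. A seeded synthetic
report generator with implanted signals makes every stage testable against
known ground truth without downloading any archive.

```{r, eval = FALSE}
library(pvsignal)
sim <- synth_generate(synth_scenario_signal(seed = 1))
dir <- tempfile(); synth_write(sim$bundles, dir)
quarters <- sub(".*demo_(.*)[.]txt$", "\\1", list.files(dir, "^demo"))
cases <- lapply(quarters, \(q) faers_read_quarter(dir, q)) |>
  faers_assemble() |>
  faers_standardize_drugs(synonym_map("baricitinib", "olumiant")) |>
  faers_recode_implausible() |>
  faers_dedup()
screen <- select_cohort(cases, "baricitinib") |>
  run_screen(cases, dict = sim$dict)
glance(screen)
```

## Case assembly and cleaning

**Identifiers are opaque strings.** FAERS identifiers carry leading zeros;
nothing in the pipeline coerces them to integers except the deduplication
tie-break, which compares numerically only when every id parses as a number.

**Deduplication.** A case (`caseid`) accumulates versions (`primaryid`) as
follow-ups arrive. The convention "retain the most recent version" is
operationalized as: latest report date wins; ties break by greatest
`primaryid`. Follow-up *merging* is realized as selection of the retained
version rather than field-level union — a field-level merge has no published
specification and would make case selection non-auditable. The rule is
deterministic under any input permutation and idempotent, and the cleaning
report reconciles exactly: `output = input − duplicates_removed`.

**Seriousness.** Published descriptive tables report a "serious" fraction
alongside an outcome breakdown whose serious-category rows (death,
life-threatening, hospitalization, disability, congenital anomaly, required
intervention) sum to far less than the serious count, while the breakdown
including the "other" outcome sums slightly above it (multiple outcomes per
report). The only operationalization consistent with both is: *a report is
serious when it carries at least one outcome record of any kind*. That is the
definition used here, with the full outcome set retained per case so either
convention can be recomputed.

**Implausible values.** Negative onset intervals, ages outside [0, 120]
years and weights outside [2, 400] kg are recoded as missing and counted; the
age and weight bounds are this package's choice of implausibility cut-offs
(the convention in the field is to recode rather than drop). Ages arrive in
mixed units and are converted with fixed factors (decades ×10, months ÷12,
weeks ÷52.1775, days ÷365.25, hours ÷8766).

**Drug standardization** is exact-match only: trimmed, whitespace-squeezed,
case-folded lookup in a user-supplied synonym table whose synonym sets must
be disjoint. Fuzzy matching is deliberately excluded — a silent fuzzy hit
changes cohort membership in ways a reviewer cannot audit.

**Completeness filtering.** Study write-ups sometimes claim removal of
reports with missing age or sex while simultaneously tabulating large
not-specified fractions; the two cannot both hold. This pipeline therefore
keeps incomplete reports by default. The `adult_only` flag drops only reports
with *known* age under 18 and applies to the signal cohort; descriptive
tables always cover all ages, and the analysis output records how many
pediatric reports a stricter filter would have removed.

## Descriptive statistics

Percentages are computed against the group's report (or event) total and
rounded **half away from zero** to two decimals, matching how published
safety tables print (e.g. 153/941 → 16.26). Quartiles use linear
interpolation between order statistics (`quantile(type = 7)`). Group
contrasts follow the standard decision rule: Pearson chi-square without
continuity correction (Yates available by flag) unless some expected cell is
below five, in which case Fisher's exact test is used (2×2 only; larger
sparse tables must be collapsed by the caller — silently pooling levels would
hide a modelling decision). Fisher's two-sided p sums the probabilities of
tables no more probable than the observed one, the standard convention.
Continuous variables use the two-sided Mann–Whitney U test: exact enumeration
when both samples have at most 8 values and no ties, otherwise the
tie-corrected normal approximation without continuity correction (identical
samples then give p = 1 exactly). All tests are two-sided at α = 0.05, and no
multiplicity adjustment is applied across the many descriptive contrasts —
deliberately, since these comparisons are descriptive, not confirmatory.

## The four estimators

Each drug–event pair is summarized by the 2×2 table *a* (cohort reports with
the event), *b* (cohort, other events), *c* (other reports with the event),
*d* (remainder), with N = a+b+c+d and the expected count under independence
E = (a+b)(a+c)/N, always recomputed from the cells. Counting is at report
level: a report contributes once per distinct PT.

**ROR** = ad/bc with the Wald interval
exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)). If any cell is zero, 0.5 is added to
every cell of that table (Haldane–Anscombe) before both estimate and
interval; tables without zeros are untouched.

**PRR** = [a/(a+b)] / [c/(c+d)] on raw cells (a = 0 gives PRR 0), paired with
the Yates-corrected Pearson chi-square
N·(|ad−bc|−N/2)²/((a+b)(c+d)(a+c)(b+d)), clamped at zero and computed in
double precision (the denominator overflows 32-bit integers even at moderate
database sizes). The Yates correction is the pharmacovigilance convention for
this statistic and can be switched off.

**BCPNN information component** IC = log₂((a+0.5)/(E+0.5)) with the standard
closed-form credibility bounds IC025 = IC − 3.3(a+0.5)^−1/2 − 2.0(a+0.5)^−3/2
and IC975 = IC + 2.4(a+0.5)^−1/2 − 0.5(a+0.5)^−3/2. The closed form is used
rather than MCMC or the original full network formulation: it is the de facto
convention in FAERS screening and is what the conventional IC025 > 0
threshold was calibrated against.

**MGPS / EBGM.** The gamma-Poisson shrinker places a two-component gamma
mixture prior on the rate ratio λ; marginally each count *a* is a mixture of
two negative binomials given E. The five hyperparameters are fitted by
maximizing the marginal log-likelihood with bounded L-BFGS-B from the fixed
start (0.2, 0.1, 2.0, 4.0, 1/3), shapes and rates bounded in [10⁻⁵, 20] and
the mixing weight in [10⁻³, 1−10⁻³], so the fit is deterministic given the
data. The likelihood is evaluated in log space (log-sum-exp) and the
optimizer contract — never worse than the start — is enforced explicitly. No
count squashing and no stratification of E are applied. The posterior is
again a two-gamma mixture with weight Q from the component marginals;
EBGM = exp(E[ln λ]) via the digamma function, and EB05 is the posterior 5th
percentile found by root-finding on the mixture CDF, bracketed by the two
component quantiles (a mathematically guaranteed bracket) to a tolerance of
10⁻¹⁰, with endpoint guards for degenerate mixing weights.

A note on shrinkage diagnostics: because EBGM is a *geometric*-scale mean, it
is bounded above by max(a/E, prior arithmetic mean) but can fall slightly
below the prior arithmetic mean even when a/E exceeds it; the correct lower
envelope is the prior geometric mean. The property tests use that envelope.

**Thresholds** default to the conventional set — ROR: a ≥ 3 and lower 95%
bound > 1; PRR: a ≥ 3, PRR ≥ 2, chi-square ≥ 4; BCPNN: IC025 > 0 (strict);
MGPS: EB05 > 2 (strict) — because source studies typically cite "established
thresholds" without printing them. They are configuration, are echoed into
every output, and aggregate "any" and "all-four" flags are provided.

## Screening and subgroups

`run_screen()` screens every PT with a ≥ `min_a` (default 3, matching the
a ≥ 3 gates) against a background that contains the cohort. The shrinker
prior is fitted once per screen on all cells with a ≥ 1 — including
sub-threshold cells stabilizes the prior — and the same prior scores every
row. The default comparator is the full cleaned database, the dominant
convention in FAERS studies; a within-indication comparator is available
because source descriptions are often ambiguous about the reference set.
Subgroup screens (gender, age band, seriousness) restrict cohort *and*
background to the same stratum, so demographic reporting imbalances cannot
masquerade as drug signals; strata below a minimum cohort size are emitted as
skipped markers. Ranking offers report frequency, positive-flag count and
signal strength (EBGM then ROR), all with alphabetical tie-breaks so output
ordering is reproducible. Heatmap matrices take the union of each stratum's
top-k terms (by report count — report versus event counting is a choice, and
report counting matches the screen), carry a chosen metric (default IC, which
is symmetric around zero and comparable across frequencies) with missing
markers, and ship alongside the matching count matrix.

## The synthetic generator

`synth_generate()` draws reports from a background multinomial over
(drug, PT) pairs. Implanted pairs have their joint probability multiplied by
ρ with global renormalization, which keeps the background exactly
multinomial and makes ρ interpretable as a relative reporting ratio. Events
per report follow a shifted negative binomial (minimum one reaction, as in
real reports); report dates are uniform over the configured range, follow-up
versions get +1..90-day offsets so "latest" is well defined, and duplicate
versions share the date so the id tie-break is exercised. Demographics (sex
mix, age-band mixture, missingness, seriousness, reporter occupation) are
configurable per target drug, so a two-drug study with a consumer-heavy
recently approved drug (~52% missing age, ~15% serious, ~1.7 events/report)
versus a professional-heavy older comparator (~10% missing age, ~11%
serious, ~3 events/report) can be emulated; those profile values are the
published demographic structure the canned `synth_scenario_aa()` imitates.

What the generator does **not** emulate: misspelled drug names beyond simple
case/padding variants, narrative text, secular reporting trends,
inter-drug correlation of events within a report, or stratum-specific
background rates. Passing tests therefore demonstrate correctness of the
pipeline's logic and calibration of the estimators under clean multinomial
reporting — not robustness to every pathology of real spontaneous data.

Note that the *realized* report-level observed/expected ratio sits below ρ
(about 5–6 at ρ = 8 in the benchmark): multi-event reports and the
renormalization dilute the pair-level multiplier. This is expected sampling
behaviour, not an implementation loss; recovery is judged against the
within-2-fold band.

## Validation problem sizes

The test suite validates the estimator closed forms against independent
brute-force oracles on 1,000 random tables (10⁻⁹ relative) and EB05 against
numerical CDF inversion on 100 random prior/table draws (10⁻⁶ absolute);
calibration under a fixed-margin independence null with 1,000 replicates
(n = 500 target / 10,000 comparator reports, event probability 0.02); and
end-to-end parameter recovery on databases of 50,000 reports with 250 PTs
and five pairs implanted at ρ = 8, run through the full file-backed pipeline
for ten seeds. The prior-recovery check fits the mixture on 10,000 cells
simulated from a single Gamma(2, 4) prior and requires the fitted mixture
mean within 10% of the true 0.5. These sizes were chosen to give stable
pass/fail behaviour at desk scale; real archive-scale screens (millions of
reports) use the same code paths.

## Known limitations

- Signals are hypothesis-generating only; nothing here estimates risk.
- PT/SOC coding uses a user-supplied or synthetic dictionary; licensed
  MedDRA content is not bundled, and only the PT and SOC levels are modelled
  (no HLT/HLGT, no standardized queries).
- The MGPS implementation is pairwise only (no multi-item interactions) and
  fits one unstratified prior per screen.
- Probabilistic record linkage across caseids, field-level follow-up
  merging, and imputation of missing demographics are out of scope.
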