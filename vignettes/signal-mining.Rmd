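---
title: "Disproportionality signal mining on spontaneous ADR reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal mining on spontaneous ADR reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvkit)
```

## The setting

Spontaneous reporting systems (SRS) are passive pharmacovigilance
databases: clinicians and institutions voluntarily submit case reports
of suspected adverse drug reactions (ADRs). pvkit implements the
standard frequentist analysis of such a database for a drug class in a
pediatric population: clean and normalise the reports, expand them
into drug–event combinations (DECs), describe the reporting pattern,
and score every DEC for disproportionality.

Reports carry free-text drug names and reaction descriptions, so the
first analytic step is dictionary normalisation: raw drug names map to
canonical generic (API) names, raw reaction strings map to preferred
terms, and each preferred term belongs to exactly one
system-organ class (SOC) in the WHO-ART style. Both dictionaries are
user-supplied flat CSV files; the package enforces idempotence (a
canonical name maps to itself) and rejects ambiguous or cyclic
mappings outright, because a dictionary that disagrees with itself
silently corrupts every downstream count. Names missing from a
dictionary are kept verbatim and logged, never dropped: an unmapped
name is a dictionary gap, not evidence against the report.

Inclusion follows the conventions of pediatric SRS studies: an age
window (default 0–14 years) and the upper three levels of the
six-level reporter causality scale (certain, probable, possible).
Exclusions carry machine-readable reason codes, and the
included/excluded sets always partition the input, so the count chain
of a run can be audited. Unknown age is its own reason code: such
reports belong in the totals of a study but not in age breakdowns, and
the `unknown_age` policy flag lets the analyst choose either
behaviour; the default excludes them at filtering because the signal
mining background should match the population the criteria describe.

## Counting unit and the fourfold table

A report listing one drug and three reaction terms contributes three
events; one with two drugs and two terms contributes four. The
counting unit of everything downstream is the distinct (report, drug,
term) triple — a repeated identical pair within one report counts once
(`dedup = FALSE` restores raw multiplicity; reports rarely restate a
reaction, so the default reflects what a reviewer would count). With a
mean of ~1.3 terms per report, a database of reports expands to ~1.3×
as many events.

For a target DEC, `build_fourfold()` counts `a` (target drug, target
term), `b` (target drug, other terms), `c` (other drugs, target term)
and `d` (the remainder) over a background. The background is the event
set the pipeline was run on — the included dataset — because that is
the only universe available once inclusion criteria have been applied;
an analyst who wants a wider background can simply mine a wider event
file.

## The three methods and their thresholds

For each scored DEC (any pair with `a ≥ 1`):

* **ROR** `= ad/bc`; 95% CI
  `exp(ln ROR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`, `z = 1.96`.
  Signal: `a ≥ 3` and CI lower limit `> 1`.
* **PRR** `= [a/(a+b)]/[c/(c+d)]`; 95% CI
  `exp(ln PRR ± z·sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d)))`.
  Signal: `a ≥ 3` and CI lower limit `> 1`.
* **MHRA**: signal when `a ≥ 3`, `PRR ≥ 2` and the Yates-corrected
  chi-square is `≥ 4`.

All thresholds live in `signal_criteria()` and are tunable; the
defaults above are the conventional published values. The consensus
flag is the conjunction of the three; by construction the consensus
set is contained in each per-method set, which is why requiring
agreement is the usual noise filter in SRS practice.

Two numerical choices deserve note:

* **Zero cells.** Any zero cell makes the log-scale variance infinite,
  so the estimate is reported as `NA` ("undefined") and the DEC can
  never flag — a flag requires a computable confidence interval. A
  Haldane–Anscombe `+0.5` correction is available (`correction =
  0.5`) but off by default, since the classical formulas carry no
  correction and silently shifting estimates would make published
  thresholds incomparable.
* **Chi-square form.** The Yates statistic is computed as
  `N·(max(0, |ad−bc| − N/2))² / [(a+b)(c+d)(a+c)(b+d)]`. The
  continuity term is clamped at zero so near-independent tables score
  0 rather than a spurious positive value. Some sources print the
  denominator with transposed margins, `(a+b)(a+c)(b+c)(c+d)`; that
  variant is available as `yates_chi2(tab, denominator =
  "as_printed")` for comparison, but the standard form is the default
  and is what the MHRA rule uses — the printed variant is not a valid
  chi-square (it breaks the row-swap symmetry the statistic must
  satisfy). Similarly, where the PRR interval is sometimes printed
  with `ln(ROR)` at its centre, the package centres it on `ln(PRR)`;
  the alternative is an obvious transcription slip, as it would make
  the interval inconsistent with its own variance.

Display rounding is half-up to two decimals (`round_half_up()`),
matching how such tables are printed; internal arithmetic is full
double precision.

## Descriptive statistics

The descriptive module reproduces the tables conventional in SRS
safety papers: sex distribution with the male–female ratio, severity
and novelty breakdowns, per-stratum serious proportions (by sex, age
group, or drug, the drug mode ordered by total reports), ADR
frequencies by preferred term or SOC with cumulative percentages,
outcome distributions with a per-case extract of deaths, and route of
administration. Every frequency table carries its denominator
explicitly, because report-level statistics (denominator = reports)
and event-level statistics (denominator = events) coexist in one
analysis and conflating them is the classic error in this literature.

`pearson_chi2()` covers the r×c comparisons such papers make (severity
by sex, severity by age dichotomy). It delegates to the standard
Pearson test with Yates correction applied only in the 2×2 case, and
refuses degenerate margins. Age groups come as single-year bins 0–14
plus a named "0–4 versus 5–14" preset, the dichotomy conventionally
used to compare severity between infants/toddlers and older children.

## The synthetic generator

Real SRS databases are confidential, so validation rests on a
generator whose defaults emulate the shape of a provincial pediatric
cephalosporin database, taken from the bundled study tables
(`study_fixture()`):

* **Catalogs.** 37 cephalosporins with marginal probabilities
  proportional to their published report counts; 22 high-frequency
  ADR terms (the top 95% of events) with baseline probabilities
  proportional to their published event counts. The SOC assignment of
  the default terms is supplied by the package in WHO-ART style.
* **Terms per report.** Zero-truncated Poisson with mean 1.304 — the
  published events/reports ratio (20,681/15,857). Terms within a
  report are drawn without replacement, so the realised
  events-per-report ratio equals the configured mean.
* **Demographics.** Male:female 1.60 with a small unknown fraction;
  ages 0–14 skewed toward 0–3 (the 0–1 and 2–3 groups carry the most
  reports); 6.63% serious; 99.2% recovered or improved with a
  4-in-15,857 death rate; 96.3% injection route. Each is the published
  marginal where one is printed, and a plausible single choice where
  only a figure-level pattern is available (the exact single-year age
  histogram is not published; the default is a smooth decay matching
  the published two-year bins).
* **Implants.** An implanted association multiplies the target term's
  probability within the target drug's reports by `rate_ratio` and
  renormalises that drug's term distribution — the relative-reporting
  interpretation that PRR estimates. Renormalisation means the
  realised rate ratio is `rr/(1 + q(rr − 1))` for baseline `q`, i.e.
  slightly below the nominal `rr`; for the rare terms used in the
  benchmarks the bias is a few percent.
* **Severity** is drawn independently of the DEC by default (the
  descriptive severity analyses in this literature are marginal); a
  per-drug serious probability (`use_drug_serious = TRUE`) supports
  drug-severity patterns.
* **One suspected drug per report** by default, matching single-drug
  single-ADR mining; multi-drug reports are supported by the data
  model and expansion for stress testing.

Identical configuration and seed give byte-identical output. What the
generator does **not** emulate: reporting delays, duplicate
submissions, reporter-specific biases, term misspellings, or
drug–drug interactions. Tests passing on synthetic data therefore
validate the counting and inference machinery, not robustness to the
messiness of real SRS text fields — that is what the dictionary and
parse logs are for on real data.

## Validation strategy and problem sizes

The test suite validates on several axes, with sizes chosen to keep a
full run around a minute:

* **Oracle equivalence.** ROR/PRR/chi-square agree with independent
  implementations (log-space arithmetic, `chisq.test`) on 10,000
  random tables to relative error 1e-9; Pearson's statistic agrees
  with a first-principles expected-count loop.
* **Exhaustive algebra.** On all 20,736 tables with cells 1–12:
  `sign(ROR−1) = sign(PRR−1) = sign(ad−bc)`; `PRR ≤ ROR` whenever
  `ROR > 1`; consensus ⊆ each per-method set; and monotonicity of all
  three statistics in `a` (chi-square on the positively associated
  side).
* **CI calibration.** Over 2,000 multinomial fourfold tables with
  `E[a] = 50` and a known true reporting odds ratio, the ROR 95% CI
  covers the truth within 95% ± 1.5%.
* **Signal recovery.** Twenty implanted associations at rate ratio 5
  in databases of 50,000 reports, each implant placed (by
  `recovery_benchmark_config()`) on a distinct term with expected
  `a ≥ 12`, averaged over 20 seeds: consensus sensitivity above 0.9
  (observed essentially 1), with matched null runs confirming the
  consensus flag rate does not exceed any single method's. Implants
  sit on distinct terms because co-implanting one term across many
  drugs inflates the shared background `c` and dilutes every implant
  — a real phenomenon, but a different experiment.
* **Published-table reproduction.** The descriptive module rebuilds
  report/event sets whose margins equal the bundled study tables and
  reproduces every printed percentage and ratio exactly (1.60 sex
  ratio, 6.63%/93.37% severity split, per-drug serious percentages,
  36.18% rash, 64.29% skin SOC, 96.30% injection, four deaths).

The published per-signal statistics (individual ROR/PRR/chi-square
values) are *not* reproduction targets: their underlying cell counts
were never printed, and the published signal totals (211/207/376/206)
depend on the confidential database. Likewise the published
severity-by-sex and severity-by-age chi-squares rest on stratified
counts shown only in figures; the chi-square operation is validated
against oracles instead.

## Known limitations

* Single-database background only; no external or historical
  background rates.
* No Bayesian shrinkage methods (BCPNN, EBGM) — out of scope by
  design.
* No multiplicity control on the per-method flags; the consensus rule
  is the only noise filter, as in the classical practice this package
  reproduces. The false-discovery proportions reported by
  `evaluate_recovery()` make the cost of that choice visible.
* Dates are parsed and filtered but not modelled; there is no
  time-to-onset or trend analysis.
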