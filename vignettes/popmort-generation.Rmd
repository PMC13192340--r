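---
title: "Generating PopMort files from abridged life tables, and validating them with relative survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating PopMort files from abridged life tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmortgen)
```

## Why PopMort files

Relative survival compares a patient cohort's observed survival with the
expected survival of a matched general population, giving a
cause-of-death-free proxy for disease-specific survival. The expected side
of that ratio is driven by a *PopMort file*: one row per calendar year,
sex, and single year of age from 0 to 100, holding the central mortality
rate and the annual survival probability of the general population.
Statistical offices, though, publish *abridged* life tables: the
probability of dying \({}_nq_x\) per five-year age group, per sex, for a
multi-year reference period. This package converts the latter into the
former, and ships an estimator stack that can verify the conversion end to
end on synthetic data.

## The conversion model

**Rate inversion.** For a closed group \([x, x+n)\) the probability of
dying and the central death rate are linked through the separation factor
\({}_nf_x\), which captures the average timing of deaths inside the
interval:

\[
{}_nq_x = \frac{n\,{}_nM_x}{1 + {}_nf_x\,{}_nM_x}
\qquad\Longleftrightarrow\qquad
{}_nM_x = \frac{{}_nq_x}{n - {}_nf_x\,{}_nq_x}.
\]

The package applies the convention \({}_nf_x = 1/2\) for the combined 0–4
group — infant deaths cluster near the start of the interval — and
\(n/2\) for every other closed group (so \(5/2\) for the standard
five-year groups). A deviation from the default is possible through an
override table, but the default *is* the stated convention and the tests
pin it. The two formulas are exact algebraic inverses, which gives the
suite a free round-trip oracle: `rate_to_nqx(nqx_to_rate(q)) == q` to
1e−12 across a 99-point grid in every group.

**Probability link.** The annual survival probability is
`prob = exp(-rate)`, i.e. survival for one year under a constant hazard
equal to the central rate. The identity is maintained to full floating
precision in memory and to 1e−9 across text round-trips (decimal
serialisation is round-trippable, so in practice it survives exactly).

**Single-age smoothing.** Each group's rate and probability are assigned
unchanged to every single year of age inside the group. This
piecewise-constant rule is deliberate: no splines, no Gompertz or Kannisto
graduation. It keeps the output an exact function of the published table
and makes the synthetic validation below exact up to Monte Carlo error.

**Terminal ages.** Separation factors are defined only through the last
closed group (typically 90–94), yet the output must reach age 100, and the
open terminal row of a published table (85+ or 95+, with \({}_nq_x = 1\))
has no finite central rate under the inversion formula. The package's
choice: ages above the last closed group reuse the last closed group's
rate and probability, and the open row never enters the conversion. This
is conservative — it understates very-old-age mortality — but avoids
inventing a terminal mortality model the input cannot support. The
alternative (fitting an old-age extrapolation) is explicitly out of scope.

**Calendar assignment.** A life table for 2015–2019 is taken to represent
its midyear 2017 (even-length periods round down). Every calendar year in
the requested range maps to the *nearest* available midyear: years after
the latest midyear carry the latest table forward (the standard practice
when recent tables are unpublished), years before the earliest carry the
earliest backward — registries routinely need incidence years that precede
the first usable life table, and nearest-neighbour is the natural
two-sided generalisation of forward carry. Exact ties break toward the
earlier midyear, purely for determinism. The year-to-table mapping is kept
in the output object's `provenance` and logged by the CLI.

**Split infant rows.** Published tables often separate age 0 from ages
1–4 while the separation-factor convention addresses a combined 0–4
group. `merge_infant_rows()` combines them through the survival product
\(q = 1 - (1 - q_0)(1 - {}_4q_1)\); the operation is idempotent and
applied automatically during a build when the input starts with a
width-1 row.

## File format

The canonical output is delimited text with headers
`_year, sex, _age, rate, prob` — the naming convention common
relative-survival software expects when merging population mortality onto
patient records — with sex coded 1 = male, 2 = female. Headers and
delimiter are configurable through `popmort_file_spec()`. Numbers are
written in a round-trippable decimal form, so write → read → write is
byte-identical and files diff cleanly. The reader re-validates
completeness of the (year, sex, age) cross-product and the
`prob = exp(-rate)` link, listing the first offender on failure. Binary
or proprietary formats are deliberately not emitted.

## The synthetic world

`make_life_table()` fabricates abridged tables from a Gompertz–Makeham
hazard \(h(a) = A + B e^{Ca}\), using the closed-form cumulative hazard,
so each group's \({}_nq_x\) is exact. The defaults —
\(A = 5\times10^{-4}\), \(B = 2\times10^{-5}\), \(C = 0.1\) per year of
age — give a schedule with five-year death probabilities rising from
about 0.003 in childhood to about 0.65 at 90–94, broadly the shape of a
contemporary middle-income population. The cohort defaults emulate a
registry cancer series: diagnoses uniform over 2013–2016 and ages 45–80,
five years of follow-up, and an excess (disease-specific) hazard of 0.1
per person-year, roughly a 40% five-year net survival. These values were
fixed once as a realistic stated world; they are inputs to the tests, not
tuning knobs.

`simulate_cohort()` draws death times from the piecewise-constant total
hazard `rate(year + t, sex, age + t) + excess_hazard`, advancing age and
calendar year in whole-year steps — *exactly* the PopMort semantics. That
alignment is the point: with zero excess hazard, the cohort's true
survival equals the Ederer II expected survival computed from the same
PopMort, so relative survival must equal 1 up to Monte Carlo error alone,
with no model error term. The headline acceptance test draws 20,000 such
patients and requires RS at 1, 3 and 5 years to sit within three standard
errors of 1 and within ±0.02 absolutely.

What the generator does **not** emulate: real mortality levels of any
specific population, rural/urban or regional differentials, cohort
effects, non-uniform diagnosis flows, or loss to follow-up before the
administrative horizon. A green test therefore establishes that the
conversion and estimator machinery is self-consistent — not that any
particular published life table was transcribed correctly.

Reproducibility: the simulator uses one RNG stream keyed by `seed`, with
all per-patient draws made in a fixed order (attributes first, then one
exponential threshold per patient). The same seed yields an identical
cohort; a substream library was not needed to meet that contract.

## The validation estimators

* **Observed survival**: interval-actuarial estimator with the
  half-censoring correction (effective denominator
  \(n' = n - c/2\)), cumulative product across intervals, Greenwood
  variance of the log survival. Deaths and censorings are attributed to
  the interval containing the event time; administrative censoring exactly
  at the horizon counts as surviving the final interval.
* **Expected survival (Ederer II)**: at the start of each interval, every
  patient still at risk contributes the product of the annual population
  survival probabilities along their own (year, sex, attained age)
  trajectory; the interval's expected conditional survival is the risk-set
  mean, and cumulative expected survival the running product. Ages and
  years advance in whole-year steps because that is the PopMort
  resolution; intervals must therefore be whole years. Attained ages
  beyond the table maximum (100) continue at the age-100 rate, mirroring
  the terminal-extension decision. Ederer II was chosen because it is the
  default of the survival software this workflow feeds; no other expected
  method is implemented.
* **Relative survival**: observed divided by expected per cumulative
  interval. The 95% interval applies the log(−log) transform with
  Greenwood variance to the observed survival and divides both limits by
  the expected survival, treated as fixed — standard practice when no
  CI recipe is otherwise prescribed. Degenerate cases (no events, or
  observed survival exactly 0 or 1) collapse the interval to the point
  estimate rather than producing NaN.
* **Age standardisation**: weighted mean of group-specific RS under
  caller-supplied external weights (e.g. ICSS), normalised to sum to 1;
  the variance combines as \(\sum w_i^2 \sigma_i^2\). A group with no
  at-risk patients is dropped with a warning and the weights renormalised
  — silently imputing a group would bias the standard. No weight standard
  is baked in because none is universal.

Out of scope by design: Pohar Perme net survival, period analysis, and
flexible parametric relative-survival models.

## Numerical choices and edge cases

* All arithmetic is double precision; nothing is rounded before output.
* `nqx = 1` is accepted only in the open terminal row; a closed group with
  \({}_nq_x = 1\) would make the rate inversion blow up and is rejected at
  validation, as is any non-contiguous or non-zero-starting group schema.
* The inversion denominator \(n - f q\) is guarded even though it cannot
  go non-positive for \(f \le n/2\) and \(q < 1\).
* The forward formula's range limit (\({}_nq_x \to n/f\) as the rate
  grows) means naive use on extreme rates can produce "probabilities"
  above 1; the synthetic generator works on the hazard scale precisely to
  avoid ever clamping.
* The constant-hazard cross-check — build a table from hazard \(\mu\),
  invert with \(f = n/2\), recover \(\mu\) — holds to about 1e−3 relative
  at \(\mu = 0.02\): the separation-factor inversion is a first-order
  approximation to the exact constant-hazard inverse, and the tests assert
  it at that documented tolerance, not tighter.
* Bare-integer age labels take their width from the next row; a bare
  integer in the last row is rejected rather than guessed.
* Config files for the CLI are JSON; the structure would map to YAML
  one-to-one, but JSON parsing is available without adding dependencies.
  Spreadsheet input is likewise not implemented: delimited text is the
  canonical interchange form, and the column-schema mechanism makes any
  sheet exportable to it trivially.

## Known limitations

* Piecewise-constant smoothing produces rate steps at group boundaries;
  consumers wanting smooth schedules need a graduation step this package
  intentionally omits.
* The terminal extension flattens mortality above the last closed group,
  understating it at ages 95+.
* Expected-survival resolution is annual; sub-annual intervals are not
  supported.
* The validator is a minimal estimator stack for self-consistency checks,
  not a replacement for a full survival package in production analyses.
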