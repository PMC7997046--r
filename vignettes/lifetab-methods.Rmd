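---
title: "lifetab: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lifetab: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifetab)
```

## The cohort model

`lifetab` analyses single-pair rearing studies: each replicate is one
adult female caged with males, observed until death, with her eggs
censused at a fixed interval (default 2 days) and her brood followed to
adult emergence. Three tables capture a study — per-female records
(census egg series, longevity, oviposition and post-oviposition periods),
per-female offspring tallies (eggs, survivors to adult, females among the
adults), and a development subsample (egg-to-adult days by sex, not
linked to individual mothers). The motivating design is a 4 × 2 factorial:
single- and cross-mating groups of two *Bemisia tabaci* MED genetic
clusters on cucumber and tobacco, 30 families per cell.

## Schedules and population parameters

The life table is built at pivotal ages
`x = dev_offset + adult_age + 0.5` where `dev_offset` is the mean
egg-to-adult period of the cell's emerged subsample (sexes combined by
default; a sex-specific option exists). Survival and fecundity factor as

`l_x = SURV * NSF_x / NF` and `m_x = NEGG_x * SR`,

with `SURV` and `SR` pooled count ratios over all broods of the cell.
This treats immature survival as a single age-constant multiplier over
the adult span — the upstream measurement is one egg-to-adult fraction,
not an age-resolved mortality curve — and makes `l_x[1] = SURV`.

Two conventions are deliberately ambiguous in the source methodology and
are therefore both implemented:

* **Census-to-age mapping.** 2-day census counts are either spread evenly
  over the interval's days on a daily grid (default, `age_convention =
  "spread"`), with the final interval truncated at the death day so no
  eggs are assigned past death, or kept at interval resolution with `x`
  at interval midpoints (`"midpoint"`, giving `x[1] = dev_offset + 0.5 +
  interval/2`). Both conserve total eggs exactly.
* **Per-capita denominator.** `NEGG_x` divides each step's egg total by
  the initial female count `NF` (default; keeps `l_x` and `m_x`
  independent) or by the females alive at the step
  (`negg_convention = "living_females"`). The published numbers are
  internally most consistent with the living-females reading
  (mean fecundity × egg-to-female-adult fraction ≈ published `R0`), but
  the default follows the stated formulae; on these schedules, where most
  eggs are laid while adult survival is still near 1, the two differ by
  only a few percent.

From a schedule, `R0 = sum(lx * mx)`; `r` solves
`sum(exp(-r * x) * lx * mx) = 1`; `lambda = exp(r)`; `T = log(R0) / r`.
The Euler–Lotka left side is strictly decreasing in `r` whenever
reproduction occurs at a positive age, so the root is unique. The solver
brackets from `[-1, 2]` per day with geometric expansion, runs Brent's
method, then polishes with Newton steps to a residual below `1e-10`
(typically `1e-14`). `T` is computed from the identity, as defined; at
`r = 0` it degenerates to 0/0 and the cohort generation time
`sum(x * lx * mx) / R0` is returned with a `limit` flag.

## Jackknife inference

The resampling unit is the family: a female together with her offspring
tally. Each deletion recomputes `NF`, adult survival, the egg totals,
`SURV` and `SR`, and re-solves the system; pseudo-values
`v_i = n * theta_hat - (n - 1) * theta_hat_(-i)` give the estimate
(`mean(v)`) and SE (`sd(v)/sqrt(n)`). Three choices deserve note:

* `lambda` and `T` are jackknifed directly on their own scales rather
  than derived from `r`'s pseudo-values; the two differ slightly and the
  direct reading matches how the parameters are defined.
* The development offset is held fixed across deletions: the subsample is
  not linked to mothers, so deleting a family cannot change it. Its
  sampling error (SE of a mean of ~50 emerged individuals) is therefore
  *not* inside the jackknife SE; this is a known limitation of the
  upstream design, and the parameter-recovery test below accounts for it
  by fixing the offset at its known value. An optional
  `resample_dev = TRUE` bootstraps the offset per deletion for
  sensitivity analysis.
* A deletion that leaves a subset with no eggs or no emerged offspring is
  flagged rather than fatal; at least three valid deletions are required.

Cells are compared parameter-by-parameter with a Tukey studentized-range
test on the pseudo-values: pooled within-cell variance, Tukey–Kramer
standard errors for unequal cell counts, and a compact letter display
built by insert-and-absorb over cells sorted by descending mean (ties
broken by label, so output is deterministic). The pipeline reports
lowercase letters for comparisons within a host plant and uppercase
letters across both hosts, mirroring the published table layout.

## Trait-level statistics

`two_way_anova()` fits the full cluster × host factorial by least
squares. Balanced data reproduce the classical decomposition; unbalanced
data (development periods have unequal subsample sizes) use
Type-III-style model-comparison sums of squares under sum-to-zero
contrasts — a convention chosen to mirror the default of the GLM
procedure named in the source methodology, not a claim of numerical
equality with it. Sequential (Type-I) SS are available for comparison.
Proportions (offspring survival, sex ratio) enter ANOVA per female after
the arcsine square-root transform; the package reports both per-female
means (the comparison scale) and pooled count ratios (the schedule scale)
because the two genuinely differ across broods of unequal size.

## The synthetic cohort generator

No raw rearing data are deposited, so the generator is a first-class
module that emulates the study's stated world: 8 treatment cells, 30
single-pair families per cell, 2-day censuses, 60-egg development
subsamples. Per family it draws

* longevity ~ gamma(mean, sd), recorded to whole days (minimum 1), with
  each cell's mean and SD back-computed from the published mean ± SE at
  n = 30;
* lifetime fecundity ~ gamma(mean, sd), rounded to an integer count;
* an oviposition window equal to the published cell-level fraction of
  longevity, with the eggs placed across its days by a multinomial draw
  over an exponential-decay kernel (see calibration below) and then
  aggregated into censuses;
* offspring survivors ~ binomial(eggs, SURV) and females among survivors
  ~ binomial(survivors, SR), with the probabilities taken from the
  published pooled counts;
* a development subsample with per-sex gamma periods rounded to days.

Distribution families are declared modelling choices, not claims about
the organism. A single master seed drives deterministic per-family
substreams, so datasets are reproducible and insertion-order invariant.

**Kernel calibration.** The published tables give no age-specific
fecundity curve, but the pair (`r`, `T`) of each cell pins down how
front-loaded reproduction must be: a flat kernel over the oviposition
window yields generation times several days too long for every cell. The
decay rate is therefore solved per cell so that the *expected schedule* —
computed exactly, by integrating over the discretized longevity law with
the same census blurring and integer-day recording the pipeline applies
to data — has exactly the published `T`. `r` is never a calibration
target; that the calibrated worlds land within rounding of the published
`r` in every cell (checked in the test suite) is a consequence of the
`(R0, T)` constraints, and is the package's main evidence that the
emulated world is faithful.

`expected_schedule()` doubles as the ground truth for parameter
recovery: it is the generator's own large-n limit, so
`intrinsic_rate(expected_schedule(params))` is the known `r*` of a
stated world, against which pipeline output on finite simulated cohorts
is tested (20 replicates of 300 families recover `r*` within 2%, with
`r*` inside `jk_mean ± 2·jk_se` in ≥ 90% of replicates).

**What the generator does not emulate.** Within-female ageing trends
beyond the shared kernel, between-female heterogeneity in survival or
sex-ratio probabilities (overdispersion enters only through brood-size
variation), correlation between a mother's traits and her brood's
development, male demography, and any environmental time effects. A green
simulation test therefore establishes that the *analysis machinery* is
correct for data with this structure — not that real rearing data meet
the structure.

## Numerical and degenerate-case policy

* Solver: residual tolerance `1e-10` enforced, bracket expansion capped
  at 60 doublings, `R0 = 0` and all-mass-at-age-0 raise classed errors.
* Studentized-range p-values use `stats::ptukey`; the two-group case
  reproduces the pooled-variance t-test decision exactly.
* Zero-variance inputs: ANOVA on a constant response reports zero SS and
  flagged (NaN) F ratios; a degenerate pooled variance in `tukey_hsd`
  separates groups by exact mean equality.
* Validation errors are classed (`lifetab_schema_error`,
  `lifetab_validation_error`, `lifetab_analysis_error`,
  `lifetab_solver_error`) and name the offending record and rule.

## Known limitations

Immature mortality is age-constant by construction; there is no two-sex
or age-stage variant; the jackknife SE excludes development-subsample
uncertainty (see above); and Type-III SS are one convention among several
for unbalanced factorials. These mirror the scope of the upstream
methodology rather than gaps the package could silently fill.
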