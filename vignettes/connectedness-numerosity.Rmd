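---
title: "Simulating and analysing the connectedness numerosity illusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing the connectedness numerosity illusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numbias)
```

## The phenomenon and the measurement problem

Humans estimate the number of items in a brief visual display without
counting. This "numerosity sense" operates on segmented objects rather than
raw local features: when pairs of dots in a cloud are joined by thin lines,
the connected pairs are grouped into single perceptual units and the cloud
looks *less* numerous than an identical cloud of isolated dots. The strength
of this connectedness illusion is an objective, indirect probe of perceptual
grouping — observers are never asked about grouping, only which of two
clouds has more dots.

Grouping strength varies between people. In neurotypical adults the
magnitude of the connectedness illusion shrinks as autistic-like personality
traits (measured by the 50-item autism-spectrum quotient, AQ, scored 0–50)
increase, consistent with accounts of autistic perception that emphasise
local over global processing. `numbias` implements the complete simulation
and analysis workflow needed to study this effect: stimulus generation,
adaptive 2AFC sessions on synthetic observers, psychometric fitting, and the
group statistics, so that every stage of the analysis chain can be tested,
calibrated, and rerun on real trial logs in the same CSV schema.

## Stimulus geometry

`place_isolated(n)` casts `n` dots uniformly in a circular patch by
rejection sampling. `place_connected(n)` first casts
`round_to_even(0.4 n) / 2` dot *pairs* — the second dot of each pair placed
at a uniform random direction and distance between 10 and 15 mm from the
first, joined by a 0.5 mm line of the pair's colour — then casts the
remaining loose dots avoiding all dots and lines. Constraints enforced and
verified by `validate_pattern()`:

* no two dot centres closer than 2.5 mm (0.25 deg at 57 cm);
* connector lengths in 10–15 mm and no two connectors crossing;
* loose dots clear of every connector (non-overlap of ink, plus a
  configurable extra margin, `clearance_margin`, default 0 — the minimum
  clearance is not standardised in this paradigm, so we expose it);
* half black, half white dots (within one), with each pair and its line
  sharing one colour, pairs alternating colours, and loose dots restoring
  the global balance.

Units are degrees of visual angle with the millimetre-to-degree conversion
fixed by the viewing distance (57 cm makes 1 cm = 1 deg). Two choices were
genuinely open and are worth recording. The patch extent is not part of the
published stimulus description; we default to a 6-deg-radius field, which
comfortably holds 100 dots at the minimum spacing (the hexagonal packing
bound for that field is about 2000 dots). And "neighbouring dots" is
operationalised by *joint* casting of each pair rather than post-hoc
selection of close dots, which matches the two-stage construction
literally and guarantees every connector is a valid length. Probe stimuli
always use only isolated dots; only the reference is ever connected.

Note that a fully connected two-dot pattern cannot simultaneously satisfy
pair colouring and colour balance; the generator raises an error for such
unsatisfiable configurations rather than silently relaxing a constraint.

## The adaptive engine

Probe numerosities are chosen by a QUEST-style procedure: a discretized
posterior over candidate PSE values, updated after every trial with the
likelihood of the observed response. Published descriptions of this
paradigm leave the internal psychometric family and prior unstated; we use
a cumulative Gaussian in linear numerosity (criterion 0.5, guess rate 0,
symmetric lapse 0.02), matching the analysis-stage fitting family, with a
Gaussian prior centred on the reference numerosity with SD 40% of it, an
assumed slope of 25% of the reference (an assumed Weber fraction near
0.25), and a 201-point grid spanning the prior mean ± 4 SD (floored at 1).
QUEST is reinitialised for every (numerosity × condition) block.

After each trial the posterior *mean* is perturbed by Gaussian noise of SD
0.5 dots, rounded, and floored at 2 to give the next probe. The 0.5-dot SD
is applied literally at every numerosity, as the protocol being emulated
specifies, even though half a dot is a very small excursion at N = 100; the
SD is exposed in `perturbation_config()` for anyone wanting a
numerosity-scaled override. The first trial's probe comes from the prior by
the same perturb-and-round rule, and probes may equal the reference (such
trials are kept).

Because probes concentrate at the running PSE estimate, "probe more
numerous" and "probe less numerous" responses are automatically balanced;
over a simulated 180-trial block the chose-probe proportion stays within
[0.4, 0.6]. One calibration subtlety: for an observer whose decision noise
exactly matches QUEST's assumed slope, the posterior is well calibrated,
so the PSE estimate falls within 1.5 posterior SD of truth about 87% of the
time — the theoretical ceiling for a calibrated Gaussian posterior. In the
connected condition the observer's effective noise (scaled by the smaller
*perceived* numerosity) is below the assumed slope, the posterior is
conservative, and coverage rises to ~95%.

## The synthetic cohort

`sample_cohort()` draws observers with:

* integer AQ scores from a normal distribution truncated to [0, 50],
  centred at 15 with SD 11 — chosen to emulate a young neurotypical adult
  cohort whose median is 15 with quartiles roughly 11/26 and almost all
  scores below the clinical screening threshold of 32;
* an underestimation bias for connected patterns that declines linearly
  with AQ, with separate lines for the low-numerosity regime (N ≤ 50,
  default `0.3466 − 0.00925 × AQ`) and the high regime (N = 100, default
  `0.1264 − 0.00198 × AQ`), clipped to [0, 0.6]. The intercepts and slopes
  are calibration choices, fixed once so that the group means after a split
  at AQ 15 are ≈ 27% / 13% (low/high AQ) in the low regime and
  ≈ 11% / 8% at N = 100 — the published anchors for this paradigm. The
  two-level step (rather than a smooth function of N) mirrors the fact
  that the analysis separates exactly these two regimes; per-numerosity
  behaviour between them is unconstrained by any published value;
* Weber-fraction parameters lognormally scattered (CV 0.12) around 0.25
  for *all* observers — discrimination precision is deliberately matched
  across the AQ range;
* a 2% lapse rate and lognormal reaction times (meanlog log 0.7 s,
  sdlog 0.4).

Responses follow
`P(choose probe) = lapse/2 + (1 − lapse) Φ((probe − ref_perceived)/(weber × ref_perceived))`:
decision noise scales with the *perceived* reference, which is what keeps
the measured Weber fraction flat across numerosities. Isolated references
are perceived veridically; connected references are reduced by the
observer's regime bias.

Two distinctions matter when comparing to empirical numbers. First, the
`weber` parameter is the Gaussian SD as a fraction of the perceived
reference; the *reported* Weber fraction is JND/PSE = 0.6745 × `weber`
(≈ 0.17 at the default), since the JND is defined from the 50%→75% span.
Second, each observer's bias is an exact linear function of their AQ score
— the generator has no additional between-observer scatter around the
bias–AQ line. Simulated bias–AQ correlations are therefore limited only by
psychometric measurement noise and come out near ceiling (r ≈ 0.95–0.99),
substantially higher than the r ≈ 0.7 typical of real cohorts. Passing
recovery tests on this generator demonstrates that the *pipeline* is
unbiased and well-calibrated; it does not show that real data are this
clean. The lognormal RT model likewise produces ±2 SD trim rates of ~4%,
a little above the <2% seen with genuinely heavy-tailed human RTs.

## From trials to statistics

`analyze_trials()` applies the published analysis rules: reaction-time
trimming at mean ± 2 SD per subject (single pass over the subject's whole
session, zero-spread defined as keep-all), then a maximum-likelihood
cumulative-Gaussian fit per subject × condition × numerosity. The fit has
two parameters (PSE, sigma) in linear numerosity and no lapse by default
(a fixed lapse can be supplied); it is optimised by bounded L-BFGS-B on
(pse, log sigma) from three starting points, and cross-checked in the test
suite against probit regression, which is the same maximum-likelihood
problem in a different parameterisation. Derived quantities: JND =
0.6745 σ (we read "difference between 50% and 75% correct" on the
probe-chosen axis; no folded-function variant is implemented), Weber
fraction = JND / PSE (perceived numerosity, not the physical reference),
percent bias = 100 (PSE − N)/N.

`report_stats()` then reproduces the group workflow: per-subject mean
connected bias over N ∈ {15, 25, 50} (unweighted) and at N = 100; a median
split of AQ with ties going to the low group (the convention needed to
produce an 11/10 split when the median is attained); Pearson correlations
of bias with AQ per regime; pooled-variance t tests between the AQ groups
(df = n1 + n2 − 2); a two-way repeated-measures ANOVA on bias
(numerosity × condition, each effect tested against its subject-by-effect
stratum); and the Weber-fraction group comparison.

## Bayes factors

Published work in this area reports base-10 log Bayes factors computed
from summary statistics. Reproducing those numbers requires matching not
just the prior family but the *conventions* of the calculators used, which
we verified numerically during development:

* `bf_ttest_jzs()` integrates the noncentral-t likelihood over a Cauchy
  prior on effect size (scale 1/√2 by default). Its default effective
  sample size is the *df-based* convention, `N_eff = df + 1` — what a
  summary-statistics calculator taking (t, df) computes, and the only
  convention that reproduces the published pair (1.08, −0.56) from
  t(19) = 3.32 and 0.62 to printed precision. The textbook two-sample
  convention `N_eff = n1 n2/(n1 + n2)` is available via
  `effective_n = "pooled"` (it yields 1.05 and −0.35 for the same inputs).
* `bf_pearson()` defaults to the Zellner–Siow (JZS) g-prior formulation of
  the correlation test, which gives log10 BF = 2.13 at r = 0.72, n = 21
  and −0.54 at r = 0.24 — matching the published 2.1 / −0.55 — with
  BF10 ≈ 134, consistent with the "Bayes factor > 100" headline. The
  stretched-beta prior of modern JASP (`prior = "stretched_beta"`, width
  1 = uniform on ρ, integrating the exact sampling density of r via a
  series 2F1) is also provided; note it gives 2.18 / −0.34 for the same
  inputs, so it cannot be the convention behind the published values.

Both integrators use adaptive quadrature at relative tolerance 1e-10 and
are tested to 1e-6 relative agreement against independent dense-grid
quadrature oracles. Model-averaged ANOVA Bayes factors (the kind JASP
reports for repeated-measures designs) are out of scope; the classical F
table stands in.

## Numerical and degenerate-input choices

* Rejection sampling uses 10,000 attempts per element before raising a
  placement-failure error (the signal that a field cannot hold the
  requested numerosity at the configured spacing).
* Segment intersection uses exact orientation tests; touching endpoints
  and collinear overlaps count as intersecting, so generated connectors
  are strictly disjoint.
* Psychometric fits refuse all-identical responses (PSE unidentifiable)
  and fewer than two probe levels; perfectly separable data put the PSE at
  the step with sigma on a likelihood plateau near its lower bound.
* A perfect bias–AQ correlation (possible with deterministic synthetic
  fits tables) makes the correlation Bayes factor infinite; the report
  warns and records an infinite log BF rather than failing.
* `rm_anova_2way` requires a complete balanced design and never imputes;
  effects with zero sum of squares report F = 0.
* RT trimming with zero SD keeps all trials.

## Problem sizes used in the test suite

The default simulated experiment is the full published design — 21
subjects × 4 numerosities × 2 conditions × 180 trials (1440 per subject,
168 psychometric fits) — which runs in a few seconds. Monte-Carlo
calibration checks use 2000 replicates (type-I error of the ANOVA and
Jarque–Bera tests), 200 replicates for QUEST convergence coverage, and
20,000-observer cohorts for the bias-anchor checks; geometry invariants
are exercised over 100 seeds per reference numerosity.

## Known limitations

* The generator models trait-level bias deterministically in AQ (see
  above): realistic attenuation of the bias–AQ correlation is not
  simulated.
* Stimulus geometry affects nothing downstream of the trial log — the
  decision model acts on numerosities, not images — so the geometry module
  validates the stimulus constraints rather than re-deriving the illusion
  from pixels.
* The AQ instrument is represented only by its mechanical scoring rule
  (`score_aq()`); item content and subscales are out of scope.
* Display calibration, timing, and anything requiring a real screen are
  out of scope; `render_pattern()` exists for inspection and testing, not
  presentation.
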