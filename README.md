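# numbias

Simulation and analysis of connectedness-induced numerosity biases.

## The problem

Connecting pairs of dots with thin lines makes a cloud of dots appear
*less* numerous: the connected pairs are grouped into single perceptual
units, so number estimation — which operates on segmented objects rather
than raw local elements — counts fewer things. The size of this illusion is
an objective, indirect measure of perceptual grouping, and in neurotypical
adults it shrinks as autistic-like traits (the autism-spectrum quotient,
AQ) increase.

`numbias` is for psychophysicists and computational researchers who want a
fully tested, reproducible implementation of that paradigm: constrained
dot-pattern generation, QUEST-driven adaptive two-alternative forced-choice
(2AFC) sessions on synthetic observers with AQ-dependent grouping bias,
cumulative-Gaussian psychometric fitting, and the group statistics used to
analyse such experiments. Real trial logs can enter the same pipeline
through the trial-log CSV schema.

## The model in brief

For reference numerosity $N$ and condition $c$, a synthetic observer with
AQ score $a$ perceives

$$\hat N = N \cdot \big(1 - b(N)\,[c = \text{connected}]\big), \qquad
  b(N) = \beta_0(N) + \beta_1(N)\, a$$

with separate bias lines for the low ($N \le 50$) and high ($N = 100$)
numerosity regimes, and chooses the probe (numerosity $x$, always isolated
dots) with probability

$$P(\text{probe}) = \tfrac{\lambda}{2} + (1-\lambda)\,
  \Phi\!\left(\frac{x - \hat N}{w\,\hat N}\right)$$

(Weber-scaled noise $w$, lapse $\lambda$). Probes are placed by a
discretized-posterior QUEST procedure whose running PSE estimate is
perturbed by $\mathcal N(0, 0.5)$ dots each trial. Fitted psychometric
functions give PSE, JND $= 0.6745\,\sigma$, Weber fraction $=$ JND/PSE and
percent bias $= 100\,(\text{PSE}-N)/N$. Group analysis: AQ median split,
pooled-variance t tests, two-way repeated-measures ANOVA, Pearson
correlations, and default Bayes factors — the JZS Cauchy-prior factor for t
statistics and the Zellner–Siow (or stretched-beta) factor for
correlations, both by numerical integration.

## Worked example

```r
library(numbias)
set.seed(42)

run  <- run_experiment(run_config(seed = 42))   # 21 subjects x 1440 trials
fits <- analyze_trials(run$trials)              # RT trim + 168 psychometric fits
rep  <- report_stats(fits)
print(rep)
```

```
Connectedness-bias report: 21 subjects (AQ split at 20: 11 low / 10 high)
Low numerosities: bias -22.3% (low AQ) vs -8.2% (high AQ); t(19) = -6.06, p = 7.88e-06, logBF = 3.44
  bias-AQ correlation: r = 0.99, p = 3.31e-18, logBF = 15.17
N = 100: bias -9.2% vs -6.6%; t(19) = -2.38, p = 0.0282, logBF = 0.34; r = 0.52, logBF = 0.47
Baseline bias: -0.34% +/- 0.32% (p = 0.312)
Weber fractions: 0.152 (low AQ) vs 0.141 (high AQ); t(19) = 0.85, logBF = -0.49
```

Reading this: connected references are underestimated much more by low-AQ
than high-AQ observers at low numerosities (bias −22% vs −8%), the
per-subject bias correlates positively with AQ (less underestimation at
high AQ; the near-ceiling r = 0.99 reflects the generator's deterministic
bias–AQ line, see the vignette), the effect shrinks at N = 100, baseline
(isolated) biases are statistically indistinguishable from zero, and
discrimination precision (Weber fraction) does not differ between groups —
the evidence there leans to the null (logBF −0.49).

Desk calculators for published summary statistics:

```r
bf_ttest_jzs(3.32, 11, 10)   # BF10 = 12.13 (log10 BF10 = 1.084)
bf_pearson(0.72, 21)         # BF10 = 133.9 (log10 BF10 = 2.127)
```

Stimuli themselves:

```r
p <- place_connected(15)     # 15 dots, 3 same-colour connected pairs
validate_pattern(p)          # TRUE: spacing, lengths, no crossings, balance
img <- render_pattern(p, 40) # raster matrix for inspection
```

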