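---
title: "Bayesian population prevalence: model, algorithms and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian population prevalence: model, algorithms and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesprevalence)
```

## The inference problem

An effect is tested separately in each of $N$ participants with a test whose
false-positive rate $\alpha$ is controlled; $k$ participants come out
significant. The quantity of interest is the population prevalence $\gamma$:
the proportion of the population that would show a *detectable* effect if
tested with this experiment. "Detectable" matters — no sensitivity (power)
parameter is modeled, so $\gamma$ is the prevalence of effects the given
test can find, not of effects in some test-free ontological sense. A longer
experiment, or a more sensitive test, defines a different $\gamma$.

### Generative model and posterior

A participant drawn at random is significant with probability
$$\theta = \alpha + \gamma(1-\alpha),$$
combining true detections (the $\gamma$ fraction, assumed always detected)
with false positives (rate $\alpha$ among the rest). Then
$k \sim \mathrm{Binomial}(N, \theta)$, and $\theta$ is confined to
$[\alpha, 1]$. A uniform prior on $\gamma$ is uniform in $\theta$ on that
interval, so the posterior on $\theta$ is $\mathrm{Beta}(k+1,\,N-k+1)$
truncated to $[\alpha, 1]$, and the prevalence posterior follows by the
linear change of variables $\gamma = (\theta-\alpha)/(1-\alpha)$ with
Jacobian $1-\alpha$.

All distribution-function work (`dprev`, `pprev`, `qprev`) goes through the
regularized incomplete beta function (`pbeta`/`qbeta`), with the truncation
normalizer $P(\theta > \alpha)$ kept in log space: explicit quadrature is
never needed, and the functions stay stable for large $N$ and for sample
proportions deep in either tail. The CDF is evaluated through the upper
tail, $P(\Gamma \le \gamma) = 1 - P(\theta > \theta(\gamma))/P(\theta >
\alpha)$, and the quantile function switches between lower- and upper-tail
forms at $p = 0.5$, so both ends of the distribution keep full relative
precision.

The MAP estimate has the closed form
$\mathrm{clamp}\big((k/N - \alpha)/(1-\alpha),\,0,\,1\big)$: the Beta mode
on the $\theta$ scale is $k/N$, and clamping handles the truncation. A
sample proportion at or below $\alpha$ is fully explained by false
positives; the MAP is then 0, which is reported as a valid result (evidence
of low prevalence), never as an error.

### HPD intervals

Uncertainty is summarized by highest posterior density intervals, by
default at 50% and 96%. The posterior is unimodal, so the HPD interval at
mass $m$ is found by parameterizing candidates by the CDF value $t$ of
their lower endpoint: the candidate is
$[\,\texttt{qprev}(t),\ \texttt{qprev}(t+m)\,]$, and its width is minimized
over $t \in [0, 1-m]$ with `stats::optimize` at tolerance $10^{-9}$. This
is robust for skewed and boundary-mode shapes where density-threshold
root-finding is fragile. Two boundary rules replace the search when the
mode is not interior: if $k = N$ the interval is one-sided
$[\texttt{qprev}(1-m),\,1]$, and if $k/N \le \alpha$ it is
$[0,\,\texttt{qprev}(m)]$ — the one-sided HPD of a monotone density.

Because $k$ is discrete, the frequentist coverage of a fixed-mass HPD is a
step function of the true prevalence, hovering around the nominal level
rather than matching it. Exact enumeration over the $21$ outcomes of an
$N=20$, $\alpha=0.05$ experiment gives coverage $0.938$, $0.929$ and
$0.961$ of the 96% interval at $\gamma = 0.2$, $0.5$ and $0.8$ — the dip at
$\gamma=0.5$ is one binomial mass point whose interval's lower edge lies
just above $0.5$. The test suite checks this calibration by exact
enumeration (no Monte-Carlo noise) and separately by the simulation route.

### Reporting conventions

Endpoints and MAP values are reported to four decimal places by the print
methods, with percentages rounded to the nearest integer alongside (so
$[0.2516, 0.6958]$ reads "25% to 70%"). The within-participant criterion
$\alpha$ is a free parameter everywhere — nothing privileges 0.05, and the
prevalence of effects at any other criterion is obtained by passing that
criterion as `alpha`.

## Frequentist prevalence nulls

Two binomial null tests complement the posterior. The *global null*
($\gamma = 0$) asks how surprising $k$ or more significant participants
would be from false positives alone: $P(X \ge k)$, $X \sim
\mathrm{Binomial}(N, \alpha)$. The *majority null* ($\gamma < 0.5$) uses
success probability $\theta(0.5) = 0.5 + 0.5\alpha$; the implementation
takes any null prevalence $\gamma_0 \in [0, 1)$, of which these are the two
named cases. The "at least $k$" tail convention follows from the question
asked. Tails are computed by `pbinom(..., log.p = TRUE)`, so $-\log_{10} p$
is reported accurately even when $p$ itself underflows; the test suite
cross-checks against independent term-by-term log-space summation to
$10^{-12}$ relative. `prev_contour_grid` tabulates both tests plus MAP and
HPD lower edge over every outcome of a set of sample sizes, which is the
table behind the usual evidence-contour figures.

## Prevalence differences

**Between two populations.** With independent experiments A and B, draws
from each prevalence posterior (inverse-CDF sampling: uniforms through
`qprev`) are differenced. The posterior for $\delta = \gamma_A - \gamma_B$
is summarized by its median, a central equal-tail interval, and
$P(\delta > 0)$. A central interval is used rather than a sample-based HPD:
for bounded, skewed distributions the HPD-from-draws estimator is noisy,
while sorted-draw quantiles are stable and exactly recomputable from the
returned draws.

**Between two tests on the same participants.** Participants fall into four
latent classes with probabilities $\rho_{11}, \rho_{10}, \rho_{01},
\rho_{00}$ (detectable effect in both tests, only A, only B, neither), and
the observed data are the four joint significance counts. Each test detects
a true effect in its class with certainty and otherwise fires at its
false-positive rate, giving multinomial cell probabilities
$$P_{11} = \rho_{11} + \rho_{10}\alpha_2 + \rho_{01}\alpha_1 + \rho_{00}\alpha_1\alpha_2,\quad
P_{10} = \rho_{10}(1-\alpha_2) + \rho_{00}\alpha_1(1-\alpha_2),$$
$$P_{01} = \rho_{01}(1-\alpha_1) + \rho_{00}(1-\alpha_1)\alpha_2,\quad
P_{00} = \rho_{00}(1-\alpha_1)(1-\alpha_2),$$
which sum to one on the simplex. The perfect-sensitivity assumption mirrors
the single-test model's "detectable effect" reading. The target is
$\delta = \rho_{10} - \rho_{01} = \gamma_A - \gamma_B$ under a uniform
Dirichlet prior.

The posterior is approximated by sampling-importance-resampling. Proposals
come from the Dirichlet posterior that ignores test error
($\mathrm{Dir}(\text{counts}+1)$) — already close to the target whenever
the alphas are small — and are weighted in log space by the ratio of the
error-aware multinomial likelihood to the proposal kernel. The default of
50 proposals per retained draw keeps resampling duplicates rare at
realistic $N \le 100$. The effective sample size
$(\sum w)^2 / \sum w^2$ is always returned, and a warning fires when it
drops below 1% of the proposal count (this happens when the alphas are
large and asymmetric, pulling the target away from the proposal). One root
seed drives proposal generation and resampling sequentially, so results
are bit-reproducible. The test suite validates the sampler against
exhaustive evaluation on a $0.02$-step simplex grid.

## The simulation harness

`simulate_scenario` generates the kind of dataset for which prevalence
inference was designed: per participant, `n_trials` traces of
`n_timepoints` samples, like single-electrode ERP epochs. Effect
participants add $A_p\,g(t; L_p, w)$ to every trial, where $g$ is a
unit-peak Gaussian bump of width $w$ and the amplitude $A_p$ and latency
$L_p$ are drawn once per participant; the rest is additive Gaussian noise.
Latency draws are rounded to sample indices and clipped into range with a
warning.

Noise is temporally autocorrelated by default: white noise is convolved
with a Gaussian kernel (`noise_smooth`, default SD 6 samples) whose rows
are normalized to unit Euclidean norm, so the marginal SD stays exactly
`noise_sd` at every timepoint. Real electrophysiological noise is strongly
autocorrelated (recordings are lowpass-filtered well below the Nyquist
frequency), and this matters for inference: Bonferroni correction over 60
correlated timepoints is conservative, so the realized per-participant
familywise false-positive rate is well below the nominal level, whereas
with white noise it would sit at $1-(1-\alpha/T)^T \approx 0.049$. Setting
`noise_smooth = 0` recovers white noise, which the test suite uses when it
checks the sharp Bonferroni guarantee.

The analyses mirror standard practice. `within_participant_test` runs a
two-sided one-sample t-test of the trial values against zero at every
timepoint, Bonferroni-corrected over timepoints at familywise level 0.05; a
participant is significant if any timepoint survives, so the overall
prevalence posterior uses $\alpha$ = the familywise level.
`population_mean_test` is the conventional second-level analysis (t-test of
participant trial means across participants per timepoint, same
correction). `prevalence_timecourse` applies the prevalence posterior per
timepoint with $\alpha = 0.05/T$ — the false-positive rate of the test
actually applied at each timepoint. The t-tests assume Gaussian trial
noise, which the generator guarantees by construction; with real data a
distribution-free within-participant test can replace them, and the
prevalence machinery is agnostic to that choice.

### Scenario presets and their calibration

Four shipped scenarios illustrate the dissociation between population-mean
and prevalence inference; all use 60 timepoints, 100 trials, unit noise SD
and bump width 3:

| scenario | participants | amplitude | latency SD | effect fraction |
|---|---|---|---|---|
| A variable effect size | 20 | $\mathcal N(0, 1.5)$ | 1 | 1.0 |
| B variable alignment | 20 | 1.0 fixed | 12 | 1.0 |
| C few participants | 5 | $\mathcal N(1, 0.5)$ | 1 | 1.0 |
| D subgroups | 20 | 1.2 fixed | 5 | 0.5 |

The design intent: every scenario should show *no* significant
population-mean timepoint while carrying overwhelming prevalence evidence.
A achieves this with signed amplitudes that cancel in the mean; B and D
with latency variability that smears the group mean below the Bonferroni
threshold; C with so few participants that the across-participant t-test
has no power at the corrected level.

The latency SDs for B and D were fixed by a threshold calculation done once
at design time. For a bump of width $w$ smeared by latency SD
$\sigma_L$, the across-participant mean at the true latency is
$A\,w/\sqrt{w^2+\sigma_L^2}$ while the across-participant SD stays of order
the bump height, so the expected population-mean t-statistic is
$\approx \sqrt{N}\,m/s$ against a Bonferroni threshold of
$t_{19,\,1-0.05/120} \approx 3.88$. Values of $\sigma_L$ were chosen to put
that statistic clearly below threshold (B: $\sigma_L = 12$ gives
$\bar t \approx 3.1$) while leaving within-participant detection certain
(per-participant peak t $\approx 10$ at 100 trials). With narrower timing
spread (e.g. $\sigma_L = 8$ for B) the smeared group mean crosses the
threshold in a large fraction of runs and the dissociation disappears. In
D, exact recovery of the subgroup ($k = 10$ of 20) additionally requires
the per-participant familywise false-positive rate to stay near 1% — a
further reason the autocorrelated-noise default matters: the ten
effect-free participants must rarely contribute a spurious detection. The
acceptance tests verify the calibrated claims over 200 fixed simulation
seeds: A and B show no significant population-mean timepoint together with
global-null $p < 10^{-3}$ in at least half the runs, and D recovers
$k = 10/20$ in at least 90% — the configuration whose 96% HPDI reads 25%
to 70%.

### What the simulator does and does not emulate

It emulates trial-level Gaussian noise with realistic temporal
autocorrelation, between-participant amplitude and latency heterogeneity,
and subgroup structure. It does not emulate artifacts, non-Gaussian or
nonstationary noise, spatial (multi-channel) structure, trial-order
effects, or cluster-based corrections. Passing tests therefore show that
the inference machinery behaves correctly under its own assumptions, not
that any particular real dataset satisfies them.

## Problem sizes and numerical tolerances

Posterior normalization is verified to $10^{-6}$ by adaptive quadrature;
MAP against a $10^6$-point grid argmax; HPD intervals against brute-force
shortest-interval search on a 4001-point quantile grid to $2\times10^{-3}$;
binomial tails against log-space summation to $10^{-12}$ relative; the
$\alpha \to 0$ limit against the untruncated Beta density to $10^{-4}$. The
familywise-error check uses 2000 simulated null participants; the scenario
sweeps use 200 seeds per scenario; the paired-difference sampler is checked
against a $0.02$-step simplex grid. These sizes make the full suite run in
well under a minute while leaving Monte-Carlo standard errors comfortably
inside the asserted bounds.

## Known limitations

* The uniform prior on $\gamma$ is fixed; no informative or hierarchical
  priors.
* No pooling of information across participants (each participant's test
  stands alone), so sensitivity is lower than hierarchical models for
  homogeneous effects.
* Perfect within-class sensitivity is assumed in both the single-test and
  paired models; $\gamma$ is always "prevalence of detectable effects".
* The paired-difference SIR degrades (low effective sample size, with a
  warning) when false-positive rates are large; an MCMC scheme would be
  needed there.
* Inference requires at least one participant and is uninformative for
  $N = 1$ beyond the prior's reach; single-case studies gain little.
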