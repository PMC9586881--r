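# bayesprevalence

Population prevalence inference from within-participant statistics.

Most experiments in cognitive science and neuroscience ask whether the
*population mean* effect differs from zero. An alternative question is often
more relevant: **what proportion of the population would show the effect if
tested with this experiment?** That proportion — the population prevalence
γ, or within-participant replication probability — is what this package
estimates. It is aimed at researchers who test an effect separately in each
participant (psychophysics, EEG/MEG, single-unit work, deep-phenotyping
designs) and want a formal generalization from "k of N participants were
individually significant" to the population.

## The model

Each of N participants is tested individually with a test whose
false-positive rate α is controlled. If a fraction γ of the population
carries a detectable effect, any one participant comes out significant with
probability

    θ = α + γ(1 − α)

so the number of significant participants is k ~ Binomial(N, θ). With a
uniform prior on γ, the posterior on θ is Beta(k + 1, N − k + 1) truncated
to [α, 1], and mapping back through γ = (θ − α)/(1 − α) gives the posterior
over prevalence. From it the package computes:

* the **MAP estimate** `clamp((k/N − α)/(1 − α), 0, 1)`;
* **highest posterior density intervals** (HPDIs) at any credible level
  (50% and 96% by default), one-sided when the mode is at a boundary;
* exact binomial tests of the **global null** (γ = 0, success probability α)
  and the **majority null** (γ < 0.5, success probability θ(0.5));
* Monte-Carlo posteriors for **prevalence differences**, either between two
  participant samples or between two tests applied to the same participants
  (a four-class latent structure with false-positive-aware multinomial
  likelihood, fitted by sampling-importance-resampling);
* a **simulator** of multi-trial, time-resolved (ERP-like) experiments for
  studying when prevalence inference detects effects that population-mean
  inference misses.

## Worked example

Ten of twenty participants individually significant at α = 0.05:

```r
library(bayesprevalence)
prevalence(10, 20, alpha = 0.05)
```

```
Within-participant test outcomes: k = 10 of n = 20 significant (alpha = 0.05)
MAP prevalence: 0.4737
  50% HPDI: [0.3975, 0.5498]  (40% to 55%)
  96% HPDI: [0.2516, 0.6958]  (25% to 70%)
Global null (prevalence = 0):    -log10 p = 7.9
Majority null (prevalence < 0.5): -log10 p = 0.2
```

Read: the best guess is that about 47% of the population would show the
effect in this experiment; with 96% probability the prevalence lies between
25% and 70%. The chance of seeing 10 or more significant participants if
nobody had the effect is 10^−7.9 — orders of magnitude stronger evidence of
a population-level effect than a conventional p = 0.05 group result — while
there is no evidence that a majority shows the effect.

Comparing two independent samples (10/20 vs 3/15):

```r
prev_diff_between(test_outcomes(10, 20), test_outcomes(3, 15),
                  n_samples = 10000, seed = 42)
```

```
Prevalence difference posterior (between, 10000 draws)
  median delta = 0.2834; 96% central interval [-0.0509, 0.5747]
  P(delta > 0) = 0.960
```

The same analyses are available from the shell via the installed
`bayesprevalence` script (see `exec/`): `estimate`, `nulls`, `grid`, `diff`,
`paired-diff` and `simulate` subcommands emit JSON (scalars) and TSV
(tables); for example

```sh
bayesprevalence estimate -k 10 -n 20 --alpha 0.05 --mass 0.96
bayesprevalence simulate --scenario D --out timecourse.tsv
```

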