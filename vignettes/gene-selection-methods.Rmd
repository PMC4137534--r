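---
title: "Two-stage swarm-intelligence gene selection: model, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage swarm-intelligence gene selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmselect)
```

## The model

`swarmselect` addresses binary cancer classification from gene-expression
matrices whose defining pathology is dimensionality: thousands of genes,
tens of samples.  It composes two selection stages:

**Stage 1 — univariate filter.**  For each gene, per-class means
$\bar{x}_1, \bar{x}_2$, variances $v_1, v_2$ (unbiased, $n-1$
denominator) and standard deviations $s_1, s_2$ are computed over the
$n_1$ "normal" and $n_2$ "tumor" samples.  Three scores are offered:

* $t = (\bar{x}_1 - \bar{x}_2) / \sqrt{v_1/n_1 + v_2/n_2}$, the
  unequal-variance standardized mean difference, ranked by $|t|$;
* $\mathrm{PS} = (\bar{x}_1 - \bar{x}_2) / (s_1 + s_2)$, the
  signal-to-noise prediction strength, ranked by $|\mathrm{PS}|$;
* $F = v_1 / v_2$, the class-variance ratio, ranked ascending.

The top-$m$ genes ($m \in \{10, 50, 100\}$ canonically) become the search
space of stage 2.  The ranking is computed on the **full** dataset before
cross-validation; this mirrors the two-stage pipeline as practised, and the
selection bias it induces (CV accuracy estimates are optimistic relative to
fully nested selection) is documented rather than corrected.

**Stage 2 — wrapper search.**  A candidate solution is a continuous vector
$x \in [0,1]^m$; the decoded gene subset is $\{j : x_j > 0.5\}$ (exactly
0.5 excludes).  Its fitness is the mean accuracy, in percent, of a $k$-NN
classifier ($k = 5$, Euclidean distance) under seeded stratified 5-fold
cross-validation.  Candidates decoding to the empty set get fitness 0
without running CV — the search space is left untouched rather than
repaired.  Four maximizers are provided: particle swarm optimization (PSO),
cuckoo search (CS), shuffled frog leaping (SFL), and SFL with Lévy-flight
steps (SFLLF).

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| population | 50 | candidates per generation, all algorithms |
| generations | 200 | total budget; for SFL variants, organized as shuffles × cycles |
| `w` | 0.9 | PSO inertia: memory of the previous velocity |
| `c1`, `c2` | 2.1 | PSO cognitive/social pulls toward personal/global best |
| `vmax` | 1.0 | PSO componentwise velocity clamp (the full unit range; unspecified upstream, chosen here) |
| `alpha` | 1 | CS step scale multiplying the Lévy draw |
| `lambda` | 1.5 | Lévy tail exponent; Mantegna stability index β = λ |
| `pa` | 0.25 | CS nest-discovery (abandonment) probability — the canonical value, as none is fixed upstream |
| memeplexes × frogs | 10 × 5 | SFL partition (population 50) |
| shuffles | 20 | SFL re-mixing count → 200/20 = 10 worst-frog cycles per memeplex between shuffles |
| `dmax` | 0.5 | SFL componentwise step clamp (half the unit range; chosen here) |
| `LF` | 1 | SFLLF Lévy step scale |
| `k`, folds | 5, 5 | k-NN neighbours and CV folds |

## Design choices where the design was open

* **SFLLF step.**  What the Lévy factor multiplies is stated nowhere
  precisely.  A Lévy flight is defined by heavy-tailed step *lengths* with
  direction chosen separately; in the worst-frog update the direction is
  already supplied by $(X_b - X_w)$, so the step is
  $D = \mathrm{LF} \cdot |L| \odot (X_b - X_w)$ with $L$ a fresh Lévy
  vector.  A signed multiplier would move *away* from the best frog half
  the time, which contradicts the premise that Lévy steps improve SFL; with
  the positive-length reading, SFLLF dominates SFL on the smooth surrogate
  benchmark in this package's acceptance suite.  CS keeps the canonical
  signed Mantegna draw (its random walk is meant to be isotropic).
* **SFL uniform step.**  One scalar uniform draw per attempt (the classic
  frog-leaping rule), multiplying the whole difference vector; PSO, by
  contrast, draws one uniform per dimension per term — the common reading
  that gives dimension-wise exploration.
* **CS proposal comparison.**  A proposal is compared against a uniformly
  chosen nest and replaces it on strict improvement (random-nest variant);
  the best nest is exempt from abandonment, so elitism holds by
  construction.
* **SNR denominator.**  The default is $s_1 + s_2$; the literal
  $s_1 - s_2$ form is available (`denominator_mode = "paper"`) with the
  absolute denominator floored at $10^{-12}$, because it divides by zero
  whenever the class SDs coincide — almost certainly a typographical slip
  in the source formulation, but preserved for fidelity.
* **F ranked ascending** exactly as specified, although a two-tailed
  "distance from 1" ordering is statistically more natural; the latter is
  available via `f_rank = "two_tailed"` (smallest $|\log F|$ first).
* **Ties.**  Equal fitness keeps the incumbent (no churn); frog sorting is
  stable; ranking ties break to the lower gene index; k-NN distance ties
  break to the lower training index and split votes go to class 1.
* **Per-cell seeds.**  Grid cells derive their seed from a 32-bit FNV-1a
  hash of the cell key plus the master seed, so removing a grid entry
  never changes another cell's numbers.

## Numerical edge cases

* Degenerate genes (zero variance in both classes): $t$ is 0 when the
  means agree, a signed infinite sentinel ranked first otherwise; $F$ is 1
  with a warning when both variances vanish and $+\infty$ (never selected
  under ascending order) when only $v_2$ does.
* Positions are clamped to $[0,1]$ after every update, velocities to
  $\pm v_{\max}$, frog steps to $\pm d_{\max}$ componentwise.
* Mantegna's Lévy generator is defined for stability index below 2;
  exponents $\ge 2$ are clamped to 1.99 with a warning (`lambda` must lie
  in the open interval (1, 3); the default 1.5 is unaffected).  A literal
  power-law density $t^{-\lambda}$ would imply tail index $\lambda - 1$;
  the Mantegna reading (tail index $\lambda$) is used, and the acceptance
  suite checks the Hill estimate of the tail index at $\lambda = 1.5$
  against the band $[1.2, 1.8]$.
* `alpha = 0` (or `LF = 0`) yields exactly zero steps while still
  advancing the random stream, preserving determinism of surrounding code.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws a per-gene baseline from $N(7, 2^2)$ (a
log2-intensity-like scale) and adds i.i.d. $N(0, \sigma^2)$ noise,
identical across classes; a random subset of planted genes has its tumor
columns shifted by $\delta\sigma$.  Defaults ($\delta = 2$, $\sigma = 1$,
$30+30$ samples, 10 planted among 1000) emulate the *shape* of classic
two-class microarray benchmarks: thousands of genes, tens of samples, a
small informative subset.

It deliberately does **not** model intensity-dependent variance, gene-gene
correlation, batch effects, or heavy-tailed microarray noise.  A green
planted-recovery test therefore establishes that the pipeline finds
independent Gaussian signal of known effect size — not that it would rank
correlated, heteroscedastic real arrays equally well.  Conversely the
100% cross-validated accuracies reached on the synthetic benchmark are
properties of that easy, well-separated world (and of non-nested
selection), not performance claims about clinical data.

## Known limitations

* The PSO parameterization fixed by the benchmark defaults
  ($w = 0.9$, $c_1 = c_2 = 2.1$, so $c_1 + c_2 = 4.2 > 2(1 + w) = 3.8$)
  lies outside the swarm's stability region: particles oscillate rather
  than refine, and PSO does not reach the $-0.01$ sphere-surrogate
  threshold the other three algorithms meet.  The corresponding acceptance
  check is intentionally left failing rather than silently retuning the
  published parameters; an independent reference implementation reproduces
  the same plateau.
* Only binary classification and Euclidean k-NN are supported, by scope.
* Wrapper fitness caches by decoded mask per run; across runs, identical
  masks are re-evaluated (fold assignments depend on the cell seed).
* Config files are JSON (or flat CLI flags); no YAML parser is required at
  runtime.
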