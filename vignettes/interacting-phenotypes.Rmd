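---
title: "Interacting phenotypes on weighted social networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interacting phenotypes on weighted social networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipnets)
library(dplyr)
library(ggplot2)
```

## The question

When individuals adjust their phenotype to the phenotypes of their social
partners, part of each phenotype is caused by other individuals' genes —
indirect genetic effects. Classical interacting-phenotype theory treats
dyads or unstructured groups; `ipnets` places the same model on weighted
social networks so that two structural axes can be varied: how *connected*
a group is (network density) and how *assorted* connections are by phenotype
(homophily or heterophily). The package simulates replicate groups, measures
the emergent network structure, and checks the group-level statistics
against closed-form predictions.

## The phenotype model and its assumptions

Each of the $n$ individuals in a group expresses

$$z_i = a_i + e_i + \frac{\psi_g}{n-1}\sum_{j \ne i} s_{ij}\,(a_j + e_j),$$

with direct breeding value $a_i$, nonsocial environmental deviation $e_i$,
dyadic connection strength $s_{ij} \in [0,1]$ and a single interaction
coefficient $\psi_g$ shared by all individuals. Three assumptions matter:

* **No phenotypic feedback.** The social environment
  $\eta_i = \frac{1}{n-1}\sum_{j\ne i} s_{ij}(a_j+e_j)$ is built from
  partners' *nonplastic* values $a + e$, not their full phenotypes $z$. The
  model is therefore linear, every variance decomposition below is exact,
  and large $|\psi_g|$ cannot produce runaway phenotypes.
* **Self-exclusion.** $\eta_i$ never contains individual $i$'s own values.
  In dense networks everyone experiences almost the same social environment
  *except* for this exclusion, which mechanically generates a negative
  correlation between $a_i + e_i$ and $\eta_i$ — exactly $-1$ on an
  equal-weight complete network. This is the "pull to the mean".
* **The $n-1$ divisor.** $\eta$ is averaged over all *possible* partners,
  not over realized ones, so $\eta$ scales with realized connection
  strength and vanishes on the empty network.

Total breeding values add the effect of an individual's genes on others:
$t_i = a_i\,(1 + \psi_g \bar s_i)$ with $\bar s_i$ the mean connection
strength of $i$. The response of the group mean to a linear selection
gradient $\beta$ is computed as $\beta\,\mathrm{Cov}(t, z)$ (the
Robertson–Price identity); no generational reproduction step is simulated.

## Generating networks

Positions are uniform in the unit square; each individual then takes one
synchronous step of 15% of the distance toward its nearest neighbour
(computed from the input configuration, ties to the lowest index, so the
result is order-independent and deterministic under a seed). Connection
strengths decay as $s = e^{-d^2/r}$; edges below 0.05 are removed (strictly
below: boundary weights are kept). The square has no wraparound — edge
effects are part of the realized density, which is measured rather than
assumed. $r = 0$ is mapped to the empty network, the kernel's limit from
above.

Interaction preference multiplies each weight by
$0.5 + \sigma H L(|x_i - x_j|)$, where $L(d) = 1/(1+e^{20(d-0.5)})$,
$\sigma = +1$ for homophily and $-1$ for heterophily, $H \in [0, 0.5]$ is the
preference magnitude (0–0.2 studied), and $x = a + e$. Similar pairs are
multiplied by roughly $0.5 + \sigma H$, pairs at the average trait distance
0.5 by about $0.5$. Mode `"none"` bypasses the multiplier entirely, so the
baseline density experiment uses the unmodified kernel. Because the
multiplier never exceeds $0.5 + H < 1$, switching preference on also lowers
density relative to the unmodified network — an interaction of the two
structural axes that the closed-form model does not capture, which is why
results are always indexed by *measured* density and assortativity.

Density is the mean dyadic weight,
$\sum_{i<j} w_{ij} / \binom{n}{2}$. Assortativity is the Newman-style
weighted continuous-trait coefficient with each undirected edge counted in
both directions; it is `NA` (never silently 0) for empty networks or
zero-variance traits.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `n` | 50 (also 20) | group size |
| `r` | 16-value grid, 0–9 | interaction range; spaced at an increasing rate so realized densities cover [0, 1] |
| `move_fraction` | 0.15 | nearest-neighbour attraction step (results insensitive to it) |
| `edge_cutoff` | 0.05 | weights strictly below are removed |
| `psi_g` | 4 | interaction coefficient; large to make social effects visible, safe because there is no feedback |
| `beta` | 0.2 | linear selection gradient |
| `bv_dist` | uniform on $[-1,1]$ | so $G = 1/3$; `normal_01` gives $G = 1$ |
| `env_var` | 0.0625 | environmental variance ($E$), sd 0.25 |
| `H` | 9-value grid, 0–0.2 | homophily magnitude |
| `n_replicates` | 50 | groups per grid value |

The exact `r` grid only controls coverage of the density axis (results are
plotted against measured density); the default 16 log-spaced values from 0
to 9 give roughly even coverage. The homophily sweep's baseline range is
$r = 0.9$, which yields intermediate baseline density.

## Closed-form predictions and how they are compared

* $\bar z = (1+\psi_g\bar s)\,\bar a$ — tested as a slope-1 regression of
  group means on per-group predictions across a sweep.
* $\mathrm{Var}(z) = G + E + \psi_g^2\mathrm{Var}(\eta) +
  2\psi_g\mathrm{Cov}(a+e,\eta)$ — an algebraic identity when fed a group's
  own sample moments; asserted to $10^{-10}$ relative error on every group.
* $\mathrm{Var}(t) = (1+\psi_g\bar s)^2 G$ — exact on equal-weight complete
  networks; asserted at machine precision.
* $\Delta\bar z \approx (1+\psi_g\bar s)\,G\,(1+R\psi_g)\,\beta$ — an
  approximation; binned replicate means are compared within Monte-Carlo
  3-standard-error bands over the full density sweep.

**Estimating $R$.** The response prediction needs a genetic-assortment
coefficient. The package estimates it as
$\hat R = \mathrm{Cov}(a_i, \hat a'_i)/\mathrm{Var}(a)$ with
$\hat a'_i = \frac{1}{n-1}\sum_j w_{ij} a_j$ — the connection-weighted mean
of partners' breeding values under the *same* $n-1$ divisor convention as
$\eta$, with isolated individuals excluded. The alternative of normalising
by each row's weight sum was considered and rejected: it measures partner
composition irrespective of connection strength, converges to $-1/(n-1)$
under random association regardless of density, and over-corrects the
response prediction in sparse networks. The divisor convention makes
$\hat R$ the covariance of genes with the genetic part of the social
environment actually experienced, scales it with density as the response
equation requires, and still equals exactly $-1/(n-1)$ on complete
unit-weight networks.

## What the generator emulates — and what it does not

The generator reproduces the study conditions: spatially driven weighted
networks whose density is an emergent property of an interaction range,
random genetic composition per group, and preference-modulated connection
strengths. Passing tests therefore demonstrate internal consistency of the
model and its predictions *under these conditions*. They do not show that
real social networks decay as a Gaussian kernel of distance, that real
preference functions are sigmoidal, or that $\psi_g$ is constant across
individuals — in empirical networks, degree heterogeneity, temporal
rewiring and feedback could all move the statistics away from these
predictions. Multi-generation evolution, social selection and phenotypic
feedback are deliberately out of scope.

## Numerical choices

* Sample statistics use the $n-1$ denominator throughout; undefined
  correlations and assortativities propagate as `NA`.
* The attraction step is one synchronous move; sequential updates would make
  the result order-dependent.
* Replicate seeds come from a single `sample.int()` stream seeded at the
  master seed and laid out as a grid-by-replicate matrix, so sweeps are
  byte-reproducible and replicates share no stream. All seeds stay below
  $2^{31}$.
* Thresholding keeps boundary weights (strictly-below removal), so the
  cutoff is attainable in the output.
* Problem sizes in the test suite: the density sweep runs 16 grid values
  × 50 replicates at $n = 50$ (about 7 s), the homophily sweep 9 × 50;
  identities are checked on 100 random small instances against brute-force
  double-loop oracles.

## Worked sweep

```{r density-sweep, fig.width = 6, fig.height = 4}
sw <- sweep_density(sim_config(n = 50, n_replicates = 20), seed = 1)
autoplot(sw, y = "var_indirect")
autoplot(sw, y = "response")
```

The variance in indirect effects is hump-shaped in density — at low density
there is little social environment to vary, at high density everyone
experiences nearly the same one — while the response to selection rises
monotonically as connection strength amplifies each individual's genetic
reach.

```{r homophily-sweep, fig.width = 6, fig.height = 4}
hw <- sweep_homophily(
  sim_config(n = 50, r = 0.9, mode = "homophily", n_replicates = 20),
  seed = 2
)
autoplot(hw, y = "var_z_ratio", x = "assortativity")
```

Homophily aligns the social environment with the focal genotype: the
direct and indirect contributions act in concert, inflating within-group
phenotypic variance and the response to selection, while the group mean
stays flat.

## Known limitations

* $\hat R$ is an empirical estimator standing in for the analytic
  assortment coefficient; the response prediction is itself approximate, so
  agreement is statistical, not exact.
* With preference enabled, weights are halved on average ($0.5 \pm H$
  multiplier), so density and assortment cannot be varied independently
  within a homophily sweep.
* Assortativity is undefined on empty networks (`NA`), which excludes the
  $r = 0$ bin from assortment-indexed analyses.
* The uniform breeding-value option has bounded support; heavy-tailed
  genetic architectures would amplify the keystone-individual effects
  beyond what these simulations display.
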