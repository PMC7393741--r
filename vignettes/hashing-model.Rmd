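---
title: "The hashing demultiplexing model: mixtures, droplet formation, and cluster authentication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hashing demultiplexing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(hashDemux)
```

Sample barcoding (cell hashing, MULTI-seq) tags every cell with a
sample-specific hashtag oligonucleotide (HTO) before pooling, so that a
droplet (GEM) containing cells from two different samples betrays itself
by carrying two strong HTO signals. hashDemux implements the full
analysis chain around that idea: a per-sample Gaussian-mixture
classifier for multi-sample multiplets (MSMs), a generative
droplet-formation model that estimates the *invisible* multiplets —
same-sample multiplets (SSMs), which carry only one tag — an experiment
planner built on the same model, and a hypothesis-testing authenticator
for putative cell-type clusters.

## The MSM classifier

The input is an $n \times M$ matrix of HTO UMI counts
$\bar{x}_i^l$ over post-filtering, non-empty GEMs. Counts are first
CLR-transformed per sample (column-wise across GEMs):

$$x_i^l = \log \frac{\bar{x}_i^l + 1}
  {\bigl(\prod_{j=1}^{n} (\bar{x}_j^l + 1)\bigr)^{1/n}}.$$

The CLR formula is undefined at zero counts, which are routine in UMI
data, so a pseudocount (default $+1$, tunable via `pseudocount`) is
added before the transform.

Each transformed column is bimodal: GEMs without cells from sample $l$
carry only ambient antibody (the *low* component) while $l$-cell
enclosing GEMs were stained at full pre-pooling concentration (the
*high* component). `fit_sample_mixture()` fits
$\pi_{low}\,\mathcal N(\mu_{low},\sigma^2_{low}) +
 \pi_{high}\,\mathcal N(\mu_{high},\sigma^2_{high})$
by EM. The EM design choices, all of which matter for reproducibility:

* **Initialization** splits the column at its median and
  moment-matches each half, with priors $0.5/0.5$. Because the two
  modes are far apart in practice, this deterministic start converges
  to the same optimum on every run — the classifier needs no seed.
* **Convergence** at a relative log-likelihood change below $10^{-6}$,
  capped at 1000 iterations.
* **Variance floor** $10^{-6}$, so near-point-mass components (e.g.
  ties from identical counts) cannot collapse the likelihood.

`posterior_high()` applies Bayes' rule to give
$p_i^l = P(Z_i^l = high \mid x_i^l)$, computed in log space so that
values far in the tails underflow to exactly 0 or 1 rather than NaN.

Classification considers all $2^M$ sample subsets $U$ with
$$P(U) = \prod_{l \in U} p_i^l \prod_{l \notin U} (1 - p_i^l),$$
which sum to one by construction. The empty subset is the NEGATIVE
class (ambient-only GEMs, typically failed droplets), singletons are
single-sample droplets (SSDs), and larger subsets are MSMs of a
specific sample combination — at most $2^M + 1$ classes including
UNCLEAR. Because $P(U)$ factorizes, the maximizing subset is exactly
$\{l : p_i^l > 0.5\}$ and its probability $\prod_l \max(p_i^l, 1 -
p_i^l)$, so classification is $O(nM)$ rather than $O(n2^M)$; ties at
$0.5$ resolve to the smaller subset for determinism. The maximum
probability is the *confidence*; GEMs below the cutoff $c$ (default
0.8, following the observation that over 99 % of GEMs in real cohorts
clear that bar) are labelled UNCLEAR. The cutoff is applied to the raw
maximum subset probability, not renormalized over non-negative classes
— the two choices differ only for GEMs that are nearly NEGATIVE, which
fail the cutoff either way.

## The droplet-formation model

Pooled cells are partitioned into $X$ cell-assay droplets, each cell
independently and uniformly (probability $1/X$); a droplet is captured
as a sequenced GEM with probability $r_{cap}$. With $y_l$ cells in
sample $l$ and $Y = \sum_l y_l$, every quantity of interest is closed
form. Conditional on a droplet being non-empty
($P(\text{non-empty}) = 1 - (1 - 1/X)^Y$):

$$P(\text{singlet}) = \frac{Y(1 - 1/X)^{Y-1}}{X\,(1 - (1 - 1/X)^Y)},
\qquad
P(\text{SSD}_l) = \frac{(1 - (1 - 1/X)^{y_l})(1 - 1/X)^{Y - y_l}}
                       {1 - (1 - 1/X)^Y},$$

$$P(\text{MSM}) = 1 - \sum_l P(\text{SSD}_l), \qquad
P(\text{SSM}) = 1 - P(\text{singlet}) - P(\text{MSM}).$$

The per-sample decomposition
$P(\text{SSM}_l) = P(\text{SSD}_l)(1 - E[\#\text{singlet}_l] /
E[\#\text{SSD}_l])$ is algebraically identical to the complement route;
the package computes both and the test suite pins their agreement to
$10^{-12}$ over random parameter draws. `formation_rates()` accepts
real-valued $X$ and $y_l$ (maximum-likelihood estimates are never
integers); `simulate_formation()`, the Monte-Carlo counterpart used as
a correctness oracle, rounds them. The closed forms are exact, not
asymptotic: the tests verify exact equality with complete enumeration
of all $X^Y$ assignments for every configuration with $X \le 4$,
$Y \le 4$.

The *RSSM rate* $P(\text{SSM})/(P(\text{singlet}) + P(\text{SSM}))$ is
the fraction of multiplets left among SSDs after all MSMs are removed —
the irreducible noise floor of the experiment. Expected counts follow
from the capture rate: $n_{gem} = r_{cap} X P(\text{non-empty})$ GEMs,
of which $n_{gem}(1 - P(\text{MSM}))$ survive MSM removal.
`expected_msm_venn()` gives the expected GEM count of every specific
sample combination, the model-derived Venn diagram that can be compared
against the classifier-observed one.

## Estimating the latent parameters

Neither $X$, $r_{cap}$ nor the realized $y_l$ is observable. The
classifier observes $z_l$, the number of confidently classified GEMs
containing sample $l$, and the user supplies $Y$ (a hemocytometer
count). Since $z_l/r_{cap}$ of the $X$ droplets contain sample-$l$
cells, each $z_l$ contributes a Binomial$(X,\,1 - (1-1/X)^{y_l})$
likelihood term evaluated at $z_l/r_{cap}$ — a real number, so the
binomial coefficient uses its log-Gamma extension.

A structural point that shapes the implementation: the $M$ counts
$z_l$ face $M + 1$ free parameters, and along the ridge of exact fits
the likelihood is *not* flat — the height of a binomial pmf at its
mode grows as $X$ shrinks, so the unconstrained maximizer drifts to
the small-$X$ boundary and implies absurd SSM rates. The dataset,
however, carries one more observable: the total number of
cell-enclosing GEMs, $n_{gem}$ (the matrix rows minus NEGATIVEs). The
default estimator therefore anchors
$r_{cap} X (1 - (1-1/X)^Y) = n_{gem}$, which makes the system exactly
determined and, on data simulated from the model itself, recovers the
generating rates to within a few percent. Alternatives are exposed for
completeness: `fix_X` pins the droplet count to a profiled equipment
value (the recommended practice — profile once, reuse), `profile =
TRUE` reports the profile log-likelihood over an $X$ grid, and
`anchor = "none"` gives the raw joint MLE with the degeneracy
described above. Optimization runs Nelder-Mead from a deterministic
grid of ten multi-starts ($X$ log-spaced between the feasibility floor
and $10Y$, softmax-parameterized sample weights started at the
observed $z$ proportions and at equality), followed by a BFGS polish;
the `seed` only jitters the starts, and estimates agree across seeds
to well under $10^{-4}$ relative.

## The experiment planner

`plan_experiment(X, Y, M, r_cap)` evaluates the closed forms at an
equal split $y_l = Y/M$ (kept real-valued — the planner's stated
assumption, no rounding) and returns the expected singlet/MSM/SSM/RSSM
rates and GEM counts; `sweep_plan()` evaluates grids, e.g. to find the
smallest $M$ meeting an RSSM target. Inputs outside the ranges typical
of droplet equipment (X 60K–100K, Y 1K–80K, M 1–20) warn rather than
fail, since they are soft UI-slider bounds, not model constraints. Two
facts worth knowing: the singlet rate depends only on $X$ and $Y$
(splitting into more samples converts SSMs into detectable MSMs
without changing the singlet count), and the popular fixed-doublet-rate
rule $(1 - 0.01)^{Y/1000}$ is numerically indistinguishable (within
0.5 %) from this model at $X = 100K$ across the planning range.

## Cluster authentication

A cluster of GEMs proposed as a novel cell type can be interrogated
through its MSM fraction. If the cluster is *phony* — multiplets
spanning $k \ge 2$ distinct real types — then every member is a
multiplet, and a member is an SSM (rather than MSM) only when all its
cells carry one tag: probability $\sum_l q_l^k$ under sample
proportions $q$. The default phony expectation uses the minimal order
$k = 2$, i.e. $1 - \sum_l q_l^2$ — $75\,\%$ for four equal samples —
which is the *minimum* MSM fraction a phony cluster can have: a
conservative choice that only makes the phony test harder to pass.
(The published per-cluster tables use exactly one shared phony value
per dataset, matching this construction; supplying formation
parameters instead averages $1 - \sum_l q_l^k$ over the model-implied
truncated distribution of $k$, which is strictly larger.) If the
cluster is *pure*, its MSM fraction is whatever self-collision the
formation model predicts for a population of its own size: the
underlying type population $y_t$ is recovered by inverting
$n_G = r_{cap} X (1 - (1-1/X)^{y_t})$ and the model is evaluated on
$y_t$ cells split as $q$ — small clusters almost never self-collide,
so the pure expectation grows with cluster size.

`authenticate_counts()` runs two one-sided exact binomial tests: upper
tail at the pure expectation, lower tail at the phony expectation
(both via `binom.test`, $\alpha = 0.05$ by default, no multiplicity
correction across clusters — callers screening many clusters should
adjust externally). Verdicts: **pure** if only phony is rejected,
**phony** if only pure is rejected, **mixture** if both (real datasets
show this for gating super-clusters), and **indeterminate** if neither
— small clusters are reported as such instead of being forced into a
verdict. NEGATIVE and UNCLEAR members are excluded from the counts.

## The synthetic-data generator

`sim_hashing()` builds datasets with ground truth for testing and
benchmarking. Per-sample SSD profiles draw the own-tag count from an
on-target distribution and other tags from background distributions;
defaults are the four-sample reference profile in
`default_hto_profile()` (on-target means 2789/832/1117/717 against
backgrounds of roughly 16–77, with one deliberately brighter sample,
reflecting the staining inconsistencies of real cohorts). Raw counts
are moment-matched lognormals rounded to integers — the published
protocol specifies only means and standard deviations; lognormal is
chosen for positivity and the right skew of UMI counts, and yields
CLR columns with the Gaussian-mixture shape the classifier assumes.
For $M > 4$ samples, where no reference values exist, extra samples
get a mid-range profile (on-target mean 800, sd 650; background mean
40, sd 20) chosen once as realistic for TotalSeq-style hashing.

Droplets are assembled to hit an exact cross-sample-multiplet target:
$\lceil f \cdot n \rceil$ droplets are doublets of SSDs from two
distinct samples (drawn proportionally to the sample ratios), an
optional knob adds same-sample doublets, and the rest carry one SSD.
Multi-SSD counts are $\sum_i w_i x_i$ with independent
$w_i \sim \mathcal N(1, 0.04)$, rounded and floored at zero;
single-SSD droplets inherit their SSD's counts unchanged. All
randomness flows from one seed.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: ambient-antibody gradients correlated
with droplet size, batch effects between lanes, doublets of order
three and above (available only via repeated merging), and the
long-tailed barcode-swapping artifacts of real sequencing. It emulates
the feature the classifier actually relies on: well-separated bimodal
per-sample intensity structure with realistic weight noise on merged
droplets.

## A worked run

```{r}
sim <- sim_hashing(sim_config(M = 4, n_droplets = 4000,
                              msm_fraction = 0.10, seed = 42))
fit <- demux(sim$counts, total_cells = 4400)
summary(fit)
```

```{r}
cmp <- table(truth = sim$truth$is_msm,
             called = rowSums(attr(fit$classification,
                                   "membership")) >= 2)
cmp
```

```{r, fig.width = 7, fig.height = 5}
plot(fit)
```

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant CLR columns and
single-GEM matrices transform to zeros; the EM refuses columns with
fewer than four values or zero variance; `r_cap = 0` simulations
return zero GEMs; $X = 1$ uses the $0^0 = 1$ convention so a lone
droplet with one cell is a singlet. Simulation-based checks in the
test suite use 1,500–20,000 droplets and $10^4$–$10^5$ formation
replicates — sizes at which every Monte-Carlo interval in the suite is
a fraction of the tested tolerance while the whole suite runs in well
under a minute. The largest routine fit, 20,000 droplets with four
samples, takes about one second.

## Limitations

The formation model ignores cell volume: occupancy is exactly
binomial, with no crowding penalty, and cell-size differences between
types are invisible to it. The SSM rate is *inferred*, never observed
— its trustworthiness rests on the MSM predictions matching the
classifier, which the Venn comparison checks. With $M = 2$ samples the
pooling dilution is weakest and the low/high modes may approach each
other; the mixture assumption can then degrade. Authentication
verdicts inherit the quality of the clustering they are given: a
poorly separated clustering yields mixture verdicts by construction.
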