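---
title: "Edge credibility for learned Bayesian networks: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge credibility for learned Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgecred)
```

## The model

A discrete Bayesian network is a DAG *G* plus conditional probability
tables Θ; under the Markov condition each node is independent of its
non-descendants given its parents, and the joint factorizes as
p(x₁,…,xₙ) = ∏ₖ p(xₖ | Pa(xₖ)). Structure learning searches for a
high-scoring *G*, but with finite data many structures explain the data
almost equally well. `edgecred` quantifies that ambiguity at the level of
individual edges.

The observable it models is the **edge state** of an unordered variable
pair across an ensemble of networks learned from bootstrap replicates of
the data: left-directed, absent, or right-directed (pairs are canonically
oriented lexicographically, so "right" always means smaller-name →
larger-name). The three counts per pair are treated as a multinomial
sample; with the conjugate Dirichlet(⅓, ⅓, ⅓) prior — a single
pseudo-observation split evenly, so no state is favoured — the posterior is
Dirichlet(prior + counts). Everything reported downstream is a functional
of that posterior:

* per-state means and equal-tailed credible intervals (each state's
  marginal is a Beta distribution);
* edge **existence**, by aggregating the two directed states:
  Beta(α_left + α_right, α_none);
* edge **direction** given existence: Beta(α_right, α_left);
* the **MAP state** per pair, and a thresholded MAP graph.

Modelling the pair jointly matters. The Beta-Binomial baseline
(`beta_binomial_posteriors()`) models each *ordered* arc independently:
an association that flips orientation across the ensemble splits its mass
over two posteriors and can fail the 50% selection rule even for the most
frequent arc in the ensemble. The suite demonstrates exactly this with an
arc present in 21 of 100 networks: posterior mean 22%, 95% interval
(14%, 30%), classified non-existent.

### Assumptions

Rows are complete i.i.d. categorical observations. Missing values are
rejected rather than imputed (imputation would silently change the census),
and continuous variables must be discretized upstream. The bootstrap treats
the empirical distribution as the data-generating one; time-series or
otherwise dependent rows would need a block bootstrap, which is out of
scope here.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 100 | bootstrap subsets = ensemble size; counts per pair sum to `k` |
| `n` | `nrow(D)` | rows per subset, drawn with replacement (may exceed `nrow(D)`) |
| `prior` | (⅓, ⅓, ⅓) | Dirichlet pseudo-counts over left/none/right |
| `level` | 0.95 | credible-interval mass |
| `threshold` | 0.75 | existence-mean cutoff for the MAP graph |
| `score` | `"bdeu"`, `ess = 1` | hill-climbing objective; `"bic"` selectable |
| `engine` | `"analytic"` | conjugate closed form; `"mcmc"` samples instead |

Sampling **with replacement** is the deliberate reading of "i.i.d.
resampling": i.i.d. draws from the empirical distribution are the
bootstrap, and they are the only way a subset can be larger than the source
data — a regime the sample-size experiments use on purpose (10,000-row
subsets from 1,000 rows).

The **75% threshold** is applied to the *posterior mean* of edge existence.
A MAP-density or three-state-mass rule would also be defensible; the mean
was chosen because it is the quantity the existence Beta directly
summarizes, it is monotone in the counts, and it needs no density
estimation. It is a plain argument, not a constant.

**Equal-tailed intervals** are the default (quantiles of the Beta marginals
or of the MCMC draws); highest-posterior-density intervals are available
via `credible_interval(type = "hpd")`. Equal-tailed was preferred as the
default because it is uniquely defined and reproducible without any
density or sorting convention entering the headline numbers.

## The two posterior engines

The analytic conjugate path is exact and is the default. The MCMC path
exists for fidelity to the sampling formulation of the method and as the
extension point for non-conjugate priors. It is a Metropolis-within-Gibbs
sampler on the gamma augmentation of the Dirichlet: with independent
gᵢ ~ Gamma(αᵢ, 1), the normalized vector g/Σg is Dirichlet(α), so the
sampler random-walks each coordinate yᵢ = log gᵢ against the univariate
target αᵢ·y − eʸ. The three coordinates are independent, which keeps
mixing fast even for near-flat posteriors; several chains run side by side,
per-coordinate step sizes adapt towards 44% acceptance during burn-in and
are frozen afterwards, and split-R̂ across all chains above 1.1 raises an
error rather than returning unreliable draws. The conjugate path is the
oracle: the suite requires MCMC means within 0.01 of the analytic means
across seeded random count vectors, and agreement of the aggregated
existence mean computed from draws.

## Structure search

Hill climbing starts from the empty graph and applies the best
single-edge move (add / delete / reverse) until no move improves the
score. Because the downstream census is a function of which local optimum
each subset reaches, determinism is part of the contract: moves are
scanned in a fixed order — deletions, then reversals, then additions, then
lexicographic on (parent, child) — and exact ties go to the earliest move
scanned. Random restarts (off by default) permute the scan order under
derived seeds and keep the best-scoring result. Both scores are
decomposable, so move deltas touch only the affected families, which are
memoized per (child, parent-set).

BIC is the maximized multinomial log-likelihood minus ½·log(N) per free
parameter; BDeu is the marginal likelihood under the equivalent-uniform
Dirichlet prior at equivalent sample size `ess`. On a single undirected
dependency both scores are orientation-invariant (Markov equivalence), so
which direction the learner emits is a tie broken by scan order — one
reason direction posteriors spread across the ensemble and deserve explicit
modelling.

### Score choice in the sample-size experiment

The end-to-end experiment on the five-node benchmark uses the **BIC**
learner rather than the default BDeu. The experiment's claim is about
information: an edge should be admitted only when the data carry enough
evidence for it, and BIC ties admission to a likelihood gain exceeding
½·log N per parameter. BDeu at small `ess` behaves differently in the
extreme-sparsity regime this fixture creates deliberately: with a single
positive row of a 1-in-25000 variable, adding the true-but-undetectable
parent yields a *positive* BDeu delta (+0.35 on a representative
1000-row draw, against −1.98 for BIC), so the rare pair gets asserted from
one observation — the opposite of the calibrated "not enough data" answer
the experiment probes. Both scores remain available everywhere; this
paragraph is the record of why the experiment pins one of them.

## Synthetic generators

`fixture_five_node()` is a five-variable diagnosis network (smoking history
H, bronchitis B, lung cancer L, fatigue F, chest X-ray C; edges H→B, H→L,
B→F, L→F, L→C) whose pinned conditionals span four orders of magnitude:
P(L=1|H=0) = 1/25000, P(L=1|H=1) = 1/400, P(B=1|H=1) = 1/20. The free
entries are package defaults chosen once: P(H=1) = 0.2 and
P(C=1|L=1) = 0.5 — jointly fixing the rarest three-variable event
(H=0, L=1, C=0) at exactly 1/62500 — plus P(B=1|H=0) = 0.01,
P(C=1|L=0) = 0.02 and fatigue probabilities 0.05/0.10/0.50/0.75 for
none/B-only/L-only/both. The most probable joint configuration has
probability ≈ 0.74, so the fixture covers roughly 0.75 down to 4·10⁻⁵.

`fixture_lucas()` reproduces the 12-variable, 12-edge lung-cancer benchmark
*structure* (five colliders, two common causes, and the isolated fair coin
Born_an_Even_Day at exactly 0.5 per state). The original benchmark's CPTs
are not bundled: the default parameters are this package's own synthetic
choices (moderate root rates 0.15–0.5, strong but non-deterministic child
dependencies 0.05–0.95, documented in the function help) and can be
replaced wholesale via the `cpts` argument by users holding the reference
tables. Confusion-rate numbers obtained with the default parameters
therefore characterize the *protocol*, not the original benchmark.

What the generators deliberately do not emulate: missingness, measurement
noise, continuous signals, dependent rows, and latent confounders. Passing
tests on these fixtures show the machinery is correct and that the
credibility signal behaves as designed under known ground truth; they do
not show that any particular real dataset is large enough — that is
precisely the question the credibility report is meant to answer per
dataset.

## Numerical choices and degenerate inputs

* Categories are the sorted distinct values per column — deterministic
  across platforms; encoding is pure relabelling.
* MAP-state ties resolve to "none": no edge is asserted without a strict
  winner. A direction tie inside the MAP graph resolves to the canonical
  (right) orientation; with continuous posteriors exact ties essentially
  only arise from symmetric counts.
* `forward_sample()` uses inverse-CDF draws against CPT column cumsums
  (with a 1e-15 guard so a cell of exactly 1.0 can never be skipped by
  floating-point roundoff).
* `fit_cpts(smoothing = 0)` refuses unobserved parent configurations
  instead of emitting NaN rows; any positive smoothing defines all rows.
* Variable elimination rejects zero-probability evidence ("impossible
  evidence") instead of renormalizing a zero vector.
* Zero-row datasets score 0 under BDeu (empty product); the learner itself
  requires at least one row.
* Per-subset seeds are drawn up front from one master-seeded stream, so
  subset *i* is reproducible without generating subsets 1…i−1; all seeded
  entry points restore the caller's RNG state.

## Problem sizes used by the shipped experiments

The test suite and `scripts/acceptance.R` run the full pipeline at
10³ and 10⁴ samples with k = 200 resamples on the five-node fixture
(the two-scale experiment: strong pairs reach existence means above 0.9 at
10⁴ while the 1-in-25000 pair's MAP state stays "none" at 10³), 50-vector
MCMC-vs-conjugate sweeps, 100 random exact-inference queries on the 5- and
12-node fixtures against full-joint enumeration, and CPT recovery from 10⁵
sampled rows. These sizes were chosen as the smallest that exercise every
qualitative regime the method distinguishes (saturated, intermediate, and
information-starved pairs).

## Known limitations

* The MAP graph may contain directed cycles by construction; it is a
  per-pair summary, not a joint structure estimate. Users needing a DAG
  should treat it as a candidate set for expert triage.
* The posterior is over *edge states given the learner*: a biased learner
  yields confidently wrong censuses. The learner is pluggable precisely so
  this sensitivity can be probed.
* Pairs are modelled independently; the census discards correlations
  between edges (e.g. v-structure constraints), so the method cannot
  distinguish "either of two competing edges" from "both independently
  uncertain".
* A pair with high existence probability but a flat direction posterior is
  *compatible with* a latent confounder, but the package only surfaces the
  pattern; it performs no latent-variable inference.
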