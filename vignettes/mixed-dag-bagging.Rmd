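---
title: "Learning bootstrap-aggregated DAGs over mixed continuous and binary variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning bootstrap-aggregated DAGs over mixed continuous and binary variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Molecular network studies increasingly need *directed* dependence
structures over variables of mixed type: protein or transcript abundances
are continuous, while clinical endpoints such as treatment response are
binary. Treating the binary outcome as continuous, or discretizing the
continuous measurements, both discard information and distort edge
directions precisely where they matter most — on the edges touching the
outcome. `dagboot` learns a directed acyclic graph (DAG) over such mixed
data directly, and stabilizes the notoriously noisy single-run structure
estimate by bootstrap aggregation.

## Model and score

Each node is modelled conditionally on its parent set. A continuous node
$X$ is Gaussian given its parents (linear regression, binary parents
entering as 0/1 regressors); a binary node $Y$ follows a logistic
regression on its parents. The graph score is a decomposable BIC:

$$
\mathrm{score}(G) \;=\; \sum_{X\ \mathrm{continuous}} \Big[ n\log\frac{\mathrm{RSS}_X}{n} + |pa_X|\log n \Big]
\;+\; \sum_{Y\ \mathrm{binary}} \Big[ -2\,\ell_Y + |pa_Y|\log n \Big],
$$

where $\mathrm{RSS}_X$ is the residual sum of squares of the least-squares
fit of $X$ on its parents, $\ell_Y$ the maximized binomial log-likelihood,
and $n$ the sample size. Lower is better. Intercepts are always included
and never penalized.

A note on the continuous fit term: a raw $\mathrm{RSS}/n$ term is not on
the deviance scale of the binary term and would be dwarfed by the
$\log n$ penalty, so the two node kinds could not be summed meaningfully.
The package therefore uses the Gaussian deviance form
$n\log(\mathrm{RSS}/n)$ — the $-2\times$ profile log-likelihood up to an
additive constant — as the default, which makes continuous and binary
node scores commensurable. The raw form remains available via
`search_config(form = "literal")` for comparison.

### Numerical safeguards

* **Logistic fits** are run by iteratively reweighted least squares, at
  most 25 iterations, converged when the largest coefficient change drops
  below `1e-8`. Under complete or quasi-complete separation (a parent
  configuration perfectly predicting $Y$) the unpenalized MLE diverges;
  the fit is then repeated with a small ridge penalty ($\lambda =
  10^{-4}$, intercept excluded) and a warning is recorded. Fitted
  probabilities are clipped to $[10^{-10}, 1-10^{-10}]$ before logs.
* **Single-class binary columns** (which arise routinely in bootstrap
  resamples) are scored as the constant model with clipped probabilities
  and flagged, rather than aborting the replicate.
* **Near-deterministic continuous children** have their RSS floored at
  $10^{-10}\times$ the child's total sum of squares, with a warning, so a
  collinear fit cannot produce an infinite score.

## Hill-climbing search

Starting from the whitelist-only graph (empty without priors), each step
enumerates all eligible moves — adding an absent, non-blacklisted,
acyclic-safe edge; deleting a present non-whitelisted edge; reversing a
present non-whitelisted edge whose reversal is non-blacklisted and
acyclic-safe — and applies the move with the most negative score change,
stopping at a local minimum (no move improves by more than `tol`,
default 0) or after `max_steps` moves (default 1000). Ties are broken
deterministically: add before delete before reverse, then by source, then
by target position, so a run is exactly reproducible.

Two pieces of incremental state keep steps cheap. Because the score is
decomposable, a move only re-scores the children whose parent set changed
(one node for add/delete, two for a reversal), and per-child delta tables
are re-evaluated only for those children. Acyclicity is checked against a
maintained transitive-closure matrix: adding $u \to v$ is safe iff no
directed path $v \rightsquigarrow u$ exists, an $O(1)$ lookup. Edge
additions update the closure incrementally (ancestors of $u$ reach
descendants of $v$); deletions and reversals recompute it, a deliberate
trade of micro-efficiency for correctness — the maintained index is
validated against a from-scratch depth-first-search closure in the test
suite. The search loop itself is implemented in C++ (RcppArmadillo), with
continuous-node scores computed from a precomputed centered cross-product
matrix so each candidate evaluation is a small linear solve independent
of $n$.

### The parent-set cap

`search_config(max_parents = NULL)` resolves to $\lceil \log n \rceil$.
This guard matters on bootstrap resamples: a resample of $n$ rows carries
only about $0.63\,n$ distinct ones, and when $p \approx n$ an
unconstrained BIC search can chain additions toward an interpolating fit
(RSS $\to$ 0), producing degenerate ensemble members. A cap growing like
$\log n$ keeps each per-node regression well-conditioned at every sample
size while leaving realistic in-degrees (sparse biological networks have
in-degrees of a few) untouched. Set `max_parents = Inf` to disable it.

## Bootstrap aggregation

A single greedy search is unstable: many edges reflect chance
correlation. `bagged_dag()` learns one DAG on each of $B$ bootstrap
resamples (default $B = 100$) and summarizes the ensemble by the DAG
minimizing the mean structural Hamming distance (SHD) to its members.
SHD counts the additions, deletions and reversals needed to turn one DAG
into another, a reversal costing one unit:

$$
d(G, \tilde G) = \sum_{i<j} \max\{|A_{ij}-\tilde A_{ij}|,\ |A_{ji}-\tilde A_{ji}|\}.
$$

The mean SHD to the ensemble has a closed form. With $f_{ij}$ the
fraction of members containing $i \to j$ and the *generalized selection
frequency* $gp_{ij} = f_{ij} + \tfrac12 f_{ji}$,

$$
\frac1B \sum_b d(G, G_b) = \sum_{e \in E(G)} (1 - 2\,gp_e) + C,
$$

with $C$ the total edge mass over unordered pairs — a constant in $G$.
(Including $i\to j$ costs $1-f_{ij}$ per member on that pair; excluding
the pair costs $f_{ij}+f_{ji}$; the difference is $1-2gp_{ij}$.) So an
edge lowers the aggregation score exactly when $gp_e > 1/2$, and the
consensus is found by the same hill-climbing machinery with the edge
terms as deltas, under the same acyclicity constraint and deterministic
tie-breaking. The closed form is verified against the brute-force mean
SHD exactly (to $10^{-12}$) in the test suite. There is no user-facing
frequency cutoff: the threshold is implied by the score.

### Priors

Whitelist edges are forced into every graph, blacklist edges excluded
from every graph, implemented by removing moves from the eligible set.
`bag_config(whitelist_fraction = w)` supports a two-stage design where
edge directions learned from, say, time-course data serve as priors of
mixed quality: each bootstrap replicate receives an independent random
subset (fraction $w$) of the whitelist, and with $w < 1$ the aggregation
step itself is left unconstrained, so prior edges the data do not support
tend to be voted out. Subsets containing a directed cycle (possible when
priors include both directions of a pair) are re-drawn up to 100 times,
then offending edges are dropped with a warning.

## The synthetic-data generator

`random_mechanism()` + `simulate_dataset()` emulate the data-generating
process used throughout the package's experiments:

* topology: a uniform random permutation as topological order with
  `n_edges` order-respecting pairs drawn uniformly;
* continuous children: $X_i = \sum_{j \in pa_i} \beta_{ij} X_j +
  \epsilon_i$ with $|\beta| \sim U[0.3, 0.5]$, random sign; parentless
  continuous nodes are standard normal;
* noise calibration: each node draws a target signal-to-noise ratio
  (ratio of signal to noise standard deviation) uniformly from
  $[0.5, 1.5]$; the noise scale is set against the *realized* empirical
  signal standard deviation of the generated sample, which matches the
  SNR definition exactly rather than approximately;
* noise families: gaussian, $t_3$, $t_5$, and mean-centered
  Gamma(shape 1, scale 2), each standardized to unit variance by its
  analytic standard deviation (e.g. $t_3$ divided by $\sqrt3$) before
  scaling — these probe robustness to heavy tails and skewness;
* binary children: $P(Y=1) = \mathrm{logit}^{-1}(\gamma_0 + \sum_j
  \gamma_j X_j)$. The logistic link is the natural reading of a
  "logistic regression" mechanism even where a linear-probability formula
  might be written down. Coefficient magnitudes default to
  $U[1, 2]$ with $\gamma_0 = 0$: strong enough that parent effects on a
  binary node are detectable at $n \approx 100$, while keeping both
  classes populated.

`mixed_motif_mechanism()` provides the named low-dimensional fixture used
for mixed-type experiments: a binary node that is the child of two
continuous parents and the parent of one continuous child, embedded in a
random continuous backbone (11 nodes, 8 edges by default) — the shape of
a clinical outcome wired between upstream biomarkers and a downstream
readout.

What the generator does **not** emulate: the correlation structure of
real proteomics panels (block correlation from complexes and shared
regulation), missingness, batch effects, or count/dropout distributions.
Passing the simulation-based checks therefore demonstrates correctness of
the algorithms under the stated mechanisms, not performance guarantees on
any particular real data set.

## Evaluation harness

`skeleton_metrics()` scores undirected pair recovery; an estimated pair
is correct if the truth links the two nodes in either direction.
`directed_mixed_metrics()` restricts to ordered continuous–binary pairs
and requires the exact direction; its FDR denominator counts only
estimated mixed-pair edges, consistent with the subset definition of its
power. Power is `n_correct / n_true`, FDR `(n_est − n_correct) / n_est`,
F1 the harmonic mean of precision ($1-$FDR) and recall. Zero
denominators yield 0 by convention — no discoveries means no false
discovery rate, and F1 is 0 whenever nothing correct was found.
`run_experiment()` replicates simulate→learn→score runs with full seed
derivation, records failures rather than dropping them, and can redraw
the generating mechanism per replicate (`redraw_mechanism = TRUE`) to
average over topologies as well as data.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run desk-scale versions of the
experiments: the null-graph false-positive comparison at $p = 100$,
$n = 100$, $B = 25$ (20 and 10 replicates respectively); the
noise-robustness experiment at $p = 102$, 109 edges, $n = 102$, $B = 25$,
with 20 (tests) or 10 (script) replicates per noise family and the
mechanism redrawn per replicate; and the prior-edge experiment at
$p = 50$, 50 edges, $n = 100$, $B = 10$. $B = 25$ rather than the
default 100 keeps ensemble noise modest at these sizes while the
experiments stay quick to re-run.

## A known scale limitation

The false-positive suppression of aggregation is strongest when the pool
of chance-correlation candidate edges greatly exceeds what a single
search accepts — the regime of large $p$ relative to $n$ (hundreds to
thousands of nodes), where any individual spurious edge appears in only a
minority of bootstrap members and is voted out. When $p \approx n \approx
100$, a handful of strong sample correlations clear the BIC acceptance
threshold so comfortably that they are re-selected in most resamples and
survive aggregation: the consensus then retains a few dozen false edges
rather than a handful, even though it still removes roughly 90% of the
single-run false positives. This is a property of the method at that
scale, not of the implementation — at fixed $p = 100$ the consensus
false-positive count *rises* with $n$ (chance edges become more stable)
while the single-run count falls. Users working at small $p$ should
treat consensus edges with moderate $gp$ (just above $1/2$) with
caution, or raise $B$ and inspect `consensus_edges()` frequencies.

## Other design choices

* The search starts from the whitelist-only graph; any acyclic
  whitelist-consistent `init` may be supplied instead.
* `tol` (minimum accepted improvement) defaults to 0: any strict
  improvement is taken.
* Node identity is positional internally; names are used at all I/O
  boundaries. Edge-list TSV (`parent<TAB>child`) is the canonical graph
  interchange, written in a deterministic canonical order; adjacency CSV
  is an alternative export.
* `shd()` counts a reversal as one unit; variants that count it as two
  are out of scope.
* Every run that writes files can write a JSON manifest (config, seeds,
  version, input checksums) sufficient to replay it byte-for-byte.
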