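---
title: "Methods: the DEMATEL gravity model for influential-spreader ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DEMATEL gravity model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spreadRank)
```

## The model and its assumptions

spreadRank scores node importance in an *undirected, unweighted, simple*
graph. The premise is that a node's spreading power depends on two things at
once: how connected it and its interaction partners are (local information)
and how close it sits to everybody else (path information). The gravity
analogy captures both: treating degree as mass, the interaction between nodes
$i$ and $j$ is

$$g_{ij} = \frac{k_i k_j}{d_{ij}^2},$$

with $k_i$ the degree and $d_{ij}$ the geodesic hop count. Gravity centrality
simply sums these interactions per node. The model implemented here goes one
step further: it treats $g_{ij}$ as a *direct influence* and feeds the matrix
$D = (g_{ij})$ (zero diagonal) into the DEMATEL formalism, which adds
*indirect* influence along chains of intermediaries:

$$N = D/s, \qquad s = \max\Big(\max_i \sum_j d_{ij},\ \max_j \sum_i d_{ij}\Big),$$
$$T = \sum_{k \ge 1} N^k, \qquad R_i = \sum_j t_{ij}, \quad C_j = \sum_i t_{ij},
\qquad a = R + C.$$

$T$'s entry $t_{ij}$ aggregates the influence of $i$ on $j$ through paths of
every length, weighted geometrically by the normalization. A node's
importance $a_i$ is the influence it exerts plus the influence it receives.
Because the input graph is undirected, $D$, $N$ and $T$ are symmetric, so
$R = C$ and $a = 2R$ exactly; the test suite asserts this to $10^{-9}$
relative tolerance, and it is the key internal consistency check of the
implementation.

Two readings of the published formulas deserve a note. The normalization
denominator is taken as a *single global scalar* (the larger of the maximum
row sum and maximum column sum), the standard DEMATEL choice — a per-element
denominator would destroy the Neumann-series interpretation of $T$. And the
total-relation formula is read as a series of *matrix powers*, not of scalar
powers of individual entries, which is the only reading under which "the
normalized relation matrix continues to multiply" makes sense.

## Numerical choices

**Closed form versus truncated series.** When the spectral radius
$\rho(N) < 1 - 10^{-9}$, the series is summed exactly as
$T = N(I - N)^{-1}$. $\rho$ is estimated by power iteration (tolerance
$10^{-10}$) on $N + I$; the shift makes the Perron eigenvalue strictly
dominant, so the iteration cannot oscillate between eigenvalue pairs of equal
modulus. For perfectly regular structures (a single edge, cycles, complete
graphs) the gravity matrix has constant row sums and $\rho(N) = 1$ exactly:
$I - N$ is singular and the series diverges. Rather than inverting a singular
matrix, the pipeline falls back to a truncated partial sum (default budget
1000 terms, stopping early when the max-abs increment drops below
$10^{-12}$) and warns. Partial sums of a nonnegative series are entrywise
non-decreasing and preserve the symmetry of the graph, so the *ranking* —
which only compares nodes within one run — remains meaningful: on
vertex-transitive graphs all scores stay equal, as the tests verify. Both
routes are exposed (`mode = "closed_form"` / `"series"`) and cross-checked
against each other and against an independently coded 200-term partial sum
to $10^{-8}$ max-abs.

**Unreachable pairs.** Distances use `Inf` as the unreachable sentinel, never
a large finite number; `k_i k_j / Inf^2` is exactly 0, so disconnected pairs
contribute no direct influence, consistent with gravity vanishing at infinite
distance. Average distance on a disconnected graph is computed over reachable
pairs only, with a warning.

**Eigenvector centrality** is computed by power iteration with a
deterministic uniform start, again on $A + I$: on bipartite graphs (stars,
paths) the adjacency spectrum is symmetric and unshifted iteration would
oscillate between the $\pm\lambda_{max}$ eigenvectors. The shift leaves the
eigenvectors untouched; the reported $\lambda_{max}$ is the Rayleigh quotient
with $A$ itself. The vector is normalized to unit Euclidean length with
nonnegative entries (the Perron choice) before weighting gravity scores.

**Ties.** Score tables order rows by descending score with ties broken by
ascending label, and ranks are the 1-based positions in that order — a total,
deterministic order, so repeated runs are byte-identical. Scores are printed
with 10 significant digits, enough for bit-stable regression tests without
noise digits.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `beta` | 0.1 (`simulate`) | per-contact infection probability per step |
| `steps` | 45 (`simulate`), 20 (`evaluate`), 10 (top-k curves) | synchronous SI steps ("simulation time") |
| `runs` | 10 (`simulate`), 100 (`evaluate`) | repetitions per seed node |
| beta grid | 0.05–1.0 by 0.05 | `evaluate` sweep; β = 0 excluded (all capacities 1, tau undefined) |
| `tol`, `maxTerms` | $10^{-12}$, 1000 | total-relation series stopping rule |
| tau `variant` | `tau_b` | tie-corrected; `tau_a` and the n(n−1)-denominator `paper` variant available |

The SI defaults mirror the published experimental settings of the study this
model family comes from (β = 0.1 with 10 repetitions; horizons 45, 10 and 20
for the capacity, top-k and tau experiments respectively). "Simulation time"
is read as the number of discrete synchronous steps, the only time unit the
discrete model has.

The SI update is implemented per susceptible node as one draw against
$1-(1-\beta)^{c}$, where $c$ is its number of currently infected neighbours —
exactly the aggregate of $c$ independent per-contact Bernoulli($\beta$)
trials, but one RNG call instead of $c$. Spreading capacity *includes the
seed* in the count (all nodes in state I); this is stated explicitly because
conventions differ, and it shifts every capacity by exactly 1 without
affecting any ranking. RNG streams are derived per (seed node, run index)
from the master seed, so capacities are identical whether a node is simulated
alone, in a subset, or in a different order — the suite asserts this.

Kendall's tau defaults to the tie-corrected tau-b because both simulated
capacities and several centralities (degree above all) contain many ties; the
`paper` variant with denominator $n(n-1)$ is kept for fidelity and equals
tau-a/2 on tie-free data (asserted exactly in the tests). All variants count
a pair as concordant only when $(x_i-x_j)(y_i-y_j) > 0$ and discordant only
when $< 0$; ties count as neither.

## What the synthetic generators emulate — and what they do not

All testing runs on seeded synthetic graphs, so the package is verifiable
without downloads:

* **Erdős–Rényi** `er(n, p)` — homogeneous random baseline; each pair
  independent with probability $p$.
* **Barabási–Albert** `ba(n, mAttach)` — right-skewed degree distributions
  like real contact networks. Convention (stated because implementations
  differ): a complete-triangle seed core, each arriving node attaching
  `mAttach` edges to *distinct* existing nodes sampled proportionally to
  degree, so $m = 3 + m_{attach}(n-3)$ exactly.
* **Watts–Strogatz** `ws(n, kRing, pRewire)` — clustered small worlds; ring
  lattice with each edge's far endpoint rewired with probability
  `pRewire`, resampling to avoid self-loops and duplicates.
* Deterministic fixtures (`path3`, `star4`, `cycle5`, `complete5`,
  `two_stars_bridge`, `grid4x4`) with exact hand-computed reference values.

These generators reproduce degree heterogeneity, short path lengths and
(for WS) clustering, which are the structural features the gravity and
DEMATEL machinery respond to. They do *not* reproduce community structure,
degree assortativity, weighted or temporal contacts, or the particular
degree-distribution shapes of real collaboration and airline networks. A
green test suite therefore shows the implementation is correct and the
model behaves as designed under controlled conditions — not that the model's
empirical advantage carries over to any particular real network. For real
data, `readPajek()`/`readEdgeList()` ingest standard files, and
`scripts/check_table1.R` reproduces published summary statistics of the
three classic benchmarks once their Pajek files are downloaded (they are not
redistributed here; the published Jazz edge count is internally inconsistent
with its published average degree and is excluded from that check).

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run on sizes chosen to make every
stochastic check statistically decisive while keeping a full run comfortable
on a laptop: oracle comparisons on all-pairs enumerable graphs ($n \le 7$ for
path enumeration, $n \le 12$ for Floyd–Warshall, $n \le 200$ for pair-count
tau); DEMATEL property sweeps over 50 random graphs; SI checks with $10^4$
runs where a binomial expectation is asserted to ±0.05; and the headline
experiments on Barabási–Albert graphs with $n = 200$ (ranking, top-20
curves) and $n = 100$ (tau-versus-capacity sweep, 30 runs per node). The
top-k effectiveness comparison uses the top 20 of 200 nodes, the same
1-in-10 fraction as the published top-50 experiments on networks of a few
hundred nodes.

## Known limitations

* Complexity: distances cost $O(nm)$ BFS, the closed-form total relation an
  $O(n^3)$ solve, and `geodesicCounts()` stores $O(n^3)$ entries — fine for
  the few-hundred-node networks this model family targets, not for
  million-node graphs.
* The model is defined for undirected, unweighted graphs; edge weights in
  Pajek files are deliberately ignored.
* On vertex-transitive graphs the normalized relation matrix has spectral
  radius exactly 1; scores from the truncated-series fallback grow with the
  term budget and only their *relative* pattern is meaningful (all equal, by
  symmetry). The `converged` flag and warning make this case visible.
* SI ground truth is itself stochastic; tau values against capacity carry
  simulation noise that shrinks with `runs` but never vanishes.
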