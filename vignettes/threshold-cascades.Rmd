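---
title: "Computational cascades in threshold networks: model, predictions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational cascades in threshold networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ltmcascade)
```

## The model

The linear threshold model (LTM) runs on an undirected
Erdős–Rényi–Gilbert graph with `N` nodes and edge probability
`p = z/(N-1)`, `z` the target mean degree.  Each node carries a
threshold `phi` drawn uniformly from the open interval (0, 1).  Nodes
are binary — *unlabelled* (0) or *labelled* (1) — and all start
unlabelled except `k` designated *seed* nodes, which are clamped to an
input pattern for the whole run.  The dynamics repeatedly sweep over
the currently unlabelled non-seed nodes in a fresh uniformly random
permutation; a node whose fraction of labelled neighbours reaches its
threshold (`L(u)/deg(u) >= phi_u`) is labelled immediately and stays
labelled.  The run stops when a full sweep labels nothing, which is
guaranteed within `n` sweeps because every earlier sweep labels at
least one node.

The antagonistic variant (ALTM) negates the rule for a fraction
`theta` of the non-seed nodes: an antagonist fires while its labelled
fraction is *strictly below* its threshold.  Antagonism is the
model's stand-in for inhibition; an isolated antagonist fires
unconditionally (its labelled fraction is defined as 0), which is why
the constant-1 function arises off the giant component once `theta > 0`.

Running the cascade once per input pattern — `2^k` cascades against a
frozen network — assigns every non-seed node a Boolean function of the
seeds: its truth table is its final label across patterns.  Tables are
numbered most-significant row first, so for `k = 2` AND = 1, XOR = 6,
OR = 7, NAND = 14.

## Why these update semantics

The dynamics are stated as random asynchronous examination that
continues "until no more nodes become labelled", which leaves the
schedule open.  We use random-permutation sweeps with immediate
commitment for three reasons.  First, termination is detectable (a
sweep that labels nothing is a fixed point).  Second, for a pure LTM
the firing rule is monotone in the labelled set and labels are
permanent, so the fixed point is provably independent of the schedule
— the test suite verifies identical fixed points across ten schedules
on fifty random networks.  Third, the alternative one-pass reading
(each node examined exactly once) breaks that order independence, so
it cannot be what a reproducible LTM means.  With antagonists the
fixed point genuinely depends on the order; the schedule stream is
seeded per pattern, making every assignment a reproducible sample of
the order-dependent dynamics.  No unlabelling rule exists in the
model, so labels are permanent within a run even when an antagonist's
neighbourhood later crosses its threshold; this is the main semantic
ambiguity of the ALTM and we flag it below where it matters.

## Percolation predictions

The giant-connected-component (GCC) fraction `v` at mean degree `z`
solves the self-consistency relation `v = 1 - exp(-z v)`.  `v = 0` is
always a root; above the critical mean degree `z_c = 1` the relevant
root is the nonzero one, which `gcc_fraction_theoretical()` brackets
by bisection on `(1e-12, 1]` after checking `z > 1` (excluding the
trivial root is the point of the bracket; residuals are below 1e-10).
The graph stays locally tree-like well above criticality because the
clustering coefficient is approximately `p` — about 1/1000 at
`N = 10^4`, `z = 10`.

A node computing a monotone function `f` needs one seed-to-node path
per relevant input.  The number of relevant inputs is the
decision-tree complexity computed from Hamming-cube symmetry:
`C = D - R`, where `D = k` and `R` counts the axes along which the
truth table is constant.  In a tree, `C` paths meeting at a node
involve `C + 1` specific nodes, each of which must lie in the GCC, so
the occurrence probability scales as `v^(C+1)`.  This is the
complexity-based prediction that the census experiments correlate
against; for the non-monotone functions it undercounts — the minimal
XOR motif needs 6 paths among 5 nodes, exponent 5 rather than
`C + 1 = 3` — and the motif catalog records the correct per-function
exponents.

## What the cascades actually do at z = 4

With thresholds uniform on (0, 1), a cascade reaching a new node of
degree `d` recruits it with probability `1/d`, so the branching factor
along an edge is `E[(d-1)/d] = 1 - (1 - e^{-z})/z < 1` for every `z`:
single-seed cascades are *subcritical*, with mean size
`1/(1 - b)` — about 4 nodes at `z = 4`.  Non-zero functions are
therefore rare events; an ensemble of hundreds of realizations is what
makes their mean frequencies measurable.  This is a property of the
model, not of the implementation, and it is why the default ensemble
size is 500 realizations (the scale at which the headline statistics
are quoted).

## Numerical choices

* Thresholds are drawn from the open interval (0, 1): `phi = 0`
  (probability zero under the stated distribution) would let an LTM
  node fire with no labelled neighbour, so the boundary is excluded by
  redrawing.
* Update schedules use a dedicated splitmix64 generator with an
  unbiased bounded-draw shuffle, so cascade results are bit-identical
  across platforms and independent of R's RNG state.  Topology,
  thresholds, seed choice, antagonist choice and schedules each get an
  independent stream derived from one master seed; ensembles derive
  one seed per realization up front, so results do not depend on
  execution order.
* At large mean degree the GCC fraction is within machine epsilon of
  1 and the raw predictions `v^(C+1)` collapse to exactly 1.0 in
  double precision.  `prediction_correlation()` then correlates
  against `(C+1) * log(v)` with `log(v)` evaluated as
  `log1p(-exp(-z v))`; Pearson correlation is invariant under positive
  affine maps and the exponential is affine to first order in
  `log(v) ~ -1e-28`, so this equals the exact value far beyond
  representable precision.
* Antagonist count is `round(theta * (n - k))`; seeds are never
  antagonistic because they are clamped inputs whose own rule is never
  applied.
* Rank orderings break frequency ties toward the smaller function id;
  `argmax_theta()` breaks diversity ties toward smaller `theta`.
  Giant-component ties go to the component containing the smallest
  node index.

## Correlation alignment

`prediction_correlation()` offers two alignments.  `align = "id"`
(default) pairs each function's mean frequency with its own
prediction: the literal reading of "correlation between frequency and
predicted probability".  `align = "rank"` correlates the
rank-ordering curve with the descending-sorted prediction curve — the
two overlaid traces of a rank-ordering figure — and measures whether
the predicted frequency *profile* matches the observed decay
regardless of which function occupies which rank.  For the pure LTM
the observed ordering already follows the predicted one and the two
alignments coincide.  In the mixed LTM/ALTM regime (`z = 64`,
`theta = 1/3`) they diverge sharply: every input pattern ignites a
large cascade (all antagonists fire on the all-zero pattern), the
fixed points are shaped by global activity rather than by individual
seed-to-node paths, and pattern-symmetric functions such as NOR, AND,
NAND and OR dominate the census.  The id-aligned correlation is then
negative (about −0.47), while the rank-aligned correlation is
positive (about 0.78).  We report the rank-aligned value for that
regime, since it is the figure-level comparison the prediction is
meant for, and note that under permanent-label sweep semantics the
dense-regime agreement remains materially weaker than in the sparse
LTM; the order-dependence of ALTM fixed points is exactly the
semantic ambiguity flagged above.

## The k = 4 correlation and the zero function

For `k = 2` the correlation over non-zero functions is robustly near
1.  For `k = 4` we quote the correlation over *all* observed
functions including the zero function `f0`.  The zero function is
excluded from rank-ordering plots (it would dwarf the curve), but
excluding it from the correlation as well leaves only the handful of
observed non-zero monotone functions, whose frequencies are so
strongly ordered by complexity that the correlation saturates near
0.996 and stops being informative about the prediction's absolute
quality; including `f0` (predicted `v^1`, observed at nearly `n - k`
nodes) yields a stable value near 0.70 that reflects how far the
single-exponent family compresses four orders of magnitude of
frequency.  Both variants are one `exclude =` argument away.

## The synthetic generator and what passing tests mean

All inputs are generated internally: ER topology, uniform thresholds,
uniformly chosen seeds and antagonists.  The generator's defaults are
the study conditions of the headline statistics — `N = 10^4`, `k = 2`,
`z = 4`, 500 realizations for the sparse censuses; `z = 64`,
`theta = 1/3` for the mixed regime; the `z x theta` diversity grid
over `theta ∈ {0, 1/6, …, 1}` with the desk preset (`N = 2000`, 50
realizations, `z ∈ {8, 64, 1024}`) for routine runs.  Real neuronal or
social networks are not ER: they have degree heterogeneity, clustering
and geometry, none of which the generator emulates, so passing tests
certify the model's internal predictions, not transfer to any
particular empirical network.  User-supplied networks enter through
`read_edgelist()`.

Problem sizes in the test suite are chosen so the full suite completes
in a few minutes: module tests use networks of 50–3000 nodes, and the
end-to-end statistical checks run the quoted study conditions
directly (the compiled cascade engine makes 500 realizations at
`N = 10^4` a matter of seconds).

## Known limitations

* Non-ER topologies, edge weights, synchronous or continuous-time
  updates, and `k > 4` ensembles are out of scope.
* No complexity measure beyond the axial-reflection count is defined,
  and that count is known to under-predict path requirements for
  non-monotone functions (XOR is the documented example).
* ALTM fixed points are schedule samples, not canonical objects; any
  statistic quoted for `theta > 0` is an expectation over schedules as
  well as over networks.
* Minimal motifs are catalogued for `k = 2` only, with direct edges
  standing in for paths; path multiplicity enters only through the
  giant-component exponents.
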