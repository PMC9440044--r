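# ltmcascade

Boolean computation emerges spontaneously in randomly connected
threshold networks: when a cascade is run from a set of clamped input
("seed") nodes once per input pattern, every other node ends up
computing some Boolean function of the inputs.  `ltmcascade` simulates
these *computational cascades* for the linear threshold model (LTM)
and its antagonistic (inhibitory) variant (ALTM), identifies the
function computed at every node, and tests the percolation-theoretic
predictions for how often each function occurs.  It is aimed at
researchers in statistical physics, computational neuroscience and
network science who study avalanche dynamics, criticality and
emergent computation.

## Model and theory in brief

* **LTM**: an Erdős–Rényi graph with `N` nodes, edge probability
  `p = z/(N−1)`, node thresholds `φ ~ U(0,1)`.  An unlabelled node
  fires when its fraction of labelled neighbours reaches its
  threshold, `L(u)/deg(u) ≥ φ_u`; labels are permanent.  Updates are
  asynchronous random-permutation sweeps, run to the fixed point.
* **ALTM**: a fraction `θ` of non-seed nodes obey the negated rule
  (`L(u)/deg(u) < φ_u`), modelling inhibition.
* **Function identification**: with the network frozen, one cascade
  per input pattern assigns each non-seed node a truth table; tables
  are numbered most-significant row first (AND = 1, XOR = 6, OR = 7,
  NAND = 14 at `k = 2`).  A pure LTM computes only monotone increasing
  functions.
* **Predictions**: the giant-component fraction solves
  `v = 1 − e^{−zv}` (nonzero only above `z_c = 1`); a function with
  decision-tree complexity `C = D − R` (inputs minus constant
  Hamming-cube axes) needs `C` seed-to-node paths, hence `C + 1` nodes
  jointly in the giant component, so its frequency scales as
  `v^{C+1}`.  Minimal *logic motifs* realise every `k = 2` function and
  carry the exact giant-component exponents (XOR needs 6 paths among 5
  nodes — exponent 5, not `C + 1 = 3`).

## Worked example

```r
library(ltmcascade)

net <- generate_network(n = 10000, z = 4, k = 2, theta = 0, rng_seed = 1)
length(giant_component(net)) / net$n   # 0.9801
gcc_fraction_theoretical(4)            # 0.9801726

table(extract_functions(net), useNA = "no")
#>    0    5
#> 9988   10

cen <- function_census(n = 10000, k = 2, z = 4, theta = 0,
                       realizations = 500, master_seed = 1)
pc <- prediction_correlation(cen)
pc$table[, c("rank", "fn_id", "mean_freq", "complexity", "predicted")]
#>   rank fn_id mean_freq complexity predicted
#> 1    1     5     4.134          1 0.9607383
#> 2    2     3     3.338          1 0.9607383
#> 3    3     1     0.004          2 0.9416894
pc$r
#> [1] 0.9833647
```

The single network's giant component holds 98% of the nodes, matching
the self-consistent percolation fraction.  Cascades at `z = 4` are
subcritical (mean size ≈ 4 nodes), so in one realization only a
handful of nodes compute a non-zero function — here ten nodes copy
seed *b* (function id 5).  Across 500 realizations the mean
frequencies order exactly as the complexity prediction `v^{C+1}`
says: the single-input projections (ids 3 and 5, exponent 2) are
roughly a thousand times more frequent than two-path AND (id 1,
exponent 3), and the Pearson correlation between frequency and
prediction is 0.98.

Motifs are built and verified exhaustively over update orders:

```r
m <- build_motif(6)   # XOR
m
#> <motif> f6: 5 nodes, 6 edges, 6 required path(s), output node 5
verify_motif(m)
#> [1] TRUE
```

## Command-line interface

A thin wrapper is installed at `inst/cli/ltmcascade.R`:

```sh
Rscript inst/cli/ltmcascade.R census --preset desk --seed 1 --out runs/census
Rscript inst/cli/ltmcascade.R surface --preset desk --seed 1 --out runs/surface
Rscript inst/cli/ltmcascade.R motifs --out runs/motifs
```

Each command writes tab-separated result tables plus a YAML manifest
with the config echo, derived seeds and artifact checksums; identical
config and seed give byte-identical outputs.

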