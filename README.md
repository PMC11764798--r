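# hammingnet

Structural analysis of **bit-string similarity networks** — graphs whose
nodes are length-`B` binary strings (stylized genomes, viral sequences,
cultural profiles) and whose links join every pair at Hamming distance at
most a threshold `G`. In evolutionary and cultural models where only
sufficiently similar individuals can interact, this graph *is* the
interaction network. The package is for modellers who need the exact
structural theory of these networks next to fast, seeded simulations.

## What it computes

With `M_G = sum_{H=1..G} choose(B, H)` strings inside a `G`-ball, the
connectivity parameter is

    mu = M_G / (2^B - 1)

and the analytic results implemented in pure form are:

* **Degree distribution** — binomial, `g_k = C(N-1, k) mu^k (1-mu)^(N-1-k)`,
  mean degree `z = mu (N-1)`; identical to an Erdős–Rényi graph with
  `mu N(N-1)/2` links (`degree_pmf()`).
* **Giant component** — critical point `mu_c = 1/(N-2)`; extinction
  probability `u` solving `u = (1 - mu + mu u)^(N-2)` and giant fraction
  `S = 1 - u^((N-1)/(N-2))` (`solve_giant()`); large-`N` limit
  `u = exp(-(mu/mu_c)(1-u))`, `S = 1 - u` (`solve_giant_largeN()`).
* **Richness** — components per node, with the sub-critical approximation
  `R = exp(-r) + (1 - exp(-r))/2`, `r = mu/mu_c` (`richness_approx()`).
* **Mean clustering** — an exact hypergeometric-tail formula for the
  probability that two neighbours are mutually linked, averaged over the
  neighbourhood distance profile; independent of `N`
  (`neighbor_pair_prob()`, `clustering_coeff()`).

Around the theory sit a neutral-evolution generator (`run_evolution()`:
parent copy, single-bit mutation, random death — plus replace-parent and
recombination variants), network construction (`similarity_network()`),
empirical metrics (components, richness, mean clustering, the link-Pearson
degree assortativity, mean geodesic distance) with an Erdős–Rényi
comparator (`er_graph()`), and seeded realization-averaged experiment
drivers (`experiment_*()`).

## Worked example

```r
library(hammingnet)

theory_summary(N = 1024, B = 20, G = 3)
#> Bit-string similarity network, N = 1024  B = 20  G = 3
#>   neighbourhood volume M_G : 1350
#>   connectivity mu          : 0.00128746  (mu_c = 0.000978474, mu/mu_c = 1.316)
#>   mean degree z            : 1.317
#>   giant component S        : 0.4388  (u = 0.5615)
#>   mean clustering C        : 0.1114
#>   richness approximation R : 0.6341
```

`M_G = 1350` strings sit within distance 3 of any node, so `mu` is just
above critical (`mu/mu_c = 1.32`): the tree-based theory expects a giant
component holding 44% of the network, and each node's neighbours have an
11% chance of being mutually linked — orders of magnitude above the
Erdős–Rényi level `z/(N-1) = 0.0013`.

Measuring one simulated realization:

```r
set.seed(1)
X <- random_bitstring_set(200, 12)     # 200 distinct strings of length 12
g <- similarity_network(X, G = 3)
network_report(g)
#> Network report: 200 nodes, 1473 links
#>   components               : 1 (richness R = 0.005)
#>   largest component        : 1 of the network
#>   mean clustering C        : 0.2765
#>   degree assortativity A   : 0.2425
#>   mean geodesic distance L : 2.518
```

Here `z = 14.5` is far above the transition, so a single component spans
all 200 nodes (richness `1/N`), clustering is high (`clustering_coeff(12, 3)` gives
0.265 — the measured 0.277 agrees to sampling error), and paths are
short. Realization-averaged curves come from the drivers, e.g.
`experiment_giant_richness(N = 1024, B = 20, G = 1:6, reps = 50, seed = 1)`
returns the measured `S` and `R` with their analytic columns across the
transition.

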