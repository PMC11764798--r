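---
title: "Bit-string similarity networks: model, theory, and measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-string similarity networks: model, theory, and measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hammingnet)
```

## The model

A bit string is an ordered array $b = (b_1, \dots, b_B)$ of binary variables
— a stylized genome, viral sequence, or cultural profile. Two strings of
equal length are compared by their Hamming distance
$H(b, b') = \sum_i |b_i - b_i'|$, the number of positions at which they
differ. Given $N$ mutually distinct strings, the *similarity network* links
every pair with $H \le G$ for a threshold $1 \le G \le B$. In evolutionary
models where only genetically compatible individuals interact, this graph
*is* the interaction network.

The three parameters and their roles:

* `N` — network/population size. Desk-scale experiments use $N$ up to 1024.
* `B` — string length. Controls how finely the code space ($M = 2^B$
  strings) resolves distances; structural quantities depend on $B$ mainly
  through the ratio $G/B$.
* `G` — similarity threshold, the only dial that tunes connectivity at
  fixed $N, B$.

All connectivity theory flows through a single derived quantity, the
probability that a uniformly chosen *other* string lies within distance
$G$:
$$\mu = \frac{M_G}{M - 1}, \qquad M_G = \sum_{H=1}^{G} \binom{B}{H}.$$
Because $G$ is discrete, $\mu$ takes discrete values; experiment drivers
therefore report curves at the achievable $\mu$ rather than interpolating.

## Random sets from neutral evolution

`run_evolution()` implements the constant-size neutral model: from $N$
identical all-zero strings, each step copies a random parent, flips one
uniformly chosen bit of the copy, and lets the child replace a uniformly
chosen member. Two variants are provided: the child may replace its own
parent, or be formed by single-point recombination of two distinct parents
before mutation. Two details are underdetermined by the verbal model and
were fixed once as package choices:

* the victim draw includes the parent by default (`exclude_parent = TRUE`
  gives the other reading of "another randomly selected member dies");
* recombination uses a single crossover point uniform over the $B - 1$
  internal boundaries, with parents drawn uniformly without replacement.

Convergence toward a random set is tracked by
$D(T) = \sum_H (f_H(T) - f_H^{\mathrm{random}})^2$, where $f_H$ is the
pairwise distance histogram and $f_H^{\mathrm{random}} = 2^{-B}\binom{B}{H}$
its value for uncorrelated uniform strings. At $T = 0$ the histogram is
$\delta_{H,0}$, giving the exact starting value
$D(0) = (1 - 2^{-B})^2 + 2^{-2B}\big[\tbinom{2B}{B} - 1\big]$, which the
test suite checks to $10^{-12}$. Time is reported rescaled by $NB$, the
mean waiting time for any bit in the population to mutate; on that scale
the decay rate is essentially independent of $N$ and $B$.

**A note on the plateau.** After the exponential decay, $D$ fluctuates
around a plateau set by the residual fluctuations of $f_H$. Since the
fluctuation of each histogram bin is of order $N^{-1}$ (the effective
number of independent pairs grows as $N^2$), the plateau of $D$ — a *sum of
squares* of those fluctuations — scales as $N^{-2}$. The acceptance suite
measures doubling ratios near 3.9 across $N \in \{256, 512, 1024\}$ at
$B = 20$, i.e. $\sqrt{D}$ (the RMS histogram error) scales as $N^{-1}$.
Descriptions of this model sometimes attribute the $N^{-1}$ law to $D$
itself; the simulator shows that it belongs to the RMS difference, not to
the squared diagnostic.

## Degree distribution and the giant component

Each of the other $N - 1$ nodes falls inside a given node's $G$-ball
independently with probability $\mu$, so degrees are binomial,
$g_k = \binom{N-1}{k}\mu^k(1-\mu)^{N-1-k}$, with mean
$z = \mu(N-1)$ — exactly an Erdős–Rényi graph with $\mu N(N-1)/2$ links.
The generating-function formalism then gives the extinction probability
$u$ as the smallest root of $u = (1 - \mu + \mu u)^{N-2}$ and the giant
fraction $S = 1 - u^{(N-1)/(N-2)}$, with the critical point
$\mu_c = 1/(N-2)$. For $N \gg 1$ everything depends on the single ratio
$\mu/\mu_c \approx z$: $u = e^{-(\mu/\mu_c)(1-u)}$, $S = 1 - u$.

`solve_giant()` and `solve_giant_largeN()` find the root by bracketed
bisection (`uniroot`) on $[0, 1 - 10^{-12}]$ to tolerance $10^{-12}$,
returning $u = 1, S = 0$ whenever no interior root exists; plain
fixed-point iteration is avoided because it stalls near criticality.

**Where the random-graph theory bends.** The binomial degree law is exact,
but link *placements* are not independent: the Hamming metric correlates
neighbourhoods (see clustering below). The package's acceptance tests
measure the consequence: at $B = 100$ the measured largest-component
fraction agrees with the solver to well within sampling error
(e.g. $0.728 \pm 0.007$ vs 0.732 at $\mu/\mu_c = 1.80$), but at $B = 20$ —
where the transition falls in a strongly clustered regime ($C \approx 0.11$
at $G = 3$) — the giant component near criticality is systematically
smaller than the tree-based prediction (about $0.20$ vs $0.44$ at
$\mu/\mu_c = 1.32$). Triangles spend links inside already-connected
neighbourhoods, which slows giant-component growth. Away from the
transition zone the prediction is accurate at every $B$ tested.

The *richness* $R$ — components per node, a diversity proxy — is
approximated below the transition by counting isolated nodes
($e^{-\mu/\mu_c}$ each) and assuming the rest pair up:
$R = e^{-\mu/\mu_c} + (1 - e^{-\mu/\mu_c})/2 \approx 1 - \mu/2\mu_c$,
accurate to a few percent up to $\mu/\mu_c \approx 1$.

## Clustering: the combinatorial formula

For a node $b_0$ and neighbours $b_1, b_2$ at distances $H_1, H_2$, the
number $h$ of positions where their differing bits coincide is
hypergeometric — $h \sim \mathrm{Hyper}(H_1, B - H_1, H_2)$ after fixing
$b_0 = 0\cdots0$ — and the mutual distance is $g = H_1 + H_2 - 2h$. So the
probability that the two neighbours are themselves linked is a
hypergeometric tail over $h \ge h_0 = \max\{0, \lfloor (H_1 + H_2 - G +
1)/2 \rfloor\}$ (`neighbor_pair_prob()`, evaluated through `phyper` — exact
and stable even at $B = 100$, where naive factorial ratios overflow).
Averaging over the distance profile of a neighbourhood, with distance $H$
carrying weight $\binom{B}{H}/M_G$, gives the mean clustering coefficient
$$C = \sum_{H_1=1}^{G}\sum_{H_2=1}^{G} w(H_1)\, w(H_2)\, P(H_1, H_2),
\qquad w(H) = \binom{B}{H}/M_G,$$
independent of $N$. Two conventions required a decision:

* **Normalization.** The $\binom{B}{H_1}\binom{B}{H_2}$ weights are
  normalized by $M_G^2$, making $C$ a genuine conditional probability
  (given that both strings are neighbours of $b_0$) with $C(G = B) = 1$;
  the exhaustive all-$2^7$-string network at $B = 7$ adjudicates this
  choice in the test suite.
* **The identical-pair outcome.** The tail term $h = H_1 = H_2$ corresponds
  to $g = 0$, i.e. $b_1 = b_2$ — impossible between distinct network
  nodes. By default it is removed from numerator and normalization
  (`identical = FALSE`); the as-printed tail is available with
  `identical = TRUE`. The difference matters only at small $G$: at $G = 1$
  the full tail gives $C = 1/B$ while measured networks give exactly 0,
  since two distinct neighbours at distance 1 sit at mutual distance 2.

$C$ is *not* monotone in $G$ at small thresholds: pairs at distances
$(H, H)$ are automatically linked once $2H \le G$, so opening a new odd
distance shell can dip $C$ (at $B = 20$: $C = 0.182$ at $G = 2$ but
$0.111$ at $G = 3$) before the S-shaped rise toward 1. The measured curves
reproduce the dip exactly; it is a parity feature of the metric, not an
artifact.

Empirically, `mean_clustering()` averages local coefficients over nodes of
degree $\ge 2$ (nodes with fewer neighbours have no neighbour pair; counting
them as zero — available via `low_degree = "zero"` — would bias sparse
regimes against the conditional-probability prediction). The sweep driver
computes local coefficients from dense adjacency products
($\mathrm{tri}_i = \tfrac12[A^2 \odot A]\mathbf{1}$), which keeps a full
$G$-sweep at $N = 1024$ to minutes on one core.

## Assortativity and geodesic distance

No accurate analytic prediction is available for degree assortativity, so
it is measured: over all links, with $k_1, k_2$ the endpoint degrees,
$$A = \frac{4\langle k_1 k_2\rangle - \langle k_1 + k_2\rangle^2}
           {2\langle k_1^2 + k_2^2\rangle - \langle k_1 + k_2\rangle^2},$$
a symmetric form indifferent to edge orientation. Degenerate cases
(zero variance, e.g. complete graphs) report `NA` rather than a silent 0.
Similarity networks show small positive assortativity (peak means at or
below about 0.17, at $G/B < 0.5$, decreasing with $B$ and decaying toward
zero as connectivity grows), while matched Erdős–Rényi graphs are
indistinguishable from zero.

The mean geodesic distance $L$ averages breadth-first shortest-path
lengths over unordered same-component pairs (cross-component pairs are
infinite and excluded; `igraph::mean_distance` provides the BFS). $L
\approx 1$ both for very sparse graphs (components are single links) and
near-complete ones, with a sharp peak just above the giant-component
transition ($1 \lesssim \mu/\mu_c \lesssim 2$) where the component
structure is most irregular. Here the Hamming structure leaves no
signature: matched Erdős–Rényi comparators (same $N$, same link count,
drawn from the $G(N, M)$ ensemble by uniform pair-index sampling) give the
same $L$ within realization fluctuations.

## Experiment drivers, seeds, and problem sizes

Each `experiment_*()` driver derives one sub-seed per (experiment,
parameter point, replicate) from its master seed, so whole runs replay
bit-identically and a $G$-subset reproduces the matching rows of a full
run. One distance matrix is computed per realization and thresholded at
every $G$ in the sweep — distances, not graphs, dominate the cost.
Realization counts default to 50, the reference averaging depth for these
ensembles; the geodesic driver defaults to 20 replicates, which already
renders the peak's location stable while its tails have negligible
variance. Divergence trajectories default to 10 rescaled time units
sampled every 0.1 — the decay completes within about 1.5 units, leaving
the final 20% of the record (the plateau estimator's window,
`plateau_divergence()`) safely in the stationary regime.

## What the generator does and does not emulate

The synthetic inputs are uniform random distinct bit strings and
neutral-evolution populations. They capture the combinatorics of Hamming
space — which is all the analytic theory uses — but deliberately omit
features of real genetic or cultural data: selection and fitness
differences, mutation-rate heterogeneity along the string, linkage and
recombination hotspots, non-binary alphabets, and non-uniform string
frequencies. Passing tests therefore validate the model's mathematics and
its implementation, not the claim that any particular empirical network is
well described by uniform bit strings. Multi-state arrays, distance-weighted
links, and dynamics under selection are out of scope.

## Numerical choices and degenerate inputs

* Binomial-coefficient sums use exact double-precision `choose()` up to
  $B = 1000$ and `lchoose`/log-sum-exp beyond; hypergeometric weights go
  through `phyper`/`dhyper` rather than factorial ratios.
* Root finding is bracketed bisection with tolerance $10^{-12}$; a
  supercritical root pushed numerically onto $u = 1$ is reported as
  subcritical rather than spuriously positive.
* Degenerate metrics report `NA` (assortativity of regular graphs, mean
  clustering with no degree-2 node, geodesics of edgeless graphs) and
  errors are raised for contradictory inputs (duplicate strings in a
  network set, $N > 2^B$, mismatched lengths, thresholds outside $[1, B]$).
* `random_bitstring_set()` samples the code space by index below
  $B = 25$ and by bitwise draws with duplicate rejection above — both
  exactly uniform without replacement; populations and sets are plain 0/1
  matrices, and distance matrices are a single BLAS product.
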