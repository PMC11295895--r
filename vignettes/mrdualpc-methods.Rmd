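---
title: "Causal molecular networks with dual-order filtering: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal molecular networks with dual-order filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdualpc)
```

## The problem

Expression of thousands of genes, genotypes at variants associated with
that expression (eQTLs), and a disease outcome are measured on the same
individuals. The question is directional: which genes sit *upstream* of
the disease — genes whose perturbation would propagate to the outcome —
rather than merely correlated with it. Constraint-based structure
learning (the PC family) answers this by testing conditional
independences, but on a complete graph over hundreds of nodes the number
of tests explodes, which is why genome-scale data are first split into
co-expression modules and why the PC search itself needs a cheaper entry
point. This package implements that cheaper entry point — a dual-order
conditional-independence pre-filter — together with the module detection,
the Mendelian-randomization (MR) orientation, and a simulator that makes
every stage testable against known ground truth.

## The statistical machinery

### Conditional-independence testing

All stages consume one `sufficient_stats` object: the sample correlation
matrix over every node (genes, variant dosages, outcome) plus the sample
count. Under a linear-Gaussian model, `x` is conditionally independent of
`y` given a set `S` exactly when the partial correlation
$\rho_{xy\cdot S}$ vanishes. The partial correlation is read off the
inverted sub-correlation matrix,
$\rho_{xy\cdot S} = -P_{xy}/\sqrt{P_{xx}P_{yy}}$, and tested with
Fisher's transform: $z = \operatorname{atanh}(\hat\rho)$ with
$\sqrt{n - |S| - 3}\,|z|$ referred to a standard normal. The default
level is $\alpha = 0.05$ per test with no multiplicity correction — the
exploratory convention of this analysis style; a caller can apply
`p.adjust` to the returned test log if desired.

Numerical guards, all flagged in results rather than silent:

* $|\hat\rho|$ is clamped to $1 - 10^{-12}$ before `atanh`, so duplicated
  or collinear variables cannot produce infinite statistics.
* A singular sub-correlation matrix (possible when $|S| + 2 > n$) falls
  back to a shrinkage inverse $(1-\lambda)R + \lambda I$ with
  $\lambda = 10^{-3}$.
* If $n - |S| - 3 < 1$ the test is refused and the edge kept: an invalid
  test never deletes an edge.

### The dual-order pre-filter

The defining step of the method. For each pair the filter tests
independence conditioning simultaneously on the empty set (order 0) and
on the full set of remaining neighbours (order $k$). The full-order side
costs almost nothing: one inversion of the correlation matrix yields the
full-order partial correlations of *every* pair at once. An edge is
deleted the first time either test accepts independence, and the
witnessing set is recorded as the pair's separating set. Deeper inward
marching (orders $1, k-1$; $2, k-2$; …) is available via
`filter_config(max_depth = )`; candidate subsets are then chosen by
descending marginal correlation with the endpoint, at most 20 per size,
because exhaustive subset enumeration would defeat the purpose of the
filter. The default depth is 1 — the shallow pass is what the per-module
workflow uses, with depth exposed for experimentation.

Two properties matter. First, soundness: adjacent nodes in the true graph
are never conditionally independent (faithfulness), so no true edge can
be removed by a correct test, at any order — the package verifies this
with an exact d-separation oracle in its test suite. Second, the
mechanism of the speedup: every edge the filter removes is an edge the
subsequent PC search never has to test at orders $\ge 1$, where the
subset enumeration lives. The benchmark module measures exactly this,
reporting CI-test counts rather than seconds so that the comparison is
hardware-independent.

A practical consequence observed in the simulations: pairs that survive
the order-0 test by chance (roughly $\alpha$ of all null pairs) often
survive *every* later PC test too, because the conditional statistics on
a null pair barely move as the conditioning set changes. The full-order
test gives each pair a second, nearly independent chance of removal,
which is why the dual filter also improves the false-discovery rate of
the final skeleton, not just its cost.

### Skeleton refinement

`refine_skeleton()` is a PC-stable skeleton search: for ascending order
$\ell$, every surviving edge is tested against all size-$\ell$ subsets of
each endpoint's neighbourhood, with neighbourhoods frozen per order so
that the result does not depend on edge visiting order, and deterministic
lexicographic subset enumeration over the fixed node order so that runs
are bit-reproducible. Sequential (classic PC) deletion is available
behind `skeleton_config(stable = FALSE)`. `max_order` is unbounded by
default; termination comes from the degree condition.

### MR orientation

Orientation uses the one piece of background knowledge genotype data
provides for free: a variant can cause a phenotype but never the
reverse. Three passes:

1. `orient_variant_edges()` directs every variant–phenotype edge away
   from the variant.
2. `orient_v_structures()` looks at unshielded triples $x - z - y$ and
   orients a collider $x \to z \leftarrow y$ when $z$ is outside the
   stored separating set of $(x, y)$ and, by default
   (`confirm_with_test = TRUE`), a confirmatory pair of tests agrees:
   $x \perp y$ given the stored set, $x \not\perp y$ given $\{z\}$.
   Re-testing at orientation time mirrors the reference behaviour of
   testing the triplet topology directly rather than trusting stored
   sets. Contradictory claims on one edge cancel (the edge stays
   undirected, logged), and a proposed arrowhead into a variant is
   skipped and logged.
3. `propagate_orientations()` applies the standard closure rules (no new
   v-structure, no directed cycle) to fixpoint, under the extra
   constraint that no rule may orient into a variant. The full
   four-rule closure is implemented because the variant arrows
   constitute background knowledge, which is precisely the situation in
   which the fourth rule fires.

Whether the reference pipeline's orientation step performs an exact
Meek-equivalent completion is not documented; implementing the
constrained closure is this package's choice, validated two ways: a
brute-force rule-application oracle in the tests, and
`true_cpdag()` — an independent DAG-to-CPDAG construction by compelled-
edge labelling (itself cross-checked against full enumeration of
Markov-equivalent DAGs on small graphs). On variant-free oracle inputs
the search returns the true CPDAG in 50/50 random DAGs; with variants
attached, orientation recovers strictly more directed edges than the
equivalence class allows without instruments — the point of MR
anchoring.

Finite-sample orientation can create directed cycles; graphs store them
without crashing and `causal_ancestors()` — a reachability query over
fully directed edges only — attaches a warning when it happens.
Partially oriented edges are never traversed: the reported "causal
ancestors" are the conservative reading of a causal pathway. This is a
deliberate resolution of an ambiguity (counting genes connected through
undirected edges would inflate ancestor sets unverifiably).

### Background knowledge: mutually independent instruments

The pipeline assumes instrument sets have been pruned to mutual
independence upstream (LD clumping is the standard step that produces
eQTL instruments, and the simulator emits independent variants by
design). `run_module(assume_independent_ivs = TRUE)` therefore excludes
variant–variant edges from the search a priori, recording the empty
separating set. This removes a class of structurally impossible edges
that otherwise accumulates chance false positives (a material share of
skeleton false discoveries in the default simulation conditions, with no
effect on power) and shortens the search. Set it to `FALSE`
when instruments may be correlated. The benchmark module does *not* use
this shortcut: both benchmarked methods start from the same unrestricted
complete graph so that the measured difference is the pre-filter alone.

## Co-expression module detection

The clustering stage mirrors the weighted co-expression convention:
unsigned adjacency $a_{ij} = |\mathrm{cor}_{ij}|^\beta$ with $\beta$
chosen by `pick_soft_threshold()` as the smallest power whose scale-free
fit $R^2$ reaches 0.85 (the conventional target; the fallback is the
argmax power, with a warning); topological overlap
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\min(k_i,k_j) + 1 - a_{ij})$; average-linkage hierarchical clustering of
$1 - \mathrm{TOM}$. The scale-free fit bins connectivities into
equal-width bins and regresses log frequency on log mean connectivity —
equal-width, because equal-count bins make the frequency constant by
construction and the regression degenerate.

The dynamic hybrid tree cut of the reference workflow is a separate
publication's algorithm and is *not* re-implemented. In its place:
a static cut at `cut_height` (default 0.99 on the dissimilarity scale),
merging of clusters whose average inter-cluster dissimilarity falls
below `merge_cut_height` (default 0.3), and absorption of clusters
smaller than `min_module_size` (default 40) into their nearest cluster.
The stated purpose of the cut — modules large enough to be informative
and small enough to be computationally manageable — is met by these
exposed parameters; exact module counts on real data are cut-algorithm-
dependent and are not a target. `kmeans_refine()` then runs Lloyd
iterations on the rows of the dissimilarity matrix, initialized from the
hierarchical modules with $k$ fixed, which is the published refinement
that reduces misplaced genes. The objective trajectory is recorded and
non-increasing by construction; an emptied cluster is dropped with a
warning.

## The simulator

`sim_scenario()` defaults describe the study-like conditions every
recovery claim is measured under: 50 genes, one SNP instrument per gene
(no pleiotropy; a `pleiotropy_prob` knob exists for robustness
experiments), `n = 2000` samples, gene–gene edge probability 0.04
(expected degree ≈ 2, a sparse regulatory backbone), structural
coefficients drawn from $\pm[0.5, 1]$, SNP effects from the same range
on standardized dosages, unit noise, MAF uniform on $[0.05, 0.5]$, and a
binary outcome produced by thresholding a latent liability (three gene
parents) at its median — echoing a near-balanced case/control design.
Genotypes are Binomial(2, MAF) dosages, standardized inside the
structural equations so that one noise scale is meaningful across node
types; the emitted genotype matrix keeps raw 0/1/2 dosages (correlation
is invariant to the standardization). Dichotomizing the outcome while
testing with Gaussian machinery is a deliberate, acknowledged
approximation: it attenuates outcome correlations by roughly the factor
$\phi(0)/\sqrt{1/4} \approx 0.8$ and is part of what the recovery
criteria absorb.

The benchmark derives its module sizes from a template scenario with
`expected_degree = 2` rather than a fixed edge probability, so sparsity
stays constant as modules grow — fixed edge probability would make the
mean degree scale linearly with module size, which neither regulatory
networks nor co-expression modules do.

What the simulator does *not* emulate: linkage disequilibrium between
variants (instruments are pre-clumped in the emulated workflow),
realistic allele-frequency spectra, non-linear or non-Gaussian
expression noise, batch structure, and confounding by unmeasured common
causes. Passing recovery tests therefore demonstrate correctness of the
machinery under the stated model, not robustness to everything real
kidney data contains.

## Problem sizes and reproducibility

The shipped test suite and acceptance script run: 50 oracle DAGs of up
to 10 nodes; 20 simulation seeds at the default 101-node scenario;
benchmark sizes 50–400 nodes with 5 replicates; 2000 null replicates for
test calibration; 200 random instances per statistical primitive; and a
3 × 60-gene planted-partition clustering problem. These sizes were
chosen so the full battery completes in minutes on a single core while
leaving each estimate's Monte Carlo error far below the margins being
asserted. Every random quantity flows from an explicit integer seed;
graph iteration follows the node-table order; and the
simulate-then-infer command-line round trip is byte-identical across
runs with the same seed.

## Known limitations

* Gaussian partial-correlation tests only; no discrete or nonparametric
  CI tests, and binary outcomes are handled by the liability
  approximation described above.
* No latent-confounder machinery (no bidirected edges, no FCI): an
  unmeasured common cause of two genes will appear as an edge or an
  oriented path between them.
* The reported ancestor sets inherit PC's order-dependence in
  principle; PC-stable deletion and fixed iteration order make runs
  reproducible, but different node orderings can still change
  finite-sample output, as in every PC implementation.
* `overlap_test()` treats the gene universe as exchangeable; it knows
  nothing about gene length, expression level or LD-driven selection
  biases that affect real enrichment analyses.
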