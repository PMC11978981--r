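---
title: "Leakage-aware data splitting: model, heuristic, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leakage-aware data splitting: model, heuristic, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldsplit)
library(tibble)
```

## Why similarity-aware splitting

Random train/test splits of biomolecular data routinely place
near-duplicates — molecules sharing a scaffold, homologous proteins — on
opposite sides of the fold boundary. A model evaluated on such a split is
tested in-distribution even when its intended use is out-of-distribution,
and its reported performance is inflated by similarity shortcuts that do
not transfer. `coldsplit` treats splitting itself as an optimization
problem: find the fold assignment that minimizes the similarity crossing
fold boundaries, subject to the folds having (approximately) the sizes and
class composition the user asked for.

## The model

A *split instance* holds elements with entity types t(x) ∈ {1, 2} (one- or
two-dimensional data; cross-type similarity is not supported and counts as
zero), positive integer cardinalities κ(x) (1 for elementary data points,
member counts for clusters), optional class sets σ(x), and one symmetric
pairwise similarity matrix per type with entries in [0, 1]. Distance
matrices may be supplied instead and enter all computations through the
complement 1 − dist. The diagonal is ignored everywhere: leakage and
linkage are sums over unordered *distinct* pairs.

The leakage of a fold assignment π into k folds is

$$L(\pi) = \sum_{\{x, x'\}:\ \pi(x) \ne \pi(x')} \mathrm{sim}(x, x')\,\kappa(x)\,\kappa(x'),$$

and the constraints are lower bounds only: for every fold i and type r the
assigned mass must reach $(1-\epsilon)\, s_i\, n_r$, and for every class c
additionally $(1-\delta)\, s_i\, n_r^c$. No explicit upper bounds are
added — each fold's ceiling emerges from the other folds' floors plus
totality of the assignment. When no element carries a class, all elements
implicitly share one dummy class and the stratification bounds coincide
with the fraction bounds, so they are not emitted twice. When
$\epsilon \ge \delta$ and the classes cover every element, per-class
feasibility implies fraction feasibility; both sets of bounds are always
reported by `check_constraints()` for transparency.

An earlier per-test-sample leakage measure — the mean over test elements
of the single largest similarity to any training element — is provided as
`elangovan_leakage()` for comparison. It ignores everything but the worst
leak per element and is not symmetric in the folds, which is why the
summed, fold-symmetric $L(\pi)$ is the objective here.

For reporting we scale $L(\pi)$ by the total pairwise similarity of the
instance. The denominator carries the same $\kappa$ weighting as the
numerator, which is what guarantees scaled $L \in [0, 1]$ for every
partition; dropping the weights from the denominator only (flag
`kappa_weighted = FALSE` on `scaled_leakage()`) is offered because the
unweighted normalization is also in circulation, but it can exceed 1 on
cluster instances and is not the default.

## Exact solving

`build_ilp()` encodes the problem with binary assignment variables
$\xi_{x,i}$ and one binary cut variable $\zeta_{xx'}$ per unordered
same-type pair with positive objective weight
$\mathrm{sim}(x,x')\,\kappa(x)\,\kappa(x')$. The linearization
$\zeta_{xx'} \ge \xi_{x,i} - \xi_{x',i}$ (one row per fold) forces
$\zeta_{xx'} = 1$ exactly when the pair is separated; minimization with
non-negative coefficients pushes it back to 0 otherwise, so the ILP
objective equals $L(\pi_\xi)$. The $\kappa$ factors sit in the objective
coefficients so that the cluster-level ILP minimizes exactly the
element-level leakage it stands for. Zero-weight pairs get no cut variable
or rows — they cannot contribute to the objective — which keeps desk-scale
models small without changing the optimum.

The default backend serializes the model to JSON and solves it with HiGHS
through SciPy's `milp`, invoked as a subprocess of the system `python`;
many models can be solved in one invocation (`solve_split_batch()`), which
matters when benchmarking hundreds of small instances. HiGHS is run with
`mip_rel_gap = 0` and **presolve disabled**: on these cut-linearized
models, HiGHS's MIP presolve was observed to return solutions flagged
optimal that a feasible integer point strictly beats; without presolve the
true optimum is recovered, and the reduced instances are small enough
(≈ 100 assignment + ≈ 1200 cut binaries at K = 50, k = 2) that presolve is
not needed for speed. Optimal solutions are decoded and re-verified: the
recomputed element-level leakage must match the solver objective to 1e-6
and the constraint report must be feasible.

A second backend, `"enumeration"`, is the independent oracle
(`brute_force_optimum()`): it enumerates all $k^n$ assignments, filters by
the bounds, and breaks ties by the lexicographically smallest assignment
vector. It is capped (default 12 elements) and exists so that the ILP path
can be tested against something that shares none of its code.

Infeasibility is reported, not raised: because cardinalities are integers,
the effective bound of each fraction row is its ceiling, and when those
ceilings sum beyond the available mass no assignment exists;
`check_spec_feasibility()` names the offending bound set before a solver
is ever called. We report such specs as infeasible rather than rounding
bounds down, because silently weakening a user's ε is worse than a clear
failure.

## The cluster-then-solve heuristic

Exact solving scales poorly in $|D|$, so `heuristic_split()` first reduces
the instance to at most K clusters per entity type (default K = 50 —
empirically, split quality saturates around this order and the ILP stays
trivially small), then solves the reduced instance exactly, then unpacks.

*Clustering.* Similarity matrices are clustered spectrally (the matrix is
treated as a kernel matrix; kernlab's implementation, seeded, with a
deterministic spectral-embedding + k-means fallback if the kernel k-means
initialization degenerates, as it can on near-block-constant matrices).
Distance matrices are clustered agglomeratively (average-linkage
hierarchical clustering, cut at K), which is deterministic.

*Reduction.* Cluster cardinality is the summed member cardinality; the
cluster-pair similarity is a linkage over member pairs. On similarities
the orientation is chosen conservatively: `"single"` keeps the *maximum*
member-pair similarity (the strongest potential leak between two
clusters), `"complete"` the minimum, `"average"` the mean; on distances
the conventional min/max/mean apply, followed by 1 − dist. Hierarchical
clustering convention defines linkages on distances only, so the
similarity orientation had to be fixed; keeping the strongest leak under
`"single"` is the choice that cannot understate leakage risk. With unit
cardinalities and average linkage, the cluster-level objective equals the
unpacked element-level leakage exactly; other linkages make the reduced
objective a surrogate (an upper bound for `"single"`, a lower bound for
`"complete"` on similarity instances).

*Classes.* A cluster that mixes classes carries a per-class mass table
aggregated from its members rather than a binary class membership, so the
stratification bounds on the reduced instance are evaluated on true member
masses. Together with mass conservation this gives the guarantee the
pipeline relies on: any feasible cluster partition unpacks to a feasible
element partition.

## Baselines and two-dimensional data

`random_split()` and `stratified_random_split()` implement the
similarity-unaware baselines: a seeded shuffle followed by a greedy fill
that hands each element to the fold that is most underfilled *relative* to
its target $s_i n_r$ (per class for the stratified variant; multi-class
elements sum their classes' relative deficits). Relative — not absolute —
deficit matters: an absolute rule starves small folds of small classes by
one element in edge cases where a feasible allocation exists. The greedy
result is checked against the bounds and an infeasible outcome is an
error, naming the violated bound.

For two-dimensional data, `assign_interactions()` places a record in fold
i exactly when both endpoints are in fold i and discards cross-fold
records; discard counts and fractions are always reported, and the
command-line interface exposes `--min-retained-fraction` to fail runs that
lose too much data. `random_interaction_split()` (technique R) shuffles
records directly and keeps everything — the leakiest baseline. The same
discard rule applies to identity-based (I2) and similarity-based (S2) 2D
splits.

## Small-molecule similarity

`scaffold_fingerprint()` computes Bemis–Murcko scaffolds and hashes their
radius-2 circular (Morgan/ECFP4) fingerprints to 1024 bits, delegating
chemistry to RDKit through a bundled Python helper. Acyclic molecules have
an empty scaffold; they fall back to full-molecule fingerprints (marked
`origin = "full-molecule"`) because an empty scaffold would make all
acyclic molecules mutually identical — the opposite of what a scaffold
split intends. The flag `use_scaffold = FALSE` switches to full-molecule
fingerprints throughout, since both conventions are used for splitting
similarity in practice. Two all-zero fingerprints get Tanimoto 1: they are
indistinguishable objects, and treating them as identical is the
conservative choice for leakage. Sequence-type data enters through
user-provided matrices (`read_matrix()`); no alignment tools are shelled
out to.

User-supplied matrices are min–max normalized to [0, 1] over the
off-diagonal when they arrive outside that range; a constant matrix maps
to zero off-diagonal similarity (no pair is more related than any other,
so nothing should count as leakage). Matrices asymmetric beyond 1e-9 are
rejected; smaller asymmetries are averaged away.

## What the synthetic generators emulate

`make_block_instance()` plants block structure — the idealized form of the
scaffold families and homology clusters that make real cold splits
necessary: high within-block similarity (default 0.9), low between-block
(0.05), optional clipped symmetric Gaussian jitter, optional class labels
either aligned with blocks (to create stratification-versus-similarity
tension) or in exact user-given proportions (largest-remainder counts over
shuffled elements — exact, because random per-element draws can produce
class sizes for which the stratification bounds are integer-infeasible for
*every* split, which would test the bounds rather than the splitters).
`make_two_dim_instance()` gives each entity type its own block structure
and samples an interaction table at a given density with standard-normal
labels. `make_replicated_instance()` and `make_graph_instance()` build the
two constructions with provable optima (the factor-3 copy-replication
identity and the minimum k-section equivalence) used by the verification
suite.

What these fixtures do *not* have: realistic similarity distributions
(true Tanimoto matrices are sparse and heavy-tailed), correlated label
structure, or measurement noise in the similarity itself. Tests passing on
them demonstrate that the optimizer, the constraints, the reduction and
the discard rule behave exactly as specified — not that any particular
biological dataset will yield well-separated splits.

## Numerical choices and problem sizes

Symmetry tolerance 1e-9 (symmetrize by averaging within it, reject
beyond); objective-versus-recomputation agreement 1e-6; constraint
slack 1e-9 on the mass bounds; enumeration ties broken lexicographically
so the oracle is deterministic; all stochastic steps (jitter, shuffles,
spectral initialization) flow from explicit integer seeds. The default
solver time limit is 1000 s; a solve that hits it returns the incumbent
with status `"feasible-time-limit"`. The verification suite runs the
solver-versus-enumeration comparison on 200 instances with up to 10
elements, minimum k-section checks on graphs with up to 9 vertices,
replication identities on bases of 4–6 elements, and the
pipeline/baseline checks on fixtures of 15–40 elements — sizes at which
the independent oracles are exact and the whole suite completes in a few
minutes on one CPU.

## Known limitations

At most two entity types; no cross-type similarities; no custom clustering
algorithms behind `cluster_elements()`; discarded 2D interactions are
reported but not penalized in the objective (a data-loss term would be a
natural extension); and the heuristic's optimality gap is unbounded in
general — only the K = n case provably coincides with the exact optimum,
and the two-block recovery results are properties of well-separated
fixtures, not guarantees.
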