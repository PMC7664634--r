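---
title: "Block learning of discrete Bayesian networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block learning of discrete Bayesian networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blmkm)
```

## The problem

Exact score-based structure learning of a discrete Bayesian network — finding
the DAG that globally minimizes a decomposable score — is feasible only for
small variable counts: the dynamic-programming search expands the full subset
lattice of the variables, whose size is $2^n$, and becomes impractical in the
mid-twenties of nodes. Many real networks, however, are *sparse and blocky*:
groups of variables are densely connected internally while connections between
groups are rare. `blmkm` exploits that structure with a divide-and-conquer
pipeline:

1. **Blocking (MKM).** Partition the variables into $k$ blocks by K-medoid
   clustering under mutual-information similarity.
2. **Skeleton (MMPC).** Recover the undirected adjacency structure with the
   max-min parents-and-children constraint-based procedure and a conservative
   AND symmetry rule.
3. **Combine.** Identify the $m$ skeleton edges that cross blocks and
   enumerate all $2^m$ orientations of them.
4. **Exact search per candidate.** For each orientation, solve every block
   exactly by MDL-scored dynamic programming over order and parent graphs,
   pruned by the skeleton, with the oriented cross-block parents included in
   their children's scores.
5. **Selection.** Assemble each candidate into a full network, discard cyclic
   assemblies, and keep the BIC-best one.

The result is globally optimal *given* the skeleton, the blocking and the
orientation enumeration: each candidate's blocks are solved to optimality and
every orientation of the cross-block edges is scored.

## Scores

All information quantities use natural logarithms so that entropies, the MDL
penalty and the BIC penalty are commensurate.

**Mutual information** between two discrete variables is the plug-in
estimate $I(X;Y)=\sum_{x,y} \hat p(x,y)\log\frac{\hat p(x,y)}{\hat p(x)\hat
p(y)}$ with $0\log 0 := 0$. It is symmetric and non-negative; it is used as a
*similarity*, not a metric — the triangle-type inequality holds only under a
Markov-chain assumption, and nothing in the package relies on it.

**Independence tests** are $G^2$ tests: $G^2 = 2N\cdot\widehat{CMI}$ with
degrees of freedom $(r_i-1)(r_j-1)\prod_{s\in S} r_s$, where conditioning
configurations that never occur contribute nothing and reduce the effective
df (floored at 1). No smoothing is applied anywhere; all scores operate on
raw counts.

**MDL node score.** For child $X_i$ with parent set $PA_i$,
$$\mathrm{MDL}(X_i \mid PA_i) = H(X_i \mid PA_i) + \frac{\log N}{2} K(X_i \mid PA_i),$$
with the empirical conditional entropy on counts
$H = -\sum_{x_i,pa_i} N_{x_i,pa_i} \log (N_{x_i,pa_i}/N_{pa_i})$ and
$K = (r_i - 1)\prod_{l \in PA_i} r_l$ free parameters. The total score of a
DAG is the sum of its node scores (decomposability), and lower is better.

**BIC.** $\mathrm{BIC} = \log P(D\mid \hat\theta_{ML}) - \frac{d}{2}\log m$
with $d = \sum_i K_i$. Under the shared count conventions
$\log P(D \mid \hat\theta_{ML}) = -\sum_i H_i$, so raw BIC is exactly minus
the total MDL; the pipeline computes both, asserts the identity on every fit,
and reports the per-sample normalization $\mathrm{BIC}/m$ alongside the raw
value (normalized magnitudes for a 12-node, 10,000-sample fit land around
$-7$). Maximizing BIC across candidates and minimizing MDL inside the DP are
therefore the same criterion seen from both ends, which is also how the
pipeline reconciles a selection step phrased as a maximization with a search
phrased as a minimization.

## The MKM blocking

The K-means template is adapted in two ways: distances are replaced by
mutual information (higher = more dependent, so assignment maximizes MI to
the medoid), and centers are actual member variables (medoids) rather than
virtual means, since an averaged "variable" has no meaning in a network.
Cluster quality is the cost $\sum_{x \in C, x \neq m} I(x; m)$; a member is
promoted to medoid whenever that strictly increases the cluster cost. Sweeps
of assignment and replacement repeat until the medoid set is stable. Total
cost is non-decreasing across sweeps, which guarantees termination; the
`max_iter` cap (default 100) is a safety net, not a convergence device.

Decisions taken where the procedure was open:

* **Assignment direction.** Maximal MI, ties to the lower-indexed medoid;
  a variable with zero MI to every medoid goes to the smallest-index medoid.
* **Initialization.** Uniform random distinct medoids from the seed; an
  MI-weighted variant (`init = "mi_weighted"`) is available behind a flag.
* **Replacement policy.** Full-sweep: all clusters update their medoid, then
  assignment re-runs (rather than reassigning after every single swap).
* **Choosing k.** Always explicit. `mkm_suggest_k(p)` offers
  $\mathrm{round}(\sqrt{p/2})$ as a convenience but is never applied
  silently, because no principled default exists for arbitrary data.

## The MMPC skeleton

For each target variable the forward phase repeatedly adds the candidate
that *maximizes the minimum association* over conditioning subsets of the
current PC set (association = $G^2$ p-value complement; smaller p = stronger,
ties broken by larger $G^2$), stopping when no remaining candidate is
dependent at level $\alpha$. The backward phase removes any member that some
subset of the others separates from the target. The skeleton keeps edge
$(i,j)$ only when each endpoint is in the other's PC set (AND rule) — the
conservative choice, and the mechanism behind the pipeline's zero
added-edge behavior. Defaults: $\alpha = 0.05$, conditioning sets up to 3,
PC size capped at 10 with a warning (the test count grows exponentially in
the PC size, which is the procedure's known cost).

## Exact search: order and parent graphs

Per block, per variable, the *parent graph* caches
$\mathrm{BestMDL}(X, P) = \min_{S \subseteq P} \mathrm{MDL}(X \mid S)$
bottom-up over the subset lattice of the variable's *skeleton neighbours
inside the block* — subsets touching non-neighbours are never materialized,
which is the skeleton pruning. The *order graph* then runs
$\mathrm{MDL}(O \cup X) = \mathrm{MDL}(O) + \mathrm{BestMDL}(X, O)$
over the block's subset lattice, realized as layered tables that are
discarded after use; the optimal DAG is reconstructed from backpointers.
Blocks beyond 25 variables are refused with an explicit error instructing
the user to re-block, since the plain subset lattice is hopeless past the
mid-twenties.

**Forced external parents.** An oriented cross-block edge $u \to v$ makes
$u$ a *mandatory* parent of $v$ in $v$'s block problem: $u$ joins every
evaluated parent set of $v$, contributing to the counts of $H$ and to $K$,
but is not a node of the subproblem's DAG. A config switch
(`forced_mandatory = FALSE`) downgrades such parents to optional candidates
that are always available regardless of the order mask.

**Ties and the canonical member.** Score-equivalent DAGs are common —
Markov-equivalent structures have exactly equal likelihood and, because
covered-edge reversal preserves $K$, exactly equal MDL. Deterministic
tie-breaks fix one canonical member: parent sets of equal score go to the
smaller, then lexicographically smaller, set; score-tied leaf choices in the
order graph go to the higher-indexed variable, so lower-indexed variables
enter the build order earlier. Because equivalent orderings accumulate the
same node scores in different sequences, ties are detected with a $10^{-9}$
relative tolerance (float summation noise is orders of magnitude below any
genuine score difference at the sample sizes involved), and the stored
score always keeps the minimum.

**Cycles across blocks.** Orientations of the inter-block edges cannot be
pre-filtered for global acyclicity because intra-block directions are
unknown until the DP runs; assembled candidates that turn out cyclic are
discarded at selection time, counted, and reported in the fit's provenance.
Selection ties between acyclic candidates go to the first in enumeration
order (lowest orientation bitmask, i.e. low-index-to-high-index directions
first).

## The synthetic-data generator

`generate_block_network()` emulates the sparse block regime the pipeline
targets: several densely connected blocks joined by a handful of crossing
edges. Edges point from lower to higher variable index (fixing a topological
order); within-block pairs are sampled to a target density, crossing pairs
to an exact count. CPT rows are symmetric Dirichlet draws (concentration
0.5) rejected until their total-variation distance from uniform is at least
0.1, so that every edge carries a detectable signal.

The study fixture used throughout the tests is 3 blocks x 4 nodes with 2
inter-block edges, cardinalities 2-3, and intra-block density 0.7. The
density was chosen from the edge-per-node ratios of the classic benchmark
networks of this size class (roughly 1.2-1.5 edges per node): 0.7 gives 4 of
the 6 possible edges per 4-node block, about 1.17 edges per node overall.
Full density would make blocks complete — and a complete block's direction
structure is entirely unidentifiable, which no algorithm can recover.

What the generator does *not* emulate: latent confounders, selection bias,
deterministic relations, missing data (rejected at load time, since every
score assumes complete counts), and real-world cardinality skew. Passing
tests on this fixture therefore demonstrate correct optimization and
faithful-case recovery, not robustness to those complications.

## Problem sizes and numerical choices

The suite's study conditions, chosen as realistic desk-scale instances of
the regime: oracle-equivalence checks use 200 random problems of 3-5
variables at $n = 1000$; skeleton-recovery and end-to-end checks use 8-12
variables at $n = 10{,}000$ over 20 seeds; the degenerate-blocking check
uses 10 variables at $n = 2000$. The exhaustive test oracle enumerates every
parent-set assignment and filters acyclic ones up to 4 variables (25 DAGs at
3 variables, 543 at 4), and switches to enumerating all 120 topological
orderings with per-node subset minimization at 5 variables; the two modes
are cross-validated against each other. The oracle returns *all* optimal
structures so that agreement checks are robust to tie-break conventions
between independent implementations.

Structure recovery is scored by the Hamming decomposition against the
generating truth: added (A), missing (M) and inverted (I) adjacencies, with
$H = A + M + I$. Because learned adjacencies are confined to the MMPC
skeleton, A is structurally zero whenever the skeleton has no false
positives; residual error is dominated by M (weak edges whose entropy gain
does not beat the MDL penalty) and I (orientation choices within
score-equivalent classes).

## Known limitations

* Reference networks from the public BN repository (e.g. the 11-node
  protein-signalling benchmark) are not bundled; benchmarks against them run
  only when the user supplies the BIF files.
* The $2^m$ orientation loop assumes few inter-block edges; the cap
  (default 16) converts silent blow-up into a diagnosable error, and a finer
  blocking is the remedy.
* MI estimates and $G^2$ tests are plug-in/asymptotic; no bias correction or
  permutation testing is offered.
* Only complete-case discrete data is supported: no Gaussian variables, no
  imputation, and no `.net`/`.dsc` BIF dialects.
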