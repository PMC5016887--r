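---
title: "Driver proteins by collective-influence-corrected minimum dominating sets"
author: "ciMDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver proteins by collective-influence-corrected minimum dominating sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciMDS)
```

## The model

In an undirected protein interaction network $G = (V, E)$ a *dominating set*
is a node subset $S$ such that every protein is in $S$ or interacts with a
member of $S$; a *minimum dominating set* (MDS) is a smallest such subset,
and its size is the domination number $\gamma(G)$. Under network
controllability arguments the members of an MDS are candidate driver nodes:
perturbing them reaches the whole network in one step. Finding an MDS is the
binary integer program

$$\min \sum_{v \in V} x_v
  \quad \text{s.t.} \quad
  x_v + \sum_{u \in N(v)} x_u \ge 1 \;\; \forall v \in V,
  \quad x_v \in \{0, 1\},$$

which is NP-complete but solvable exactly at the network sizes that arise
here. The practical difficulty is not the solve but the *degeneracy*: real
networks admit many MDS configurations of the same size, and different exact
optimizers return different ones, so the reported driver set is an artifact
of the solver.

The correction implemented here selects, among all minimum dominating sets,
the one whose members carry the highest total **collective influence**

$$CI_\ell(v) = (d_v - 1) \sum_{u \in \partial \mathrm{Ball}(v,\ell)} (d_u - 1),$$

where $d_v$ is the degree and $\partial \mathrm{Ball}(v,\ell)$ the set of
nodes exactly $\ell$ hops from $v$. This is a second binary program over the
same cover constraints with the cardinality pinned to $\gamma(G)$ as a hard
equality:

$$\max \sum_v CI_\ell(v)\, x_v
  \quad \text{s.t.} \quad
  x_v + \sum_{u \in N(v)} x_u \ge 1 \;\; \forall v, \qquad
  \sum_v x_v = \gamma(G).$$

Only two solves are needed in total. Because all $CI_\ell$ scores are
integers, the maximal objective is compared exactly, with no floating-point
tolerance anywhere downstream.

### Assumptions and conventions

* The graph is simple and undirected. Self-loops and duplicate edges are
  canonicalized away on ingest; a self-loop would make a node dominate
  itself twice under the cover constraint, which the model does not intend.
  Weighted or directed variants are out of scope — the dominating-set model
  is defined on unweighted adjacency.
* Isolated nodes have a degenerate constraint $x_v \ge 1$ and are forced
  members. Their collective influence is defined as 0 (the reduced degree
  $-1$ of an isolated node has no meaning; analyses normally run on a
  connected component, and 0 extends the definition without special cases).
* Residual ties — several MDSs attaining the same maximal total
  $CI_\ell$ — are possible (any vertex-transitive graph is a worst case).
  The contract is that size and total CI are solver-invariant; membership
  within an exact tie is backend-dependent. `enumerateAllMDS()` exposes a
  deterministic lexicographic enumeration for small graphs when full
  reproducibility of membership is needed.
* Betweenness is reported unnormalized (raw path counts, each unordered
  pair once). All uses are rank or distribution comparisons, so any fixed
  convention works; it is documented and constant.
* The largest-component tie (two equally large components) is broken toward
  the component containing the lexicographically smallest label, purely for
  determinism.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `ell` | hop distance of the CI frontier | 1 | $\ell = 0$ collapses to squared reduced degree (degree-like); large $\ell$ reaches the network boundary and all scores shrink toward 0. $\ell = 1$ keeps topological content beyond degree while staying well inside typical network diameters, and the selected members are stable for $\ell \in \{1,2,3\}$ (checked via `mdsOverlap()` across $\ell$). |
| `threshold` (per source) | expression call cutoff | none — mandatory | each platform (microarray, antibody-based, RNA-seq) needs its own stringent cutoff; a missing threshold is a configuration error caught before any solve. Calls use strict `>` ("exceeds"), switchable to `>=`. |
| `hkMin`, `tsMax` | breadth cutoffs for housekeeping / tissue-specific classes | 14, 3 | the established convention for a 16-tissue panel (expressed in 14–16 vs 1–3 tissues). They are plain inputs: for other panel sizes choose values explicitly; nothing is rescaled automatically. |
| `tsStrict` | TS-MDS reading | `TRUE` | strict: a tissue-specific MDS protein must be selected in *every* tissue where it is expressed ($n_{MDS} = n_{expr}$); relaxed (`FALSE`): selected in at least one. Both readings are defensible; strict is the default and the switch makes the difference auditable. |
| `backend` | exact solver | `"bb"` | see below. |
| `universe` | enrichment background | `"union"` | proteins present in at least one tissue network form the natural background for class enrichment; `"global"` (all interactome proteins) is available because the choice is genuinely ambiguous and materially changes p-values. |

## Exact solving and the two backends

Two interchangeable exact backends are wired so that optimality claims can
be cross-checked rather than trusted:

* **`bb`** — a depth-first branch-and-bound written in R. It branches on the
  uncovered node with the fewest admissible coverers (closed-neighbourhood
  candidates), excludes each candidate after exploring it so no cover is
  enumerated twice, and prunes with (i) a covering lower bound
  $\lceil \text{uncovered} / \max_u |N[u] \cap \text{uncovered}| \rceil$,
  (ii) for stage 2, an optimistic bound adding the heaviest remaining
  scores to the incumbent. A greedy cover seeds the incumbent. Once all
  nodes are covered in stage 2, remaining slots up to $\gamma(G)$ are
  filled with the heaviest admissible nodes (supersets of dominating sets
  remain dominating).
* **`highs`** — the HiGHS branch-and-cut MILP solver, driven through SciPy's
  `optimize.milp` with `mip_rel_gap = 0` via the `python` interpreter on
  `PATH`. The problem is shipped as JSON; an unproven or failed solve is an
  error, never a silently suboptimal set.

Agreement of $\gamma$ and of the maximal total CI between the two backends
on random ensembles is part of the test suite. The branch-and-bound backend
is comfortable to a few hundred nodes on sparse graphs; the MILP backend
scales further and is the recommended choice for large inputs.

## Tissue-specific networks

A tissue network is built by **node removal**: keep the proteins called
expressed in the tissue (so every retained interaction joins two proteins
co-expressed there), then keep only the largest connected component. The
LCC step removes small isolated fragments whose trivial domination would
inflate and distort the driver set; it is applied per tissue *after*
filtering, and the global network is never pre-trimmed. A protein counts as
"expressed in a tissue" downstream exactly when it is a node of that
tissue's post-LCC network — the same object all dominating-set calls
operate on — so breadth counts, histograms and classes are internally
consistent. Expression calls OR across sources: a gene expressed according
to any one platform is expressed; a gene absent from a platform's universe
contributes "not expressed" for that platform and is never an error.

## Classification

Per protein, `countBreadths()` counts tissues of presence
($n_{expr}$) and tissues of MDS membership ($n_{MDS}$), with
$0 \le n_{MDS} \le n_{expr} \le T$. The six classes
(HK-MDS, TS-MDS, Remaining-MDS, HK-NMDS, TS-NMDS, Remaining-NMDS) partition
the union protein set by MDS status ($n_{MDS} \ge 1$) crossed with breadth
(housekeeping $\ge$ `hkMin`, tissue-specific $\le$ `tsMax`, remainder in
between). Partition and marginal-reconciliation checks
(`#HK-MDS + #TS-MDS + #Remaining-MDS = #{n_{MDS} \ge 1}`) run on every
fixture in the suite.

## Statistics layer

Class enrichment uses the exact one-sided (greater) Fisher test: the
p-value is the hypergeometric upper tail of the observed overlap, computed
with `phyper` and verified in the suite against an independent
log-factorial summation to $10^{-9}$ relative tolerance. One-sided testing
matches the directional question (enrichment); depleted classes legitimately
return p near 1. Raw p-values are reported with no multiple-testing
correction by default, `stats::p.adjust` being one line away for batteries
of tests. Distribution contrasts between classes use the two-sample
two-sided Kolmogorov–Smirnov test with the asymptotic p-value; group sizes
in this context are hundreds to thousands, where the asymptotic law is
accurate, and using it unconditionally keeps the convention constant.

## What the synthetic data emulate — and what they do not

`randomNetwork()` provides Erdős–Rényi and preferential-attachment graphs;
PA reproduces the heavy-tailed degree profile of an interactome well enough
to exercise hub-vs-leaf behaviour of the solver. `syntheticExpression()`
draws each gene's true breadth from a three-band mixture — 65.9 %
housekeeping (top three breadth bins), 10.7 % tissue-specific (bins 1–3),
the rest mid-range, matching the bimodal breadth profile reported for human
16-tissue panels — then scatters each expressed call over a random
non-empty subset of three sources (so the OR rule is load-bearing) and
drops ~10 % of genes per source to emulate differing platform universes.
`plantedMultiMDSNetwork()` builds, for any seed, a hub-plus-satellites graph
with $\gamma = 2$, exactly three MDS configurations and a unique CI-optimal
one, verified internally by enumeration — the canonical degenerate case the
correction exists to resolve.

These generators do **not** reproduce interactome community structure,
degree–expression correlation, or the co-expression of interacting
partners. Passing tests therefore certify the algorithms (exactness,
invariants, calibration), not biological conclusions about any real
tissue; analyses of real interactomes must supply their own curated
networks and thresholds.

## Numerical and design choices

* All CI scores and objectives are integers; ties and optima are compared
  exactly.
* The stage-2 cardinality constraint is an equality, not an upper bound, so
  the result is an MDS by construction even if the CI weights would prefer
  a larger set.
* The enumeration oracle refuses graphs above 16 nodes (subset counts grow
  combinatorially; it exists for ground truth in tests, not for analysis).
* The overlap metric between driver sets is the Jaccard index; it is a
  parameter-free default and is exposed directly (`mdsOverlap`) rather than
  hidden in reports.
* Degenerate inputs: empty networks, unknown nodes/tissues, empty gene
  sets, candidate sets outside the network and thresholds missing from a
  source all raise immediate, named errors; nothing degrades silently.
* Problem sizes in the shipped tests and the reproduction script are kept
  at fixture scale (tissue networks of tens to a few hundred nodes, solver
  cross-check ensembles of 50 graphs at 20–40 nodes, 200 oracle graphs at
  4–12 nodes) — large enough to exercise every branch of the exact solvers
  and the bimodal mixture, small enough to rerun anywhere in minutes.

## A short worked example

```{r example, eval = FALSE}
pm <- plantedMultiMDSNetwork(seed = 1)
pm$mdsList            # three equally small dominating sets
solveCIMDS(pm$network, ell = 1)   # the unique CI-optimal one

g <- randomNetwork(120, m = 2, model = "pa", seed = 1)
expr <- syntheticExpression(g, nTissues = 16, seed = 2)
tns <- buildTissueNetworks(g, callExpression(expr$sources))
mds <- lapply(tissueNames(tns), function(t)
    dsMembers(solveCIMDS(tissueNetwork(tns, t))))
names(mds) <- tissueNames(tns)
classes <- classifyProteins(countBreadths(tns, mds))
table(classes$label)
```

## Known limitations

* Exact solving is the point; there is no heuristic fallback for networks
  beyond what branch-and-bound or MILP can prove optimal.
* The critical/intermittent/redundant node taxonomy (which requires $|V|$
  solves) and centrality-weighted MDS variants with tunable weights are
  deliberately not implemented.
* KS p-values are asymptotic; for groups of fewer than ~20 proteins treat
  them as indicative only.
* `hkMin`/`tsMax` defaults target a 16-tissue panel; there is no principled
  automatic rescaling to other panel sizes.
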