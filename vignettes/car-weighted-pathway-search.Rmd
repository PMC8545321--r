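---
title: "CAR-weighted pathway search: model, parameters and design notes"
author: "carpath maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAR-weighted pathway search: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carpath)
```

## The problem

Shortest-path search on a naive metabolite graph is biochemically blind: it
happily routes glucose to an aromatic compound "via ATP" because hub
metabolites (ATP, CO2, H2O, CoA) touch thousands of reactions. A
biologically meaningful linear pathway instead conserves a core of atoms
from source to target across consecutive enzymatic steps. carpath encodes
that preference directly in the edge weights of the search graph, so that
standard graph algorithms find atom-conserving routes first, without
hand-curated cofactor blacklists.

## The Conserved Atom Ratio

Every atom-mapped reaction is split into all reactant x product pairs. For
a pair with $n_c$ shared non-hydrogen atoms, $n_r$ reactant and $n_p$
product heavy atoms,

$$CAR_r = \frac{n_c}{n_r}, \qquad CAR_p = \frac{n_c}{n_p},$$
$$CAR = \frac{CAR_r + CAR_p}{2}\,\bigl(1 - |CAR_r - CAR_p|\bigr).$$

The mean of the two one-sided ratios is damped by a correction factor that
punishes size mismatch: a CO2 molecule fully mapped into a large substrate
has $CAR_p = 1$ but a small mean and a large mismatch, so its pair scores
low. Hydrogens never enter the counts; the result is clamped to $[0,1]$
(the correction factor alone cannot push it negative, but the clamp makes
the contract explicit, since the CAR doubles as a classifier score).

Two properties are worth knowing:

* `computeCAR` is symmetric in $n_r, n_p$ and never exceeds the plain mean
  of the one-sided ratios;
* the CAR is **not** monotone in $n_c$ when the molecules differ in size.
  `computeCAR(1, 12, 2)` = `r round(computeCAR(1, 12, 2), 4)` exceeds
  `computeCAR(2, 12, 2)` = `r round(computeCAR(2, 12, 2), 4)`: conserving
  one more atom increases the mismatch penalty faster than the mean. This
  is intrinsic to the correction factor, not an implementation artifact;
  between equal-sized molecules monotonicity does hold, and the test suite
  asserts exactly that split.

### Coenzyme A as a single pseudo-atom

Two CoA thioesters share the ~48 heavy atoms of the cofactor, so an acyl
swap would score CAR close to 1 no matter how much the interesting acyl
chemistry changes. When a CoA-carrying compound occurs on *both* sides of
a pair, the moiety is therefore collapsed to a single conserved
pseudo-atom on each side before counting; the pair's CAR then reflects the
acyl groups. Contraction is strictly per pair — a thioester paired with a
CoA-free leaving group keeps its ordinary counts. Identifying the moiety
inside an arbitrary atom map would require substructure matching on
molecular structures; carpath instead expects the moiety's map indices to
be annotated on the molecule (`attr(atoms, "coa")`, or the `coa_indices`
column of the structured reaction table) and carriers to be flagged in the
compound table (`coa_carrier`). The free cofactor itself (KEGG `C00010`)
is excluded from the graph by default, because even the contracted pairs
around free CoA are biochemically uninformative; the exclusion list is a
plain argument and can be extended to a full cofactor list for benchmark
networks in which cofactors are removed wholesale.

## From CAR to distance

Edges carry a distance derived from the CAR under one of three transforms,
all equal to 1 for a perfectly conserving pair:

| transform | distance | effect |
|-----------|----------|--------|
| `default` | $1/CAR$ | baseline |
| `sqrt`    | $\sqrt{1/CAR}$ | softens the conservation penalty; favours short routes |
| `exp`     | $e^{1/CAR}/e$ | sharpens it; favours conserving routes even when long |

The typeset forms of the two alternatives are easy to misread; the
readings used here are the only ones for which all three transforms agree
at $CAR = 1$ and bracket the default from below and above — the ordering
$d_{sqrt} < d_{default} < d_{exp}$ holds strictly on $(0,1)$ and is
asserted property-style in the tests. The hub-shortcut fixture
(`makeHubShortcut()`) shows the practical consequence: a 2-step route
through a CAR-0.2 hub scores 10.0 (default), 4.47 (sqrt) and 109.2 (exp),
while a 5-step CAR-0.9 chain scores 5.56, 5.27 and 5.59 — so the sqrt
transform picks the shortcut and the exponential transform pays five
well-conserving steps over two lossy ones. (Under the default transform
the chain also wins on this fixture: 5.56 < 10.0. Which route wins under
`default` depends on the actual CARs and lengths; only the two extreme
transforms are guaranteed to disagree here.)

## Graph construction

`buildPairGraph()` is deliberately strict about what becomes an edge:

* pairs with $CAR = 0$ are dropped (nothing conserved, infinite distance);
* stereoisomers are merged on the first fourteen InChIKey characters — the
  connectivity block, which ignores stereochemistry, charge and isotopes —
  with the lexicographically smallest member id as the node id; compounds
  without a valid key fall back to themselves, and malformed keys are
  treated as absent with a warning rather than silently trusted;
* pairs whose endpoints merge onto one node would be self-loops and are
  dropped with a warning (a loop can never sit on a loop-less path);
* parallel pairs between the same two nodes collapse into a single edge
  carrying the **maximum** CAR and the union of supporting reaction ids —
  shortest-path semantics only ever use the best edge, and reporting keeps
  every reaction alternative.

The graph is undirected: the pair relation is symmetric and pathways may
traverse any reaction in either direction. Where a directed-arc count is
conventional (network reports), each undirected edge counts as two arcs.

`thresholdSubgraph()` produces the unweighted view: edges with CAR
*strictly* greater than the threshold survive with unit distance. The
default threshold of 0.34 is the Youden-optimal cutoff for predicting
main biotransformation pairs (below).

## Pathway search

`yenKShortest()` implements Yen's k-shortest loop-less path algorithm with
Dijkstra as the inner routine. The implementation is in-package because
the output contract demands more than a stock routine offers:

* **Determinism.** Candidates and results order by (score, step count,
  lexicographic node sequence), with a 1e-9 tolerance for score ties; when
  the k-th place is tied the candidate pool is drained before truncation so
  the returned set never depends on extraction order. The suite checks the
  output against exhaustive simple-path enumeration on 100 seeded random
  graphs and against igraph's independent k-shortest implementation.
* **Length cap.** Candidates longer than `maxLength` steps (default 100)
  are discarded but do not count toward `k` — `k` is the number of
  pathways *returned*, not attempted.
* **Degenerate queries.** Unknown ids fail naming the id; source = target
  is rejected; endpoints in different components return an empty result
  after a connectivity warning (`connectivityCheck()` offers the same test
  up front, on the thresholded view, as a structured warning).

Pathways report a score (sum of step distances; lower is better) and an
average CAR (mean of step CARs; a quality summary independent of length).
One representative reaction (smallest id) is printed per step; the full
sets stay in the object and in the JSON dump.

On unweighted views, `twoSidedUnweightedSearch()` enumerates all
minimum-hop simple paths along the meet-in-the-middle of the two BFS
distance fields — the fast mode for big thresholded networks — and falls
back to the unit-weight k-shortest search for ranks beyond the minimum-hop
layer, keeping identical loop-less/`k` semantics.

## Validating CAR as a main-pair classifier

`rocAnalysis()` scores the CAR against curated binary labels ("is this the
main biotransformation pair of its reaction?") on a grid of 100 cutoffs
$c_i = i/100$; prediction is inclusive (`car >= c`), so a zero cutoff is
the degenerate all-positive classifier and the grid covers (0, 1]. AUC is
the trapezoidal area under the (FPR, TPR) points closed with (0,0) and
(1,1) — on continuous scores it agrees with the rank-based estimator to
well under a percentage point, which the suite cross-checks against pROC.
The optimal cutoff is the smallest grid point maximising Youden's index
(sensitivity + specificity − 1). Ties in the argmax take the smallest
cutoff; both choices are deterministic conventions, not statistics.

## What the synthetic data emulates — and what it does not

The package tests itself entirely on generated fixtures:

* `makeHubShortcut()` encodes the motivating shortcut-vs-chain scenario
  with hand-derived ground-truth scores;
* `makeCoaCase()` encodes three CoA thioester transformations plus a
  small-molecule analog, with hand-counted atom sets, such that
  contraction flips the best route between two thioesters;
* `makeLabeledPairs()` draws the two CAR populations from Beta
  distributions — positives Beta(1.6, 1.4), negatives Beta(1.3, 5.75),
  class sizes 5148/5599. The shapes were calibrated once so that the
  theoretical AUC (0.880) and density crossing (0.341) match the
  discrimination reported for the curated reference pair set, making the
  downstream ROC numbers meaningful rather than arbitrary;
* `makeRandomGraph()` provides seeded Erdos-Renyi networks for
  oracle-equivalence tests (n <= 50, where brute force is exact and fast).

All generators are deterministic given a seed and restore the caller's RNG
state. What passing tests on these fixtures shows is algorithmic
correctness: formula values, orderings, determinism, equivalence with
brute-force oracles. What they cannot show is performance on real curated
networks — real CAR distributions are not Beta, real degree distributions
are heavy-tailed, and real atom maps contain polymer/R-group oddities the
generators do not model. The replication checks against the curated KEGG
reactant-pair network (published statistics: 5578 nodes, 20 911 directed
arcs, 813 components above the 0.34 threshold, diameter 40; AUC 0.88) are
therefore wired into the acceptance tests but require that dataset to be
placed locally; they report as failures, not skips, when it is absent.

## Numerical choices and problem sizes

Score ties use a 1e-9 absolute tolerance; CAR cross-checks on load use
1e-6 (pair files rarely carry more precision). Report tables round to two
decimals with banker's rounding; machine dialects keep 17 significant
digits and round-trip bit-exactly. Oracle tests run on graphs of 5–20
nodes (100 seeds for search, 50 for network statistics) and ROC checks on
10 000–10 747 labelled pairs — sizes at which exhaustive enumeration
stays exact while exercising every code path; the whole suite completes in
a few minutes on one core.

## Known limitations

* Atom maps are consumed, never produced: reaction SMILES must already
  carry map numbers, and map validity is the caller's responsibility.
* The SMILES reader extracts heavy-atom counts and map indices only; it
  does not canonicalise structures, so unnamed molecules are identified by
  their map-stripped SMILES string, which conflates nothing but also
  merges nothing beyond textual identity.
* CoA moieties must be annotated; there is no substructure detection.
* Pathways are linear by construction — branched routes appear only as
  their linear decompositions.
* No feasibility checks (thermodynamics, flux, enzyme availability); the
  output is a ranked hypothesis list, not a validated design.
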