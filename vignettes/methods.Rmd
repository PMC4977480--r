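---
title: "Inferring signaling networks from partial RNAi data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring signaling networks from partial RNAi data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinecr)
```

## The model

A signal transduction pathway is modelled as a simple directed graph over
named genes with a designated receptor gene (where the external signal
enters) and reporter gene (where its effect is read out). A single-gene
knockdown RNAi experiment classifies each gene: **critical** if knocking it
down blocks signal flow — structurally, the gene lies on *every* directed
path from receptor to reporter — and noncritical otherwise. A constraint
vector stores one value per gene: 1 (critical), 0 (noncritical), or -1
(experiment missing). A network is **consistent** with a constraint vector
when every 1-gene is critical in it and every 0-gene is not; -1 imposes
nothing. The receptor and reporter are critical by definition, so a 0 on
either is rejected at construction.

Two modelling conventions worth stating explicitly:

* **Walk semantics.** "Lies on every path" is evaluated by node deletion
  plus reachability, which is exact whether paths may revisit nodes or not,
  because containment of a node is monotone under revisits.
* **Vacuous criticality.** If a network has *no* receptor-to-reporter path,
  the universal condition holds vacuously and every gene is reported
  critical. Constructed networks always contain such a path, so this only
  surfaces on raw inputs; we chose the faithful reading over a special case.

The distance between two networks on the same gene set is the size of the
symmetric difference of their edge sets. Given a reference network and a
constraint vector, the inference problem is to find a consistent network at
minimum distance from the reference.

## Ranking critical genes

The constructor needs the critical genes in the order the signal plausibly
visits them. Two strategies are provided.

**Sloan.** The classic profile-reduction ordering run on the undirected
view of the network: node priority is $-W_1\,\deg(v) + W_2\,d(v,
\text{reporter})$ with the standard weights $W_1 = 1, W_2 = 2$; the
highest-priority *preactive/active* node is numbered next, and numbering or
activating a node raises its neighbours' priorities by $W_1$. Ties break by
stable gene order (the order genes first appear in the input, which we use
as the global tie-break everywhere). Untouched components are restarted
from the best remaining node. The total order is then restricted to the
critical genes.

**TopSoG.** A topological sort generalized to cyclic graphs: (i) find the
strongly connected components; (ii) pick an entrance for each multi-gene
component; (iii) condense components into super nodes, giving a DAG;
(iv) traverse the DAG depth-first from the receptor's node, preferring the
unvisited successor with the largest score $1/d_s - 1/d_t$, where $d_s$ and
$d_t$ are shortest directed distances from the receptor and to the reporter
measured in the *original* network, with the convention $1/\infty = 0$;
(v) expand each super node in place by the same guided traversal of the
component's induced subnetwork from its entrance. Genes unreachable from
the start are appended afterwards, sorted by score then gene order, so the
restriction to criticals is always total. A super node scores as its
entrance (the gene through which the signal enters it) — the one defensible
scalar summary of a component's position.

**Entrance selection.** The entry points of a component are its members
with an incoming edge from outside. Selecting among them by the smallest
sum of within-component distances to the other entry points is a sensible
centrality heuristic, but on its own it can pick an entry point that is fed
only from *downstream* of the component; the within-component expansion
then runs against the direction of signal flow, and the constructor will
"repair" a reference that is already consistent. We therefore restrict the
candidates to **first-contact** entry points — those with an outside
predecessor reachable from the receptor without touching the component —
whenever any exist, and apply the distance-sum rule (ties by gene order)
among them. A component containing the receptor uses the receptor; one
with no entry point at all falls back to the member with the best priority
score. With this refinement one can show that on a network already
consistent with its constraints, the guided traversal visits the critical
genes in their canonical order (the unique order in which every
receptor-to-reporter path meets them), which is what makes the constructor
a no-op on consistent inputs.

Both rankings are independent of *which* genes are critical, so the
optimizers compute each reference's total ranking once and restrict it per
constraint assignment. The restriction pins the receptor first and the
reporter last; both algorithms can otherwise strand the reporter mid-order
in degenerate inputs (e.g. a reporter inside a cycle).

The motivating contrast between the two strategies is packaged as
`fig1_network()`: gene `va` feeds `vb` and both sit one step from the
reporter, so causality puts `va` first (TopSoG), while `vb`'s larger,
early-activated neighbourhood makes Sloan number it first. The fixture
verifies its own defining properties programmatically on creation.

```{r fig1}
fx <- fig1_network()
sloan_order(fx, attr(fx, "criticals"))
topsog_order(fx, attr(fx, "criticals"))
```

## The constructor

Given a complete constraint vector, `sinec_construct()` works in three
steps on the reference:

1. **Rank** the critical genes (above), yielding $g_0 = $ receptor,
   $g_1, \dots, g_m$, $g_{m+1} = $ reporter.
2. **Delete** edges that conflict with the ordering: after deletion, no
   path whose interior genes are all noncritical may connect two
   nonconsecutive critical genes (such a path would let the signal bypass
   the critical gene between them). For each consecutive pair index $i$ we
   compute a minimum unit-capacity edge cut separating $g_i$ from all of
   $\{g_{i+2}, \dots, g_{m+1}\}$ in the subnetwork whose interior is the
   noncritical genes ($g_{i+1}$ and all other critical genes removed;
   later criticals act as pure sinks). Cuts are computed sequentially on
   the progressively deleted network — never larger than cutting on the
   pristine network — and unioned. Backward edges (towards earlier
   segments) are never deleted: they cannot complete a forward bypass.
   Max-flow is an in-package Edmonds–Karp specialized to unit capacities;
   the test suite cross-checks it against an independent max-flow
   implementation.
3. **Insert** the direct edge $(g_i, g_{i+1})$ for each consecutive pair
   where either no admissible path remains (case 1) or some noncritical
   gene sits on *all* admissible paths and no direct edge exists (case 2 —
   left alone, that gene would itself become critical, contradicting its
   constraint). Detection of case 2 removes each interior candidate in
   turn and tests reachability. The direct edge is the single cheapest fix
   for both cases; no alternative rewiring is attempted.

Two guards complete the step: if the reference is already consistent with
the constraints the constructor returns the empty edit script immediately
(by the problem definition this is the exact optimum, and it makes the
constructor idempotent); and after insertion the result is re-verified
against the full constraint vector, raising an error naming the offending
genes if violated — this guards implementation bugs, and no generated
instance has ever triggered it.

Per-pair cuts unioned sequentially are not guaranteed globally minimal.
On enumerable instances (at most 10 genes / 14 edges / two intermediate
criticals) the deletion step matches the subset-enumeration minimum on
over 90% of seeded instances and the full edit script matches the
brute-force minimal consistent-network distance at a similar rate, never
exceeding it by more than a couple of edits; exact minimality is not
claimed.

## Resolving unknown genes

Real pathways have few critical genes, so all three optimizers start from
the completion that sets every unknown to noncritical.

* **Holistic** hill climbing: each round, every still-noncritical unknown
  is temporarily set critical, the network rebuilt, and the best strictly
  improving flip accepted permanently; stop when no flip improves. Flips
  are one-directional (0 to 1) and never reverted. $O(n^2)$ constructions.
* **Prioritized** hill climbing: each unknown is first probed alone and
  the resulting distance recorded; unknowns are grouped by equal probe
  distance (smaller probe distance signalling higher likelihood of being
  critical) and the groups climbed in increasing order, holistic-style
  within the group, advancing when a group stops improving. All groups are
  processed — this matches the method's stated
  $O(n + \sum_i n_i^2)$ cost. Completions are memoized by assignment and
  cache hits are free: the $n$ probes *are* each group's first sweep.
  When the baseline already has distance 0 the probe phase is skipped;
  nothing can improve an exact match.
* **Exhaustive**: all $2^n$ completions, exactly $2^n$ constructions
  (refused above a configurable cap, default $n = 20$). Ties prefer fewer
  critical genes, then the lexicographically smallest assignment.

Climbing ties (several equally best flips) resolve to the gene earliest in
stable gene order, so all runs are deterministic. Because a sweep accepts
only strictly better flips, hill climbing terminates at assignments where
no *single* flip helps; pairs of jointly beneficial flips are invisible to
it. On small seeded instances (8–12 genes, up to 6 unknowns, 15% noise)
both climbers reach the exhaustive optimum on roughly three quarters of
instances and never beat it; every observed miss is such a strict local
optimum. On larger networks at the benchmark's scale the discrepancies
vanish in the sweep averages.

## The synthetic benchmark

`make_benchmark()` emulates the synthetic study design end to end:

* **Targets** grow by preferential attachment: `density` (default 3)
  initially isolated core genes; each arriving gene attaches `density`
  edges to distinct existing genes with probability proportional to
  current degree (uniform while all degrees are zero), each edge oriented
  by a fair coin — the attachment model is undirected by nature and the
  orientation convention is ours. Exactly `density * (size - density)`
  edges result. Targets whose terminals cannot be placed are regenerated
  from a derived seed.
* **Terminals** sit on a diameter path: the maximum finite entry of the
  all-pairs shortest-path table defines receptor (source) and reporter
  (sink), ties broken uniformly at random under the seed.
* **Constraints** are the ideal noise-free screen: genes on all
  receptor-to-reporter paths get 1, the rest 0; a target is always
  consistent with its own derived constraints. `mask_unknown()` then sets
  `n_unknown` genes (default 15; never the terminals, whose status is
  definitional) to -1.
* **References** come from degree-preserving double edge swaps: a mutation
  rate $r$ rewires $r \cdot |E|$ edges via $\lceil r|E|/2 \rceil$
  successful swaps $(a,b),(c,d) \to (a,d),(c,b)$, rejecting self-loops,
  duplicates and no-ops; in- and out-degrees are preserved exactly.
  References are not required to keep the receptor-reporter connection —
  the constructor can insert edges.

The default grid is four sizes (50, 75, 100, 125) times ten replicates
with seven noise levels (5%–35% in steps of 5), i.e. 40 targets and 280
references; the default noise for single-condition runs is 15%. Every
artifact's seed is recorded in `manifest.json`, and regeneration from the
manifest is byte-identical.

What the generator does *not* emulate: signed or weighted interactions,
hub-biased terminal placement, correlated noise between paralogous edges,
and the modular structure of curated pathways. Passing the synthetic suite
therefore shows the algorithms handle scale-free topology and
degree-preserving noise, not that they capture every property of real
screens; real-network use goes through the generic TSV/SIF/GraphML
readers.

## Numerical and degenerate-input choices

* $1/\infty = 0$ throughout the priority score; the receptor itself takes
  score $+\infty$ ($d_s = 0$) and the reporter $-\infty$, which simply pins
  them to the ends.
* All tie-breaks (Sloan extraction, guided DFS, entrance selection,
  climbing sweeps, exhaustive ties) resolve by stable gene order, making
  every code path deterministic for fixed inputs and seeds.
* Duplicate edges in input files are collapsed with a warning; self-loops
  are rejected; constraint files may omit genes, which default to unknown
  with a warning.
* Edge shuffling has an attempt budget (200 tries per required swap) and
  reports the completed swap count if the degree sequence admits too few
  rewirings.

## Problem sizes used by the test suite

The suite exercises the full 40/280 grid for counting, optimizer
comparisons on 100 instances of 8–12 genes with up to 6 unknowns,
deletion-minimality enumeration on 50 instances of at most 14 edges, and a
reduced trend sweep (sizes 30 and 50, four noise levels, five replicates,
prioritized under both rankings). These sizes keep brute-force oracles
enumerable while spanning the regimes where the algorithms differ; the
reduced sweep reproduces the qualitative study findings (distance grows
with noise; TopSoG dominates Sloan) rather than any figure's exact curve.

## Known limitations

* Deletion/insertion minimality is per-segment greedy, not global; the
  edit distance is an upper bound on the true minimum (tight on ≥90% of
  enumerable instances).
* Hill climbing cannot escape strict local optima; with many unknowns on
  tiny networks the exhaustive baseline wins a visible fraction of
  instances (see above). The strictly-improving acceptance rule is the
  method's defining behaviour and is kept deliberately.
* One receptor-reporter pair per network; no edge weights or signs.
* The Sloan weight constants and tie rules are not uniquely determined by
  the profile-reduction literature's many variants; the classic
  $W_1 = 1, W_2 = 2$ completion is used and documented rather than tuned.
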