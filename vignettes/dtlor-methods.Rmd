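---
title: "Reconciliation in the DTLOR model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciliation in the DTLOR model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtlor)
```

## The model

Classical duplication–transfer–loss (DTL) reconciliation embeds a rooted
gene tree $G$ into a rooted species tree $S$ and reads off the events that
explain their discordance. For clades of closely related microbes two
phenomena fall outside that model: a gene family may *enter* the sampled
species tree by horizontal transfer from an unsampled lineage, and genes
move between *syntenic regions* of the genome (integer labels summarizing a
gene's neighborhood; shared labels mean shared core-gene context). The
DTLOR model adds an **origin** event (entry from outside) and a
**rearrangement** event (change of syntenic region along a gene-tree edge)
to duplication, transfer and loss.

A reconciliation is a pair of mappings. $\Phi$ sends every gene vertex to a
species vertex or to the outside location $N$; $\Gamma$ sends every gene
vertex to an actual syntenic region or to the unknown region $*$. Leaves
follow the observed tip associations; $\Phi(g)=N \iff \Gamma(g)=*$; once a
lineage is inside the species tree it stays inside, and once its region is
actual it stays actual. An internal vertex mapped inside induces exactly
one of speciation (zero cost), duplication, or transfer; lineages passing
through species vertices induce losses. An origin is induced wherever an
actual region first appears below an unknown one; a rearrangement wherever
two adjacent actual regions differ. Costs $D, T, L, O, R \ge 0$ weight the
events; the package's defaults are $(1,1,1,2,2)$. We accept zero costs as a
documented degenerate case — useful for reduction tests, though they can
make the number of co-optimal reconciliations explode.

Both trees are undated. As in plain DTL parsimony, an optimal reconciliation
is not guaranteed to be time-consistent; detecting or enforcing
time-consistency is a separate problem this package does not address.

## Decoupled dynamic programs (binary gene trees)

Inside an *origin subtree* (a maximal gene subtree whose root induces an
origin) the species mapping and the synteny labeling are independent, so
each is solved by its own program and the results are combined.

**Species map.** Every vertex is identified with its incoming edge; an
artificial *handle* edge sits above each root. Tables are indexed by
(gene edge, species edge) pairs, filled with gene edges in postorder
outside and species edges in postorder inside. A cell is resolved through
four cases (leaf/leaf base case; speciation/loss/duplication/transfer; the
leaf-edge specializations), with a Best-Entry table (cheapest placement
inside a species subtree) and a Best-Transfer table (cheapest placement on
an incomparable edge, computed in a preorder sweep) supporting the transfer
case. The species handle is a legal placement — a gene may map to the
species root — but never a transfer target, which falls out of initializing
Best-Transfer to $\infty$ at the handle.

Two implementation choices deserve a note:

* Alongside the *placed* table `C` we keep a *terminates* table `term`
  restricted to mappings with $\Phi(g)=s$. The two satisfy
  `C = min(term, L + min over child edges of C)` and share all row minima,
  so every published recurrence value is unchanged. The distinction matters
  for exact solution *counting* and for traceback at entry points: origin
  entries and transfer landings induce no losses (there is no species path
  from an outside parent), so with $L=0$ a count over placed cells would
  double-count mappings through zero-cost loss chains.
* In the counting tables, the duplication route with both children
  continuing into *opposite* child subtrees describes a mapping whose
  induced event is a speciation, already counted by the speciation route
  (the two routes tie exactly when $D=L=0$); those cross-continuation pairs
  are subtracted from the duplication count.

**Synteny map.** `syn(g, l)` is the optimal rearrangement cost of labeling
the subtree below `g` with actual regions, `g` labeled `l`: each child
independently keeps the parent's label or pays `R` to switch to its own
best label. Only actual labels enter this table; the unknown region is
handled by the combine step, since the decoupling argument holds only
inside origin subtrees.

**Combine.** `Origin(g) = O + C(g) + syn(g)` prices an origin subtree at
`g`; `Null(g)` (infinite at leaves, else the sum over children of the
cheaper of staying unknown or starting an origin) prices keeping `g`
outside; the optimum is the better of the two at the root. A single-leaf
gene tree is the documented degenerate case: the leaf cannot be unknown, so
the optimum is exactly one origin.

**Traceback** is deterministic: unknown-region before origin at ties;
within a cell speciation < loss < duplication < transfer; ties among
species edges resolved to the first edge in postorder, ties among regions
to the smallest label; a vertex reached through losses maps to the lowest
species edge of its chain. The traced reconciliation is re-validated and
re-scored through the independent event-inference path, and an internal
assertion fails if it does not reproduce the optimum.

**Counting** follows the annotated tables with sums over achieving
alternatives and products over children, and counts distinct $(\Phi,\Gamma)$
pairs exactly: loss placements are determined by $\Phi$ (tree paths are
unique), the speciation/duplication/transfer patterns are mutually
exclusive given $\Phi$, and a child re-labeled to its parent's own region
is never treated as a distinct labeling. Counts are stored in doubles,
exact up to $2^{53}$ — ample for the instance sizes verified here, but a
limitation for very large instances with near-zero costs.

## The joint program for multifurcating gene trees

Gene trees often contain soft polytomies. The problem then asks for the
optimum over all binary resolutions of every multifurcation, and the
species/synteny decoupling breaks: one resolution can favor the species
map while another favors the synteny map. The solver therefore works on
joint tables `C(e_g, e_s, l)` — cost of reconciling the subtree with the
gene edge placed on the species edge and the gene vertex in region `l`,
rearrangements included — with each child term taking
`min(keep l, R + free minimum)`, and ℓ-indexed Best-Entry/Best-Transfer
tables computed per label column exactly as in the binary case.

Each multifurcation with $k$ children is expanded into all $(2k-3)!!$
binary resolutions (recursive leaf insertion on every edge including the
handle, which enumerates each topology exactly once). Resolution leaves
inherit the child tables, internal resolution vertices are filled with the
joint recurrence, and the per-cell minimum over resolutions is kept —
resolved subtrees are reused through the tables, so the cost is additive,
not multiplicative, in the per-vertex resolution counts. The default arity
cap is 8; beyond it exhaustive resolution is impractical and the cap is a
hard error.

One design point was genuinely open: the unknown-region recursion for a
multifurcation. Because an origin can be induced at a vertex *internal to a
resolution* — grouping a strict subset of the children into one origin
subtree, which beats one origin per child whenever `O` exceeds the extra
joint mapping cost — `Null(g)` must be minimized over resolutions, applying
the binary recursion to every resolution vertex (`Origin = O + min` over
the vertex's joint table, `Null = sum of per-child minima`). A per-child
shortcut that ignores resolution-internal origins looks plausible but is
refuted by the exhaustive-resolution reference on random instances; the
package implements the full minimization.

Traceback records the winning resolution per table cell and re-evaluates
its scratch tables on demand (memory over speed; a trace touches few
cells). Multifurcations that end up entirely outside the species tree are
resolved by a canonical left comb — any resolution is cost-neutral there.
MPR counting is not offered for multifurcating input: when two
reconciliations live on different resolutions sharing a topology,
distinctness is ambiguous, so counting stays restricted to binary trees.

## Verification strategy

The reference implementations are deliberately naive: every assignment of
internal gene vertices to species vertices or $N$ is enumerated and
filtered by the constraint checks; event costing re-derives classification,
path losses and origin counts from first principles; for a fixed species
map the rearrangement part is enumerated over all labelings (once per
outside-pattern, which leaves results unchanged). The polytomy reference
reconciles every complete binary resolution with the binary pipeline. The
test suite checks exact equality of optima and counts on hundreds of
seeded random instances drawn from small trees (≤ 5–6 leaves, ≤ 3 regions)
with integer costs 0–3 — a regime that exercises every event type, heavy
ties, and all zero-cost degeneracies — plus closed-form reductions:
`R = 0` zeroes the synteny table; a single region with `O` above
`(D+T+L)(|V(G)|+|V(S)|)` forces exactly one origin plus the plain DTL
optimum; binary input through the polytomy solver must reproduce the
decoupled solver.

## The synthetic generator and simulator

`random_instance()` draws uniformly random rooted binary topologies
(sequential leaf insertion on a uniform edge), a uniform leaf map, a random
surjective region labeling, and optional polytomies by random edge
contraction under an arity cap. `simulate_history()` forward-simulates one
gene lineage entering the species tree (at the root handle by default) and
evolving tipward with per-arrival Bernoulli probabilities of loss,
duplication and transfer (target drawn uniformly among incomparable edges)
and a per-gene-edge rearrangement probability (defaults 0.05 each; the
test suite uses 0.08–0.1 to exercise event-rich histories while keeping
most lineages alive). It is a testing aid, not a calibrated evolutionary
model: events are per-branch coin flips, not continuous-time rates; there
is a single origin per history; and duplications are tandem (a duplication
alone never changes the region). Unary vertices left by one-sided losses
are contracted away; the returned true mapping is the history restricted
to the observed tree, and the true cost is that reconciliation's cost plus
the cost of all events on pruned lineages — by construction an upper bound
on the parsimony optimum, which is the property the suite asserts on every
draw. Consequently, passing these tests shows the solvers are exact for
the model, not that the model's defaults describe any particular real
dataset; real gene families bring rooting error, arity far above 4, and
non-tandem duplications, all outside the generator's scope.

Problem sizes used in the shipped checks: 500 random binary and 200 random
multifurcating instances for oracle equivalence, 100 simulated histories
for the parsimony bound, and solver timings on 50–200-leaf instances for
the scaling trend (the binary fill is `O(|G||S| + |G||L|)`; the timing
check asserts the trend, not absolute times).

## Known limitations

* No time-consistency detection or enforcement; no rooting search (the
  caller roots the gene tree); branch lengths are ignored.
* MPR counting is binary-only and double-precision.
* The polytomy solver is exact and exhaustive per vertex; arities beyond
  the cap need a heuristic search that is out of scope here.
* The simulator's contraction step can, very rarely, produce a history
  whose restriction to the observed tree violates the mapping constraints
  (nested transfers with extinct stay-lineages); such draws are redrawn and
  reported via a message.
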