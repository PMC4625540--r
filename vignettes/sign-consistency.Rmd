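---
title: "Sign consistency: model, notions, repair and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sign consistency: model, notions, repair and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signcon)
```

## The model and its assumptions

`signcon` reasons about steady-state shift experiments on signed directed
networks. The assumptions are deliberately weak: we do not know kinetic
parameters, interaction strengths or activation thresholds — only the sign
with which one species tends to influence another, and, for a subset of
species, whether they went up, down or stayed put between two steady
states. An admissible behavior of the system is a *total labeling*
$\mu^t : V \to \{+, 0, -\}$ of the interaction graph $(V, E, \sigma)$; the
*influence* of $j$ on $i$ along an edge is the product
$\mu^t(j)\,\sigma(j,i)$ with the usual sign arithmetic.

Four constraints relate a labeling to an experimental profile
$(S, I, \mu)$:

* **C1 (observations).** On measured nodes the labeling lies in the set
  the observation admits: certain labels pin one value, the uncertain
  labels $\vartriangle$ (`u+`) and $\triangledown$ (`u-`) admit
  $\{+, 0\}$ and $\{-, 0\}$.
* **C2 (changes justified).** A non-input node may change only if some
  predecessor's influence equals the change. No-changes are free under
  this constraint: because influence strengths are unknown, an influence
  need not take effect.
* **C3 (no-changes justified).** Under the *strong propagation* reading,
  every influence does take effect, so a non-input node may show no change
  only if it receives no nonzero influence or two opposing nonzero ones.
  We read the "two edges" in the cancellation condition as two *distinct
  edges* with opposing nonzero influences; they may share a source, so an
  unsigned interaction — encoded as two parallel edges of opposite sign —
  can cancel itself.
* **C4 (foundedness).** A change must be reachable from an input along a
  chain of sign-matching nonzero influences. This is a global constraint:
  it excludes behaviors in which a positive feedback loop sustains itself
  with no cause upstream, without requiring manual removal of such loops.

Input nodes are exempt from C2 and C3 (both are stated for non-input
nodes) and satisfy C4 trivially; a *measured* input is still subject to
C1. Inputs need not be measured: genome-scale stress experiments rarely
identify the perturbed species, and the common practice is to declare all
predecessor-free nodes inputs (`auto_inputs()`, the default in
`confront()`). We therefore do not enforce $I \subseteq S$; an unmeasured
input has a free label. A consequence of C2 worth knowing: an unmeasured,
predecessor-free *non-input* can never justify a change and is forced
to 0.

The four consistency notions are the four constraint sets
WP = {C1, C2}, SP = {C1, C2, C3}, FWP = {C1, C2, C4} and
FSP = {C1, C2, C3, C4}. Because the sets nest, so do the labeling sets
they admit, and predictions can only stay equal or sharpen as constraints
are added:

```{r notions}
fx <- toy_fixtures()
sapply(c("WP", "FWP", "SP", "FSP"), function(n) {
  length(enumerate_labelings(fx$feedback$graph, fx$feedback$profile, n))
})
```

## Discretization

Raw measurements (log-ratios) are mapped to the five-valued alphabet by
four thresholds $t_1 \le t_2 < 0 < t_3 \le t_4$; the bands
$(t_1, t_2]$ and $[t_3, t_4)$ are the uncertain ones. The defaults
(−2, −0.01, 0.01, 2) are the typical choice for microarray log-ratios:
two-fold changes are certain, anything within 1% is certain no-change.
The thresholds are condition-dependent and overridable per run; degenerate
settings $t_1 = t_2$ or $t_3 = t_4$ are legal and simply empty an
uncertain band. Boundary conventions matter for reproducibility and are
fixed as: $x \le t_1 \mapsto -$, $x \le t_2 \mapsto$ `u-`,
$x < t_3 \mapsto 0$, $x < t_4 \mapsto$ `u+`, else $+$. A single global
threshold pair for all genes is a known simplification; per-gene or
variance-based discretization is out of scope.

## Prediction

A statement is a prediction when it holds in *every* consistent labeling
(cautious reasoning). Strong predictions pin a node to one label; weak
predictions exclude exactly one (`w+` never decreases, `w-` never
increases, `chg` always changes). The implementation never enumerates the
labeling set: one witness labeling provides one realized value per node,
and each remaining candidate value is tested with a pinned satisfiability
query — at most three queries per node, with the root propagation pruning
most candidates beforehand. Tests assert equality with the
enumeration-based definition on hundreds of seeded random instances.

## Repair

When no labeling satisfies all constraints, consistency is restored by
adding artificial influences: a correction $(i, s)$ adds a fresh input
node observed `+` and an edge of sign $s$ into $i$. Design choices, made
once and tested:

* *Minimal means minimum-cardinality.* The inconsistency index divides a
  single number by the observation count, and the worked examples call the
  two singletons minimal and the doubleton not minimal; subset-minimal
  enumeration is not offered.
* *The artificial influence is always active* (its node is pinned `+`; the
  edge sign carries the direction). A repair is responsible for the change
  it licenses — and can therefore itself violate C3 at a 0-labeled target,
  which the search accounts for by simply re-checking full consistency of
  the repaired instance.
* *Repairs target non-input nodes only*: an input's label is already
  unconstrained by C2–C4, so influencing it cannot license anything new.
* *Search* is iterative deepening over the cardinality $k$: all
  $k$-subsets of (non-input nodes) × {+, −} are tested for consistency
  after repair, so the result provably contains *all* minimum correction
  sets. The candidate space is not pruned heuristically; a configurable
  cap (default 32) guards against runaway instances.

Prediction under minimal repair classifies, per node, the union of
realized labels across all minimum correction sets — no minimal repair is
favored. Artificial nodes are excluded from the map.

SCEN-FIT keeps the topology fixed and asks how few observations a
labeling satisfying the propagation constraints must contradict; each
measured node outside its admitted set costs one unit (uncertain
observations admit two labels at cost zero, and no weighting is applied).
Under the founded notions we require corrected labelings to satisfy the
*full* constraint set including C4 — the selected notion is applied
uniformly rather than relaxing foundedness for corrections.

### The two repair measures order either way

Adding influences is often cheaper than discarding observations, and on
all worked fixtures MCoS ≤ SCEN-FIT holds. It is not a theorem, though.
A certain observation is a hard constraint for MCoS but not for SCEN-FIT,
and under strong propagation this bites:

```{r order}
g <- interaction_graph(data.frame(
  source = c("B", "M"), target = c("M", "T"), sign = c(-1L, -1L)
))
p <- experimental_profile(c(B = "-", M = "0", T = "-"), inputs = "B")
c(mcos = mcos(g, p, "FSP")$size, scenfit = scenfit(g, p, "FSP")$corrections)
```

The pinned `0` at M needs an added opposing influence (C3), and T's
decrease still needs its own justification — two additions — while
scenario fitting discards M's observation at cost one. The package keeps
both measures faithful to their definitions and does not enforce an
ordering between them.

## Evaluation metrics

*Recovery* is the fraction of unmeasured nodes with any prediction.
*Information gain* uses the product reading of the count
$1^k 2^l 3^m$ of behaviors left open — i.e.
$(n\log 3 - l\log 2 - m\log 3)/(n\log 3)$ — which is linear in the class
counts and reproduces the reference gains (a 7.74% weak coverage yields a
2.86% gain). *Precision* is TP/(TP+FP), where a strong prediction needs
an equal certain measurement and a weak one any compatible certain
measurement; uncertain validation measurements are deliberately excluded
from TP/FP (both are defined only against certain values) but appear as
rows of the confusion matrix, so nothing is silently dropped.

Cross-validation gives the predictor a random share of the measurements
(inputs unchanged), predicts under minimal correction sets, and validates
against the held-out rest; per-sample rates are aggregated as unweighted
means over samples, confusion matrices are summed. The shuffle null
permutes the observed labels among the measured nodes — preserving the
label multiset — and compares inconsistency indices; with a single
profile the empirical quantile of the real index is reported, across a
collection of profiles a paired Wilcoxon signed-rank test
(`stats::wilcox.test`, one-sided) compares real indices with per-profile
null means. A constant observed-label profile makes every permutation
identical; the result is flagged degenerate rather than reported as a
p-value.

## The synthetic generator

`sample_instance()` emulates the statistical structure the method
assumes: a hidden consistent total labeling (the true response), partial
observation, optional uncertainty and optional corrupting sign flips. The
hidden labeling is drawn *through the consistency engine* with seeded
randomized value ordering, not by forward simulation — forward propagation
alone cannot guarantee justified no-changes under C3, while a randomized
consistency search is valid for every notion including FSP. One integer
seed derives all sub-seeds via a fixed Lehmer-step scheme, so instances
are fully reproducible.

Defaults, chosen once as a plausible small regulatory module: 12 nodes,
18 edges (sparse, mean degree 1.5), 30% inhibitory edges, inputs = the
predecessor-free nodes plus 5% extras, 50% of nodes observed, 10% of
observed changes softened to the matching uncertain label (no-change
observations are not softened — they have no single matching uncertain
label), no flips. What the generator does *not* emulate: scale-free or
otherwise biologically calibrated topology, correlated measurement noise,
batch effects, or condition-dependent thresholds. Passing the soundness
batteries therefore shows that the *logic* is correct — every strong
prediction equals the hidden label, every weak prediction is compatible
with it, cross-validated precision is exactly 1 without noise — not that
any particular precision will be attained on real data.

## Numerical and algorithmic choices

The solver compiles graph, profile and notion into per-node candidate
sets (C1), then interleaves two sound pruning passes — arc-consistency on
C2/C3 support and a possible-foundedness fixpoint for C4 — with
depth-first search over nodes in sorted order and value order
$+ < 0 < -$, so enumeration is deterministic and lexicographic. Every
leaf is re-checked against the plain constraint definitions; pruning can
only affect speed, never results. Enumeration is guarded by a limit
(default $10^6$) with a classed truncation error. The brute-force
$3^{|V|}$ oracle used in the test suite shares no code with this engine.

Problem sizes in the shipped tests and the acceptance script are chosen
for exhaustive verifiability: random oracle instances use up to 8 nodes
(6561 labelings enumerable directly), synthetic soundness instances 8–10
nodes across 100+ seeds, and the repair oracle caps exhaustive comparison
at 2 corrections. These sizes are where brute force is a feasible
referee; the engine itself handles larger instances, limited mainly by
the exponential worst case of enumeration and of the repair search.

## Known limitations

* Exhaustive repair search grows as $\binom{2|V|}{k}$ in the correction
  cardinality $k$; genome-scale instances with large correction sets call
  for a dedicated constraint solver, which this package intentionally
  does not depend on.
* Single global discretization thresholds for all species.
* Single-experiment reasoning: repairs are specific to one profile and
  may be incompatible across experiments; multi-experiment topology
  optimization is out of scope.
* The MCoS/SCEN-FIT ordering discussed above.
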