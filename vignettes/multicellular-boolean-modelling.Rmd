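---
title: "Methods: multi-cellular Boolean modelling, calibration and knockout screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cellular Boolean modelling, calibration and knockout screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcboolnet)
```

## The modelling formalism

`mcboolnet` works with Boolean logical models: each node carries a binary
state, and rule-bearing nodes update synchronously as
`x_i(t+1) = f_i(x(t))` where `f_i` is an AND/OR/NOT expression over
regulator nodes (or a constant). Nodes without a rule are **inputs** —
external stimuli whose values are user-defined clamps, not computed.
Constant-rule nodes are deliberately *not* inputs: a constant is a form of
regulation, whereas an input stays user-settable. The synchronous scheme
makes the dynamics deterministic: from any initial state the trajectory
eventually revisits a state, closing either a fixpoint (steady state) or a
cycle. The pipeline keeps only steady states, mirroring common practice
for large disease models where cyclic attractors are logged and discarded.

Models are read from and written to SBML Level 3 with the `qual` package.
The reader accepts MathML function terms (`and`/`or`/`not` over species,
plus `eq`/`geq`/`leq` comparisons against 0/1); a transition that carries
no function terms at all is interpreted from its input signs as
"OR of activators AND NOT OR of inhibitors", with a warning, to widen
coverage of sign-only exports. Multi-valued species (`maxLevel > 1`) are
rejected rather than silently binarised. Node identity is the qualitative
species id — unique by construction — while display names and identifier
annotations (e.g. gene symbols) are retained for symbol resolution.

## Steady-state enumeration

Rather than simulating from every initial state, all solutions of
`x = f(x)` under the active clamps are found by **branch-and-propagate**:
rules are evaluated in three-valued (Kleene) logic; any rule whose value
is determined forces its target, contradictions prune the branch, and an
undetermined node (rule-bearing nodes first — their assignment constrains
others) is branched on both values. A clamped node contributes only the
constraint `x = clamp`, because clamps override rules during updates. The
solver is pinned, across hundreds of random models, against an
independent brute-force scan of all `2^n` states in the test suite.

For the input space, `enumerate_steady_states()` iterates every
assignment of the free inputs in lexicographic order (free inputs sorted
by node id), which makes output order reproducible and lets large runs be
sharded by combination index (`range`). A guard refuses more than `2^24`
combinations outright; the intended workflow for large models is to fix
differentially expressed inputs first, which shrinks the space by orders
of magnitude, and to shard what remains.

## Calibration

Differential expression enters as a discretized **observed profile**:
overexpressed molecules map to 1, under-expressed to 0; conflicting
entries for one node are an error, unresolvable symbols are an error
unless a lenient flag downgrades them to warnings. Inputs present in the
profile are clamped to their observed value before enumeration; the
remaining inputs stay free by default (an optional policy clamps them to
1, echoing tools whose default input value is 1).

Enumerated steady states are filtered by phenotype constraints (e.g.
apoptosis OFF, proliferation ON, migration ON for hyperplastic synovial
fibroblasts), scored by the fraction of mapped profile nodes they match,
and the arg-max set — *all* tied top scorers — is averaged. Nodes with
mean exactly 0 or 1 are fixed; others free. Two choices here were
genuinely open and are fixed as follows:

* **Free nodes count as non-reproducing** in the reproduction percentage.
  This is the conservative reading and keeps the statistic honest when
  many top states disagree on a node.
* **Profile entries are weighted uniformly** regardless of provenance
  (literature vs dataset); evidence-weighted scoring would require a
  calibration of its own.

## Fusion of cell-specific models

Candidate ligand–receptor interactions carry evidence records; the filter
keeps an interaction identified by **at least two distinct dataset pairs
or two distinct approaches** (literature, database mining, or either of
two omics-inference routes, which must name their dataset pair). The
filter is monotone: adding evidence can only promote an interaction.

`merge_models()` namespaces every node as `celltype::node` (so node
counts always add), then adds each interaction's ligand node as an
activating regulator of its receptor node. The new term joins an existing
receptor rule by OR — activation semantics, the least destructive
extension, with AND available as an option; a receptor that was an input
gains a rule and stops being an input. Heterodimer/contact interactions
are wired identically: at the Boolean level both are an activating
dependency. Symbols resolve within their cell's namespace by exact id,
then annotation, then case-insensitive name; ambiguity is an error, never
a guess.

When the per-cell calibrated states are combined onto the fused model,
any receptor that gained a regulator is **reset to FREE** even if its
cell-specific calibration had fixed it: the new intercellular edge can
change its value, so it must be re-determined by the attractor search on
the fused model. (The alternative — keeping the fixed value — would bake
a pre-fusion artefact into the fused state.) `fix_inputs()` then accounts
for inputs fixed by the combination, inputs fixed from
literature/expression tables, and the free remainder that defines the
enumeration space.

## Knockout screening

A knockout clamps its target node(s) to 0 — pharmacological inhibition —
on top of the fixed inputs; for steady states this is equivalent to
deleting the node and propagating the constant. Target tables are
filtered to inhibitor-class modes of action, and one symbol may resolve
to several namespaced nodes (one per cell type); a knockout clamps all of
them. Simulation starts from the calibrated state with free nodes at 0 by
default (`free_init` exposes 1 as an alternative; the choice only matters
for the transient, and a screen can be run under both policies and
intersected). Each knockout is a single synchronous trajectory rather
than a re-enumeration over free inputs: the screen asks how the
calibrated disease state responds to the perturbation, and a single
deterministic run keeps an all-pairs screen tractable.

Defaults `max_steps = 100` and `window = 50` match the common interactive
simulation setting of a 100-step horizon with a 50-step sliding window.
A phenotype in a cyclic attractor counts as active when its activity
level over the cycle is at least 0.5, and the calibrated reference is
active at mean ≥ 0.5 — the display midpoint. Deltas are reported as
`down` (active reference switched off), `up` (inactive reference switched
on) or `unchanged`. A pair of knockouts is **synergistic** when it
changes at least one phenotype that neither single knockout changes; this
emergent-effect formalisation is the package's own, property-tested
against a brute-force restatement of the definition.

## The synthetic-data generator

`gen_model()` draws a random DAG (inputs first, phenotype nodes as
sinks, per-node indegree ≤ `max_indegree`, default 3), optionally adds
feedback regulators with probability `feedback_p = 0.1` so that cyclic
attractors exist and get filtered, draws each rule as a random truth
table, and **plants a fixpoint** by flipping each rule's output on the
planted row only — rule randomness is preserved everywhere else, and the
planting is simple enough for test oracles to re-derive. `gen_profile()`
observes a `coverage` fraction of non-input nodes and flips each entry
with probability `flip_rate`; with coverage 1 and flip rate 0 the
calibration provably recovers the planted state, and the recovery
degrades monotonically with noise (both are tested).
`gen_multicell_fixture()` assembles several planted cell models, a toy
interaction table mixing single-evidence (filtered out) and
multi-evidence (kept) records, per-cell profiles, and a target table
mixing mappable inhibitors, unmappable inhibitors and non-inhibitors.
All generation is reproducible from an integer seed and restores the
caller's RNG state.

What the generator does **not** emulate: realistic transcriptomic count
distributions, correlated noise across related genes, scale-free
regulatory topology, or curated rule structure (random truth tables are
denser in feedback-relevant behaviour than hand-curated activations).
Passing tests therefore demonstrate algorithmic correctness on models
with the right structural skeleton — inputs, sinks, planted attractors,
partial noisy observation — not biological fidelity of any particular
network.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale: solver-vs-oracle
batteries on a few hundred random models of 6–14 nodes, calibration
recovery over 20 seeds, and end-to-end fused screens on two 12-node cell
models — sizes chosen so the whole suite completes in well under a minute
while still exhausting the `2^n` oracle space. Published analyses of
curated synovium models run the same pipeline at `2^20`–`2^21` input
combinations on large machines; the `range` sharding argument exists for
that regime, and nothing in the algorithms depends on model size beyond
compute. Remaining numerical conventions: state and combination
orderings are lexicographic; ties in the similarity arg-max are all
retained (never sampled); means of 0/1 vectors are exact in floating
point, so the fixed/free distinction is sharp; and the knockout runner
asserts clamp dominance on every attractor it returns.

## Known limitations

* Synchronous updates only; asynchronous schemes can reveal attractors
  the synchronous scheme misses.
* Completeness is guaranteed for steady states, not for cycles: cycles
  are only observed via simulation from chosen initial states.
* Boolean (two-level) models only.
* The evidence filter treats approaches and dataset pairs as categorical
  labels; it does not model the underlying statistics of the inference
  tools that produced them.
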