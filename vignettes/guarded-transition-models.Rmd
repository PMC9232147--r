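---
title: "Guarded-transition models and phenotype controller search"
author: "gtreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guarded-transition models and phenotype controller search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtreach)
```

## The formalism

A guarded-transition model is a discrete dynamical system over Boolean
entity states. A transition is a quadruplet (input, output, event,
condition), written `A --h[Cond]--> B`: when the clock event `h` occurs,
`A` is consumed and `B` produced, provided `A` is active and the Boolean
formula `Cond` (over entity states, with `and`/`or`/`not`) holds.
Transitions sharing an event fire *simultaneously*: an event is enabled
only when **every** one of its transitions has an active input and a
satisfied guard. This is the mechanism that encodes multi-reactant
chemistry — a reaction `A + B -> C + D` becomes four transitions
`A->C, A->D, B->C, B->D` on one event, each guarded by the presence of the
co-substrate, so the reaction proceeds only with all substrates present.
Guard atoms are read, never consumed, which is how catalysts and
transcriptional regulators act.

*Boundary entities* are the entities that no transition outputs; nothing in
the model can produce them, so they are the only entities allowed to be
active in an initial state. For a phenotype given as a Boolean formula over
entities (a *query*), the *controllers* are the boundary entities activated
in at least one trajectory reaching the query, the *trajectory entities*
are the intermediates activated along such trajectories, and the union of
the two is the causal signature of the phenotype.

## From BioPAX to guarded transitions

BioPAX Level-3 classes map naturally onto this formalism: PhysicalEntity
subclasses (Protein, Complex, SmallMolecule, Dna, Rna) become entities;
Conversion subclasses (BiochemicalReaction, ComplexAssembly, Transport,
TransportWithBiochemicalReaction, Degradation) and TemplateReaction become
transitions; Control subclasses (Catalysis, TemplateReactionRegulation)
become guard conditions — a disjunction over activators conjoined with the
negation of each inhibitor. MolecularInteraction and GeneticInteraction
cannot be read as controlled biochemical reactions and are dropped, as are
Modulation controls.

Four curation rules run in a fixed order before compilation
(`curateBiopax()`): exact-tuple duplicate merging (type, name, location,
modification features, members, components — exact matching keeps the
grouping reproducible), reification of entities appearing as both reactant
and product of one interaction into Catalysis controls, removal of the
unsupported classes above (plus, under the `acsn` profile, a restriction to
Protein/Complex/SmallMolecule), and generic-class handling. A class with
`memberPhysicalEntity` records is collapsed to a single compound when no
member acts individually anywhere, expanded (the class deleted, every
referencing interaction replicated once per member) when members do act
individually, and removed outright when the class itself touches no
interaction or control. Member participation is judged by molecule
identity (type and name), so the same molecule in another compartment
counts as acting individually; when an interaction references two classes
with mirrored member sets — the two sides of a transport — the replication
pairs members by identity rather than taking a cross product. Nesting is
handled innermost-first to fixpoint; cyclic membership is a hard error.

Per-interaction compilation (`compileModel()`) allocates one fresh event
per interaction occurrence, yielding event counts close to reaction counts.
Conversions follow the m×n rule above. Template reactions create a
gene-kind input entity (`<template>_gene`), typically a boundary entity.
Transports pair compounds across compartments by unqualified molecule id
and move each on its own event; entity ids carry compartment qualifiers, so
the same molecule in two compartments is two entities (missing locations
qualify as `cellular_component_unknown`). Degradations feed a
`degradation_sink` pseudo-entity. A reactant-less conversion (possible
after reification, e.g. `X -> X`) compiles as a template-like production
from a created `<product>_source` input guarded by its catalysts — this
preserves producibility without silently rewiring the network, and such
interactions are flagged in the curation log. Guards are flattened
(`and`/`or` nesting, TRUE conjuncts dropped) but not otherwise minimised,
so every guard remains auditable against its source controls.

## Cycle resolution

A strongly connected component of two or more entities with no incoming
transition from outside can never be activated from the boundary. Each such
component receives one virtual entity (`cycle_initiation_node_<k>`) with an
unguarded transition into the lexicographically smallest member (plain
codepoint order; no locale assumptions). Self-loops are ignored when
qualifying components, since a self-loop alone is not a production path.
The operation is idempotent, and afterwards every entity is forward-
reachable from the boundary. In reports, a virtual node is presented as the
cycle entity it feeds: activating the cycle through `I` is biologically a
statement about `I`, not about the bookkeeping node.

## Dynamics: the firing policy

The update is partially parallel: at each step the fired events act
simultaneously — an entity becomes active if some fired transition outputs
it, inactive if consumed without replacement, unchanged otherwise. The
package's solver and oracle explore the *reactive* (maximal) policy: every
enabled event fires at every step. This is a deliberate design choice, and
the one point where a weaker alternative (firing arbitrary subsets of
enabled events) was rejected. The two policies disagree on a crucial toy
case: with arbitrary subsets, the query "C and N" on the shipped toy model
would be satisfiable by simply never firing the event that consumes `N` —
but the presence of `N` is supposed to *imply* the production of the
inhibitor `M`, making the query unsatisfiable. Obligatory firing is what
gives competition between reactions its teeth; under it all five documented
toy-model outcomes hold. The policy also makes the trajectory from a given
initial state deterministic, so all non-determinism lives in the choice of
initially active boundary entities — which is exactly the question the
solver answers. `step()` still accepts any subset of enabled events, so
witness schedules can be replayed and checked independently.

Negative literals in a query are enforced over the *whole* trajectory: "C
and not J" means `J` was never active, not merely inactive at the end. This
is required for inhibition to mean anything in a monotone reachability
setting (an entity transiently active and then consumed would otherwise
evade the constraint), and it guarantees that an inhibited entity can never
appear among controllers or trajectory entities. Positive parts of the
query are evaluated at the final step of the searched horizon.

## The bounded SAT search

`encodeUnfolding()` unrolls the model for a horizon k over variables
`place(p, t)` (t = 0..k) and `fire(h, t)` (t = 0..k−1), with Tseitin
auxiliaries for guards, the firing equivalence (`fire(h,t)` iff every
transition of `h` is enabled at `t`), the frame/update rule, a closed-world
initial state (non-boundary places false, boundary places free) and the
query. Satisfying assignments correspond one-to-one with legal reactive
trajectories reaching the query. `solveQuery()` iterates k = 1, 2, … up to
`maxHorizon` (default: the number of entities, which suffices for any
acyclic chain); at each horizon it enumerates satisfying assignments,
reduces each boundary activation set to minimality by iterated single-
element removal re-checks in sorted-id order, records a witness schedule,
and blocks the found set together with all its supersets. Enumeration
therefore terminates with exactly the subset-minimal boundary sets (a
final filter removes the rare non-minimal set found before its smaller
sibling at a later horizon). Solution identity is the boundary set; two
schedules over the same set count once.

The CNF instances are small (hundreds to a few thousand variables, with
only the boundary places free once propagation runs), so the package ships
its own compact DPLL solver (Rcpp) with unit propagation, deterministic
variable order and FALSE-first branching — which biases enumeration toward
small activation sets and makes every run reproducible without a seed; the
`seed` argument is retained for interface stability. `maxSolutions`
(default 400) caps the number of distinct boundary sets per query, a
compromise between completeness and runtime for large models; results
carry a `capped` flag, and when the cap binds the enumeration order is the
deterministic solver order.

`bruteForceOracle()` is the independent reference: it enumerates every
subset of the boundary, simulates the reactive trajectory step by step
with `step()` — no CNF anywhere — and returns the subset-minimal accepted
sets. It refuses models beyond desk scale (16 entities / 14 boundary
entities / horizon 8), which is the scale the test suite uses.

## What the synthetic generator emulates

`generateBiopax()` emits seeded BioPAX documents with a configurable mix of
biochemical reactions (reactant/product multiplicities drawn from ranges),
activating and inhibiting controls, injected duplicate groups, collapse-
and expansion-case generic classes, and an optional planted boundary-to-
target chain whose known solution anchors end-to-end query tests. Each
document comes with a closed-form ground-truth record (post-curation entity
count, duplicate groups, compiled transition count by the m×n law, event
count). The generator emulates the *structural* patterns of curated pathway
databases, not their statistics: it does not reproduce realistic degree
distributions, compartment topologies, shared-substrate competition at
database scale, or annotation noise. Passing tests therefore demonstrate
the correctness of parsing, curation algebra, compilation laws and query
semantics — not biological fidelity on any particular database.

## Numerical and design choices

- **Determinism everywhere.** Interactions compile in sorted-uri order,
  guard atoms sort lexicographically, solver branching is fixed; identical
  input and options give byte-identical native JSON.
- **Minimality** is subset-minimality certified by single-removal
  re-checks, not global cardinality minimisation — reproducible, and no
  optimisation claim is made.
- **Horizon default** equals the entity count; deep models with long
  production chains need nothing more, and cycles add nothing new after
  one traversal under the reactive policy.
- **Degenerate inputs**: empty models compile and query cleanly; a
  same-compartment transport degenerates to a flagged self-loop; a
  template reaction with neither template nor product is skipped with a
  warning; unknown query atoms and unknown BioPAX classes raise errors and
  warnings naming the offender.
- **Problem sizes in the tests**: the toy model (15 entities), 200 seeded
  conversions for the m×n law, 50 random models (≤ 12 entities, horizon 6)
  for solver/oracle equivalence, 20 for inhibitor exclusion. These sizes
  keep the whole suite in well under a minute while exercising every code
  path; the SAT route itself is the one intended to scale to
  database-sized models.

## Worked example

```{r example}
m <- buildToyModel()
modelStats(m)$entities
boundaryEntities(m)

res <- solveQuery(m, "C")
res
controllers(res)
occupancyMatrix(res)
```

## Limitations

- Controllers are reachability statements, not ranked predictions: the
  number of trajectories or controllers must not be used to order genes by
  importance.
- The reactive policy is a modelling commitment; systems where an enabled
  reaction can idle indefinitely while others run are outside this
  semantics.
- BioPAX reading is restricted to the constructs the compiler consumes; it
  is not a general RDF store, and BioPAX Level 2, SBGN conversion and
  model merging across databases are out of scope.
- Quantitative/stochastic simulation and attractor analysis are
  non-goals; the formalism is qualitative by design.
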