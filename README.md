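# gtreach

Guarded-transition models from BioPAX pathway knowledge, and SAT-based
search for the boundary entities that control a phenotype.

## The problem

Large pathway databases (Pathway Commons exports such as PID and KEGG, the
ACSN cancer maps) describe signalling, regulation and metabolism in the
BioPAX Level-3 ontology. A phenotype — say, activation of a marker gene —
is a state of this system, and the biologically interesting question is
*causal*: which combinations of peripheral molecules are sufficient to
drive the network into that state, through which intermediates, despite
competition for shared substrates and explicit inhibition? Interaction-
graph methods cannot answer this (they ignore dynamics), and quantitative
models do not scale to databases built without a priori selection.

`gtreach` is for systems biologists who want that causal analysis directly
on BioPAX files. It interprets a BioPAX document into a **guarded-
transition model** — an extension of Petri nets — and answers phenotype
queries by bounded reachability.

## The formalism in brief

A guarded transition `t : A --h[Cond]--> B` consumes input `A` and produces
output `B` when its clock event `h` occurs, provided the Boolean condition
`Cond` over entity states holds. Transitions sharing an event fire
simultaneously, so a reaction `A + B -> C + D` with catalyst `E` compiles
to four transitions on one event,

```
t1: A --h[B and E]--> C    t3: A --h[B and E]--> D
t2: B --h[A and E]--> C    t4: B --h[A and E]--> D
```

which proceeds only when both substrates and the catalyst are present.
**Boundary entities** are those no transition outputs; only they may be
active initially. Given a query formula (e.g. `"PERP and MMP2"`), the
solver enumerates the *minimal* boundary activation sets reaching the
query — the **controllers** — together with witness firing schedules and
the activated intermediates (**trajectory entities**); their union is the
causal signature of the phenotype. At each step every enabled event fires,
so competition is obligatory: producing an inhibitor really does rule out
the reactions it inhibits, and negated query atoms (`"C and not J"`) are
enforced over the whole trajectory. The search works on a CNF unfolding of
the model (variables `place(p,t)` and `fire(h,t)`) solved by a built-in
DPLL solver, with minimisation by removal re-checks and blocking clauses
for enumeration; an independent brute-force simulator cross-checks it at
desk scale.

## Worked example

The shipped toy model has 15 entities and 11 transitions, including a
two-substrate production of `C` guarded by `(P or L or K) and not M`, and
an unfed cycle `I -> J -> K -> I` that cycle resolution opens from a
virtual boundary node on `I`:

```r
library(gtreach)
m <- buildToyModel()
m
#> GTModel with 15 entities, 11 transitions, 8 events
#>   boundary entities: 6

res <- solveQuery(m, "C")
res
#> QueryResult for 'C': 2 solution(s)
#>   controllers (5): D, E, F, I, L
#>   trajectory entities (6)

occupancyMatrix(res)
#>              D E F I L
#> trajectory_1 1 1 1 0 1
#> trajectory_2 1 1 1 1 0
```

Two minimal trajectories produce `C`: one activates the guard through the
boundary entity `L`, the other through the cycle entered at `I`; `D`, `E`,
`F` supply the substrates in both, giving five controllers. Forbidding the
cycle intermediate removes the second route:

```r
solveQuery(m, "C and not J")
#> QueryResult for 'C and not J': 1 solution(s)
#>   controllers (4): D, E, F, L
#>   trajectory entities (3)
```

For BioPAX input the pipeline is:

```r
g   <- loadBiopax("pathways.owl")            # RDF/XML, .gz accepted
cur <- curateBiopax(g, profile = "default")  # merge, reify, drop, expand
mod <- compileModel(cur$graph)               # guarded transitions + cycles
res <- solveQuery(mod, "MMP2")
exportTrajectoryGraph(res, mod, "dot", "mmp2.dot")
occupancyMatrix(res, "mmp2.csv")
```

A thin command-line wrapper with `compile` / `stats` / `query` / `export` /
`compare` / `synth` subcommands is installed at
`system.file("scripts", "gtreach.R", package = "gtreach")`.

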