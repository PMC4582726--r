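# embryofab

Ontology-driven 3D modeling of human embryo development.

Human embryology is hard to visualize: organs appear, grow, migrate,
rotate, fuse and divide over the Carnegie stages, and the knowledge
describing this is usually locked either in descriptive anatomy
ontologies (which say nothing about 3D shape) or in hand-built 3D
atlases (which say nothing machine-readable about anatomy). `embryofab`
is for developmental anatomists, ontology engineers and graphics people
who want the two sides joined: a declarative RDF-style knowledge graph
that *drives* a procedural 3D animation of organ development.

The package provides, end to end:

- **An ontology core** — six taxonomies (embryological entity, temporal
  entity, geometrical entity, process, spatio-temporal representation,
  disease) over a flat triple graph with named provenance, Turtle /
  N-Triples / RDF/XML I/O, and a structural validator. Anatomical
  relations (`part_of`, `subClassOf`, `directly_develops_from`, ...)
  hold between classes; instances attach via `rdf:type`. Time is
  modeled as the 23 Carnegie stages te1–te23 plus gestation weeks
  gw9–gw12, each with `from_gestation_day`/`to_gestation_day` bounds
  and a `following_stage` chain.
- **A safe-rule inference engine** — fifteen Datalog-style rules
  (lineage closure `directly_develops_from ⊑ develops_from` and its
  transitivity, propagation through `part_of`/`subClassOf`, RDFS
  subproperty entailment, stage-order closure, process dependency
  closure, disease impact propagation, process/entity/stage linking),
  saturated to the least fixpoint by semi-naive evaluation with
  per-triple rule provenance. Safety (every conclusion variable bound
  in the conditions) guarantees termination.
- **A query layer** — a SPARQL SELECT subset (basic graph patterns,
  variables allowed in predicate position, FILTER comparisons) plus the
  canned scene-extraction queries.
- **A geometry engine** — parametric meshes for the six primitive kinds
  (point, line, plane, ovoid, cylinder, duct): UV-sphere ellipsoids,
  capped cylinders, Bezier-skeleton duct sweeps with rotation-minimizing
  frames, and compact-support meta-ball fields
  `f(d) = w (1 − d²/R²)³` for fusion/division, meshed by marching
  tetrahedra over a Freudenthal-decomposed grid.
- **An animation engine** — the gestation day as common time unit, with
  per-process tracks: growth linear in scale factor, rotation linear in
  angle about the declared local axes, migration to the end-stage pose
  (or along `migration_direction`), fixation pinning a duct end to its
  junction point, and division as a one-blob-to-two-blobs implicit
  morph. Selecting a disease inactivates every process it
  `impacts_processus` in the saturated graph — so "hypoplastic kidney"
  switches off kidney growth *and* the ureter–kidney interaction it
  depends on.
- **A reference embryo fixture** — `buildReferenceEmbryo()` regenerates
  the embryo-00 urogenital worked example (kidneys, ureters, gonads,
  cloaca, bladder, rectum, the growth/rotation/migration/interaction/
  fixation/division processes and the hypoplastic-kidney disease)
  programmatically, so everything above runs without downloads.

## Worked example

```r
library(embryofab)

g  <- buildReferenceEmbryo(withGeometry = TRUE)
validateSchema(g)
#> ValidationReport: valid, 0 violations
gs <- saturate(g)
gs
#> OntologyGraph with 824 triples (383 asserted, 441 inferred)

hasTriple(gs, "mcfe:kidney", "mcfe:develops_from", "mcfe:metanephros")
#> [1] TRUE   # inferred: direct lineage + transitivity

representationsDevelopingFrom(gs, "mcfe:cloaca", "mcfe:te14", saturated = TRUE)
#>             ee                       g     stage
#> 1 mcfe:bladder mcfe:bladder_ovoid_te15 mcfe:te15
#> 2  mcfe:rectum  mcfe:rectum_ovoid_te15 mcfe:te15

scene <- buildAnimatedScene(gs, "mcfe:left_kidney",
                            c("mcfe:te14", "mcfe:te20"), saturated = TRUE)
kf <- keyframes(scene, "mcfe:e00_left_kidney")
length(kf)                                     # one per day, 32..49
#> [1] 18
kf[[18]]$axisSize / kf[[1]]$axisSize           # declared growth proportion
#> [1] 10 10 10
recoverRotationAngles(kf[[1]]$orientation, kf[[18]]$orientation, c("x", "y"))
#>  x  y
#> 90 90                                         # net rotation about two axes
exportScene(scene, "obj", "scene/")            # frame_0001.obj ... frame_0018+1
```

The 18 keyframes are the gestation days covered by stages te14–te20
(the day is the common animation unit; te14 contributes 2 units, te17
contributes 3). The axis ratio of 10 and the 90° per-axis rotation are
the process parameters declared in the graph, recovered from the
animation rather than read back from the input. Re-running with
`diseases = "mcfe:hypoplastic_kidney"` gives a final/initial axis ratio
of 1: the disease inactivates the growth process chain.

A command-line wrapper ships in `inst/scripts/embryofab.R`
(`fixtures`, `validate`, `saturate`, `query`, `animate` subcommands).

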