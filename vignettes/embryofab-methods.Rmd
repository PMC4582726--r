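---
title: "Methods: knowledge-graph-driven animation of embryo development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-graph-driven animation of embryo development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryofab)
```

## The model

`embryofab` couples two descriptions of the developing human embryo
that are usually kept apart: a symbolic one (which organs exist, what
they develop from, when they exist, what processes they undergo, what
diseases perturb those processes) and a geometric one (which simple 3D
shape stands for each organ at each moment). Both live in one flat RDF
triple graph organised into six taxonomies — embryological entity,
temporal entity, geometrical entity, process, spatio-temporal
representation and disease — with the *spatio-temporal representation*
as the hub: each representation `describes` an organ instance and
either carries a geometry `at_stage` one stage, or carries a process
`from_stage`/`to_stage` a stage interval. Relations such as `part_of`
and `directly_develops_from` hold directly between class resources (not
OWL instance axioms); instances attach via `rdf:type`. This keeps every
fact a plain triple and makes schema and data uniformly queryable.

Time is discretised as the 23 Carnegie stages followed by gestation
weeks 9–12. Stages have unequal durations, so each carries
`from_gestation_day`/`to_gestation_day` bounds and the gestation *day*
is the common animation unit. Day intervals are half-open
`[from, to)`: te14 = [32, 34) lasts exactly 2 units and te17 = [39, 42)
lasts 3, which makes "lasts n days" arithmetic exact and gives splits
of a period that sum exactly. The anchors te11 (1 day), te14 and te17
are fixed by the model description; the remaining bounds are standard
staging-table defaults embedded as data (`referenceStageTable()`) and
can be overridden by asserting different day triples in a graph.

## Inference

Implicit knowledge is made explicit by forward chaining fifteen *safe*
rules (every conclusion variable occurs in the conditions, so
saturation over the finite constant domain terminates). The rules close
lineage (`directly_develops_from` entails `develops_from`, which is
transitive, and propagates through `part_of` and `subClassOf` of the
precursor), provide the generic RDFS/mereology core (`subClassOf` and
`part_of` transitivity, `subPropertyOf` entailment), tie geometric
models to the organ instances and stages they represent, close the
stage order and the `depends_on` relation between processes, propagate
disease impacts down process dependencies, and link each process to the
entities it impacts and its stage interval. Three of the fifteen rule
statements are not fixed by the published rule list we work from (only
their ids and the remark that generic transitivity/subproperty rules
are included); we implement those ids as the RDFS/mereology core above
and ship the whole set in a declarative rules file
(`inst/extdata/rules_default.rules`) so any statement can be replaced
without touching code.

Saturation is semi-naive (each round joins the previous round's delta
against the full graph), with the naive full re-evaluation kept as an
independent oracle; both produce the same least fixpoint, and the
result is independent of rule order (Datalog confluence). Every
inferred triple records the id of the rule that first produced it;
a derivable triple that was already asserted keeps its asserted
provenance. Materialisation happens at load/saturate time by default;
queries can equally be run against an unsaturated graph.

## Querying

The query layer implements a SPARQL SELECT subset: basic graph
patterns with `.`/`;`/`,` punctuation, variables allowed in any
position including the predicate (so schema and data are queried
together), and simple `FILTER(?v op constant)` comparisons. Property
paths are deliberately excluded: closure comes from saturation, not
path expressions, which keeps query evaluation a plain series of
joins. Scene extraction is a canned query: for each requested organ
instance it collects every static representation whose stage lies in
the period and every process representation whose interval intersects
it (equality counts as intersection, using the stages' day bounds).

## Geometry

Six primitive kinds cover the coarse shapes of organs. Ovoids and
cylinders are parametric meshes (UV-sphere with
`resolution (resolution−1) + 2` vertices; capped right cylinder),
scaled by per-axis half-sizes, rotated by an orthonormal right-handed
frame (validated to 1e-6) and translated to the barycenter. Ducts sweep
a circular cross-section along a cubic Bezier skeleton whose endpoints
and tangents come from the rostral/caudal end records (Hermite control
points `p0, p0+m0/3, p1−m1/3, p1`); the ring frame is
parallel-transported (rotation-minimising) along the samples because
the source model is silent on twist handling, and the end radii
interpolate linearly. Points, lines and planes are immaterial entities
rendered as visualization stand-ins: a small sphere marker, an
epsilon-radius tube, a thin slab.

Fusion and division need shapes that blend and split seamlessly, so
they use implicit surfaces: each skeleton (point or polyline)
contributes a compact-support meta-ball field
`w (1 − d²/R²)³` for `d < R` and exactly 0 beyond, and the shape is the
isosurface `field = isovalue` of the sum. The polynomial kernel and the
default isovalue 0.3 are our choices — the source family is named but
the exact polynomial, isovalue and weights are unpublished. The
isosurface is triangulated by marching tetrahedra over the Freudenthal
6-tetrahedra decomposition of a regular grid (default 64³ over the
padded support box; tests and exports use 24–48 to keep runtimes small).
The Freudenthal split is consistent across neighbouring cells and
surface vertices are deduplicated per grid edge, so extracted surfaces
are watertight whenever they do not cross the grid boundary. For a
division, two point skeletons start coincident and move apart along an
axis; the surface splits where the midpoint field drops below the
isovalue, at the analytic separation
`s* = (R/maxOffset) √(1 − (iso/2w)^{1/3})`, which the tests verify to
within one grid cell. The blob support radius is chosen per source
shape so the undivided blob circumscribes the source primitive, and
`maxOffset = 1.5 R` so the split occurs strictly inside the parameter
range. A `has_mesh_file` literal on a geometric entity short-circuits
all of this and loads an OBJ asset verbatim.

## Animation

`buildAnimatedScene()` seeds each organ from its earliest static
representation in the period, then applies each *active* process per
gestation day `d` with interval progress
`u = clamp((d − d0)/(d1 − d0), 0, 1)`:

- **growth** multiplies the axis sizes by `1 + (proportion − 1) u`
  (linear in the factor; rostral/caudal variants scale duct end radii
  independently);
- **rotation** composes rotations of angle `degrees · u` about the
  declared local axes in declared order, applied in the organ's local
  frame;
- **migration** displaces the barycenter linearly toward the organ's
  static pose at the process's end stage when one exists, else by the
  declared `migration_direction` (interpreted as a *total*
  displacement, not a per-day velocity — the magnitude convention is
  not fixed by the source, and end-stage poses take priority when both
  are present);
- **fixation** runs last and pins the selected duct end exactly onto
  its target point's current position (the hard-link semantics: the
  contact is one point belonging to both organs);
- **interaction** is geometrically inert — it exists as a `depends_on`
  node that diseases can sever;
- **division** replaces the source mesh by the two-blob implicit morph,
  with separation `u` over the interval; the products' existence
  windows start on the first day after the source's `ends_at` stage.

Composition order per frame is growth → rotation → migration →
fixation: scale and rotate in the local frame before placing in the
world, constraints win last. All interpolation laws are linear because
the knowledge base specifies only endpoints, never easing. Organs are
keyframed on every day of their existence window intersected with the
period, the window being half-open `[starts_at.from_day,
ends_at.to_day)`. Selecting diseases inactivates exactly the processes
they `impacts_processus` in the saturated graph — the closure over
`depends_on` means the hypoplastic kidney silences the growth process,
the ureter–kidney interaction it depends on, and the fixation link
below that. An inactive process contributes the identity at every
frame. There is no randomness anywhere: identical graph and
configuration give byte-identical exports.

Export writes one OBJ file per day boundary (`totalUnits + 1` frames,
inclusive endpoints), each organ a named group. A single-file animated
export format was considered and dropped: a frame sequence is the
simplest lossless representation for downstream tools, and OBJ
round-trips through the package's own reader in the tests.

## The reference fixture and what the tests show

`buildReferenceEmbryo()` regenerates the embryo-00 urogenital example
deterministically in code: the documented anatomical facts (left kidney
under kidney, part of the embryo; kidney from metanephric blastema from
metanephros; metanephros part of nephros; bladder and rectum from the
cloaca; cloaca existing te11–te14), the stage timetable, all six
process kinds (the left-kidney growth of proportion 10 per axis over
te14–te20, the 90° rotation about two reference axes, kidney and gonad
migrations, the ureter–kidney interaction, the ureter fixation at the
uretero-vesicular junction, the cloaca division) and the
hypoplastic-kidney disease. No coordinates are published for the worked
example, so all numeric geometry (barycenters, axis sizes, duct
endpoints, the coarse ellipsoid standing in for the embryo boundary)
lives in one constants file with an explicit NON-CANONICAL banner;
these are invented placeholders with plausible embryo-local magnitudes,
fixed so tests are deterministic. Consequently the tests demonstrate
*mechanism* — closure correctness against independent oracles,
parameter recovery (growth fold, rotation angle, migration endpoint,
fixation distance zero), split thresholds, watertightness, determinism
— not anatomical accuracy; passing them says nothing about how well the
placeholder shapes resemble a real embryo.

Problem sizes used in the test-suite: random-graph oracle checks run
100 graphs of 4–14 nodes; isosurface grids are 24–48³; meshes use
resolutions 3–32; animation checks cover the 18-day te14–te20 window
and the te10–te16 division window. These sizes were chosen to exercise
every code path at sub-second cost per case.

## Numerical choices and degenerate inputs

Orientation frames must be orthonormal to 1e-6 and right-handed;
non-conforming frames are validator violations (code *f*) and
constructor errors. Vector-valued properties are single literals of
three space-separated decimals, keeping triples flat and blank-node
free (round trips and rule matching stay deterministic). Degenerate
Bezier parameters outside [0, 1] error; zero-length tangents error in
normalisation; a grid that misses the field support yields an empty
mesh with a warning rather than an error; marching-tetrahedra faces
that collapse when a corner value equals the isovalue exactly are
dropped. Stage intervals must satisfy `from ≤ to`; reversed periods and
unknown stages are usage errors.

## Known limitations

The SPARQL dialect is a subset (no OPTIONAL/UNION/paths/aggregates);
inference covers the shipped safe rules only (no negation,
stratification or retraction); the geometric vocabulary is the six
coarse primitives, with no level-of-detail refinement, cage-based
deformation, collision handling or physically based simulation; organ
coordinates in the fixture are placeholders; and the export is an OBJ
frame sequence rather than a single animated container.
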