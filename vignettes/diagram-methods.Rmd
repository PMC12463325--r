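---
title: "Methods: automated diagram generation for SBML models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated diagram generation for SBML models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlviz)
```

This vignette documents the model behind `sbmlviz`'s automatic diagram
generation: what is computed, which parameters govern it, which numerical
conventions are fixed, and where the boundaries of the approach lie.

## The document model

Everything operates on a single in-memory value, the `sbml_document`. It
bundles a minimal SBML model (compartments, species, reactions with
reactant/product/modifier lists) with optional diagram data mirroring the
SBML Level 3 *Layout* and *Render* package extensions. Diagram data is
stored inside the SBML file itself, so a styled, laid-out model remains one
self-contained standards-compliant artifact: `write_document()` followed by
`read_document()` reproduces glyph geometry, curves, colors, gradients,
line endings and style selectors (this round-trip fidelity is asserted by
the test suite to within 10^-6 layout points; coordinates are serialized
with `%.10g` precision).

The reader parses only the constructs the writer emits — one layout per
document, linear gradients, the selector vocabulary of the Render package
(id lists, role lists, type lists). It is not a general SBML validator;
structurally invalid input is rejected with the first offending element
named, via the same `validate_layout()` post-condition used after every
mutating operation.

## The reaction hypergraph

A reaction with *n* participants is not an edge but a hyper-edge. We follow
the usual convention of reifying each reaction as a **centroid node**,
connected to each participant species node by a role-labeled edge
(substrate, product, side-substrate, side-product, modifier, activator,
inhibitor). Modifier roles are refined from SBO terms when present
(`SBO:0000020` → inhibitor, `SBO:0000459` → activator).

Two transformations are applied to the raw bipartite graph before layout:

* **Empty-set emancipation.** A reaction with no substrate (a source) or no
  product (a sink) gets a private empty-set node per missing side. These
  nodes are never shared between reactions — sharing one "∅" node would tie
  otherwise unrelated reactions together and produce hairballs around it.
  They serialize as general glyphs with a reserved `metaid` prefix so they
  survive the round trip.

* **Hub aliasing.** A species participating in more than
  `alias_threshold` (default 10) reactions is split into
  `ceiling(k / threshold)` alias glyphs. Edges are partitioned over the
  aliases in input order and as evenly as possible (partition sizes differ
  by at most one), so no alias exceeds the threshold and the multiset of
  participations is conserved. The operation is idempotent. This mirrors
  standard practice for currency metabolites (ATP, H₂O, …) whose single
  node would otherwise dominate the embedding.

## Force-directed placement

Node placement uses the Fruchterman–Reingold scheme with the classical
force laws: repulsion `k²/d` between every node pair, attraction `d²/k`
along every edge, with the ideal edge length
`k = k_scale · sqrt(canvas_area / n)`. Displacements per iteration are
capped by a temperature that cools linearly from `initial_temperature`
(default `canvas_width / 10`) to zero over `iterations` steps (default 50),
and positions are clamped to the canvas. Updates are synchronous: all
forces are evaluated against the same configuration before any node moves,
which makes the step order-independent and lets the test suite compare the
vectorized implementation against a brute-force double loop to 10^-9 pt.

Determinism is treated as a feature throughout: initial positions are drawn
from a seeded generator whose state is saved and restored around every use
(library calls never disturb the caller's RNG), and exactly coincident
nodes are separated along a direction derived from a hash of the seed and
node indices rather than from fresh randomness. Identical inputs therefore
yield byte-identical output files.

Two properties of this parameterization are worth stating explicitly:

* An isolated connected pair equilibrates where attraction balances
  repulsion, at distance `d = k`. The suite checks convergence to within
  5% after 500 iterations — a calibration check that the force laws and
  cooling schedule are implemented as stated, not a claim about layout
  quality.
* When the model has at least two compartments, a weak pull
  (`compartment_pull`, default 0.1) draws each node toward the mean
  position of its compartment's members, keeping compartments spatially
  coherent. With fewer than two compartments the term is inactive, so the
  single-compartment case is pure Fruchterman–Reingold.

## Curves and straightening

After placement, each reaction's arcs are generated as cubic Bézier
curves. Substrate arcs leave the centroid through tangent slots fanned up
to ±60° around the axis toward the substrates' mass center; product arcs
use the opposite half-plane; modifier arcs attach perpendicularly. On the
species side, attachment points are the exact intersection of the incoming
ray with the ellipse inscribed in the species bounding box, and attachments
on a crowded node are spread to at least 15° separation.

The common uni-uni case (one substrate, one product) is special-cased: the
centroid is moved to the exact midpoint between its two species and the
curve control points are placed at 1/3 and 2/3 of the chord, so the whole
reaction renders as one straight line — by construction exactly collinear,
not approximately so. Uni-uni attachments are pinned during congestion
spreading to preserve this.

## Arrangement operations

`align_reaction()` re-poses one reaction horizontally (substrate left,
product right) or vertically (substrate on top), preserving the chord
length. `arrange_reactions_circle()` places reaction centroids on a
circular arc with exactly equal angular steps; the angle convention is
0° = up, positive clockwise. On a full circle with *n* reactions the step
is 360°/*n*; on a partial arc the span is divided inclusively
(`span/(n−1)`). When consecutive reactions share a species (the main
product of one is the main substrate of the next), their glyphs are merged
so chains and cycles read as a single path. After any manual edit, only the
curves incident to the touched elements are regenerated; unrelated geometry
is untouched, and the canvas grows (or the layout is translated into view)
rather than ever producing out-of-canvas glyphs.

## Styling and data overlays

Styling follows the Render package's selector model: a style may select by
element id, by role, or by glyph type, with precedence id > role > type >
catch-all and later styles winning ties; attributes a higher-precedence
style leaves unset fall through. The 148 standard HTML color names are
supported (CSS definitions — `green` is `#008000`). Three built-in
templates (`default`, `sbgn-pd`, `escher`) each cover 100% of layout
elements; the SBGN Process Description template resolves one of 15 SBGN-PD
classes per element from explicit annotations, SBO terms, or glyph-type
fallbacks. Custom templates load from JSON.

Quantitative overlays write id-selector *override* styles on top of
whatever template is active, so the base styling is preserved and
recoverable. Values are min–max normalized (optionally symmetrically about
zero) and mapped to a gradient color, a stroke width range, or a node size
range. Gradient interpolation is linear per 8-bit RGB channel with
round-half-up; the midpoint of black→red is therefore exactly `#800000`
(127.5 → 128). A color bar can be added as ordinary layout/render elements
that round-trip with the document.

## Export

SVG is the primary backend: a direct, deterministic serialization of the
effective styles, with gradients and line endings as `<defs>`. PNG, JPEG
and PDF are drawn through R's graphics devices using the same resolved
primitives; raster pixel dimensions are `ceiling(layout_size × scale)` at
72 dpi per unit scale. Device output is not guaranteed byte-stable across
graphics library versions, so determinism guarantees are stated for the
SVG path.

## Synthetic models and benchmarking

`generate_model(n)` produces benchmark models with a fixed 4:1
species-to-reaction ratio (`floor(n/4)` reactions), each reaction drawing
1–2 reactants and 1–2 products uniformly without replacement from the
species pool — a rough match of the uni-uni/bi-bi mix of curated
biochemical models. The generator makes no attempt at realistic network
topology (no degree-law tail, no stoichiometric consistency, no kinetics);
it exists to exercise layout scaling, not to simulate biology.
`run_benchmark()` reports median wall-clock layout times over a size sweep;
timings are machine-dependent and reported, never asserted.

## Limitations

* One layout per document is read; additional layouts in a file are ignored.
* Force-directed placement optimizes a generic aesthetic, not pathway
  conventions; expect to use the arrangement operations for
  publication-style flow.
* `validate_layout()` checks structural invariants, not canvas enclosure:
  after user-driven moves, elements may legitimately sit anywhere, and the
  pipeline instead keeps dimensions consistent by construction.
* Radial/linear gradient rendering on the raster devices approximates the
  gradient by its midpoint color; full gradient fidelity is SVG-only.
* Text metrics are not computed; label boxes are fixed-size and long names
  may overflow their glyphs.
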