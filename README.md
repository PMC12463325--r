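# sbmlviz

Standards-based visualization of SBML biochemical models in R.

`sbmlviz` reads and writes SBML Level 3 documents carrying the **Layout**
and **Render** package extensions, generates diagram data automatically for
models that have none, and keeps every bit of visualization — node
positions, reaction curves, colors, styles, data overlays — *inside the
SBML file itself*. A styled pathway map is therefore a single portable,
standards-compliant artifact that any Layout/Render-aware tool can consume.

## What it does

* **Read/write** SBML L3 + Layout + Render, with exact round-tripping of
  geometry (to 10⁻⁶ pt) and style data, validated on every write.
* **Auto-layout** via a biochemistry-aware Fruchterman–Reingold embedding
  of the reaction hypergraph: per-reaction centroid nodes, role-labeled
  arcs (substrate/product/modifier/activator/inhibitor), private empty-set
  nodes for source and sink reactions, and alias splitting of hub species
  so currency metabolites don't collapse the map. Uni-uni reactions render
  as exactly straight lines; all other arcs are role-aware cubic Béziers.
* **Arrangement**: align a reaction horizontally/vertically, place
  reactions on circular arcs with exact equal spacing (merging shared
  species so cycles read as cycles), move single species with automatic
  curve re-attachment.
* **Styling**: the Render selector/cascade model (id > role > type >
  default), 148 HTML color names, and three complete templates —
  `default`, `sbgn-pd` (SBGN Process Description, 15 classes resolved from
  SBO terms), `escher` (pathway-map look) — plus custom JSON templates.
* **Data overlays**: map fluxes or concentrations to gradient colors,
  stroke widths or node sizes, as non-destructive override styles; add a
  color bar that round-trips with the file.
* **Export** to SVG (deterministic), PNG, JPEG and PDF.
* **Synthetic models + benchmark harness** for scaling studies, and a
  **CLI** (`sbml_cli()` / `inst/exec/sbmlviz`) chaining all stages.

Everything is deterministic under a seed: the same command produces
byte-identical SBML and SVG output.

## Worked example

```r
library(sbmlviz)

# a synthetic 20-species model (4:1 species:reaction ratio)
doc <- generate_model(20, seed = 1)
doc
#> SBML document 'synthetic_20_species': 20 species, 5 reactions, 1 compartments
#>   no layout
#>   no render information

# force-directed layout + SBGN Process Description styling
doc <- build_layout(doc, layout_params(iterations = 50, seed = 1))
doc <- apply_template(doc, "sbgn-pd")
doc
#> SBML document 'synthetic_20_species': 20 species, 5 reactions, 1 compartments
#>   layout 940x716 pt: 20 species glyphs, 5 reaction glyphs, 20 text glyphs
#>   render: 7 styles, 0 colors, 5 line endings

# overlay signed fluxes as colors (blue = negative, red = positive)
fluxes <- c(R1 = 1.8, R2 = -0.4, R3 = 0.9, R4 = 2.6, R5 = 0.1)
doc <- overlay_reaction_values(doc, fluxes,
         overlay_spec("reactions", "color", symmetric = TRUE))
doc <- add_colorbar(doc, default_gradient(), range(fluxes))
effective_style(doc, "rg_R4")$stroke    # strongest flux -> gradient end
#> [1] "#D73027"

validate_layout(doc)                    # structural invariants all hold
#> [1] severity   message    element_id
#> <0 rows> (or 0-length row.names)

write_document(doc, "model_with_diagram.xml")  # all of the above, in SBML
export_figure(doc, "figure.svg")               # and as a figure
```

The same pipeline from the shell:

```sh
sbmlviz synth --species 20 --seed 1 -o model.xml
sbmlviz layout model.xml --seed 1 -o laid.xml
sbmlviz style laid.xml --template sbgn-pd -o styled.xml
sbmlviz overlay styled.xml --values fluxes.csv --target reactions \
        --channel color --colorbar -o final.xml
sbmlviz export final.xml -f svg -o figure.svg
```

Layout scaling on synthetic models (`run_benchmark(c(20, 100, 500),
iterations = 50, reps = 1, seed = 1)`, one machine, illustrative only):

```
  n_species n_reactions median_s reps iterations
1        20           5    0.027    1         50
2       100          25    0.538    1         50
3       500         125    4.954    1         50
```

## Installation and requirements

Requires R ≥ 4.0 with `xml2`; `jsonlite` (CLI/templates/acceptance) and
`png` (raster tests) are optional. Install from source:

```sh
R CMD INSTALL .
```

## Scope

The generator and layout target diagram *generation and data encoding*;
they do not simulate models, check kinetics, or aim for hand-curated
pathway aesthetics (use the arrangement operations for that). See the
vignette's Limitations section for details.
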