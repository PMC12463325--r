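Package: sbmlviz
Title: Standards-Based Visualization of SBML Biochemical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads and writes SBML Level 3 documents carrying the Layout and
    Render package extensions, auto-generates standards-compliant diagram data
    for models that lack it via a biochemistry-aware force-directed layout
    (reaction hyper-edges with centroid nodes, alias glyphs for hub species,
    role-aware Bezier reaction curves), applies style templates (default,
    SBGN Process Description, Escher-like), arranges reactions horizontally,
    vertically or on circular arcs, overlays quantitative data (fluxes,
    concentrations) as color, width and size encodings with a color bar, and
    exports figures to SVG, PNG, JPEG and PDF. All visualization data is
    stored inside the SBML file itself.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
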