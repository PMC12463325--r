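test_that("all 148 HTML color names resolve to canonical hex", {
  expect_length(sbmlviz:::HTML_COLORS, 148)
  for (nm in names(sbmlviz:::HTML_COLORS)) {
    v <- resolve_color(nm)
    expect_match(v, "^#[0-9A-F]{6}$")
  }
  expect_equal(resolve_color("red"), "#FF0000")
  expect_equal(resolve_color("green"), "#008000")  # CSS green, not lime
  expect_equal(resolve_color("REBECCAPURPLE"), "#663399")
  expect_equal(resolve_color("#ab12cd"), "#AB12CD")
  expect_equal(resolve_color("none"), "none")
})

test_that("unknown color names raise an error with suggestions", {
  err <- tryCatch(resolve_color("turqoise"), error = conditionMessage)
  expect_match(err, "turquoise")
  expect_error(resolve_color("#12345"), "color")
})

test_that("the default render covers every layout element", {
  doc <- default_render(toy_layout_doc())
  expect_equal(style_coverage(doc), 1)
  expect_equal(nrow(validate_layout(doc)), 0)
})

test_that("the style cascade prefers id over role over type over default", {
  doc <- default_render(toy_layout_doc())
  # type-level: species glyphs are filled with the default species fill
  g <- effective_style(doc, "sg_A")
  expect_equal(g$fill, "#FFE699")
  # role-level: product curves carry a filled-arrow end
  els <- layout_elements(doc$layout)
  prod_id <- names(Filter(function(e) identical(e$role, "product"), els))[1]
  expect_equal(effective_style(doc, prod_id)$end_head, "arrow_filled")
  # id-level overrides beat everything
  doc2 <- batch_set(doc, "sg_A", "fill", "#123456")
  expect_equal(effective_style(doc2, "sg_A")$fill, "#123456")
  # other attributes keep falling through the cascade
  expect_equal(effective_style(doc2, "sg_A")$stroke,
               effective_style(doc, "sg_A")$stroke)
  # and sibling elements are untouched
  expect_equal(effective_style(doc2, "sg_B")$fill, "#FFE699")
})

test_that("within a precedence level the later style wins", {
  doc <- default_render(toy_layout_doc())
  n <- length(doc$render$styles)
  doc$render$styles[[n + 1]] <- sbmlviz:::new_style(
    "late", sbmlviz:::new_group(fill = "#00FF11"), type_list = "SPECIESGLYPH")
  expect_equal(effective_style(doc, "sg_A")$fill, "#00FF11")
})

test_that("the indexed cascade agrees with the direct scan", {
  doc <- default_render(toy_layout_doc(seed = 4))
  doc <- apply_template(doc, "sbgn-pd")
  doc <- batch_set(doc, "sg_A", "stroke", "#222222")
  els <- layout_elements(doc$layout)
  idx <- sbmlviz:::style_index(doc)
  for (id in names(els)) {
    expect_identical(effective_style(doc, id, els, idx),
                     effective_style(doc, id, els),
                     info = id)
  }
})

test_that("activator and inhibitor arcs get distinct default heads", {
  doc <- toy_model(c("A", "B", "M1", "M2"), list(
    new_reaction("R1", reactants = "A", products = "B",
                 modifiers = data.frame(
                   species = c("M1", "M2"),
                   sbo = c("SBO:0000459", "SBO:0000020"),
                   stringsAsFactors = FALSE))))
  doc <- build_layout(doc, layout_params(iterations = 20, seed = 1))
  doc <- default_render(doc)
  els <- layout_elements(doc$layout)
  act <- names(Filter(function(e) identical(e$role, "activator"), els))[1]
  inh <- names(Filter(function(e) identical(e$role, "inhibitor"), els))[1]
  expect_equal(effective_style(doc, act)$end_head, "circle_open")
  expect_equal(effective_style(doc, inh)$end_head, "bar_head")
})

test_that("all three named templates cover every element", {
  for (tpl in c("default", "sbgn-pd", "escher")) {
    doc <- apply_template(toy_layout_doc(seed = 2), tpl)
    expect_equal(style_coverage(doc), 1, info = tpl)
    expect_equal(nrow(validate_layout(doc)), 0, info = tpl)
  }
})

test_that("unknown template names are rejected with the known list", {
  err <- tryCatch(apply_template(toy_layout_doc(), "sbgn"),
                  error = conditionMessage)
  expect_match(err, "default")
  expect_match(err, "sbgn-pd")
  expect_match(err, "escher")
})

test_that("every SBGN class has a style recipe", {
  for (cls in sbmlviz:::SBGN_CLASSES) {
    st <- sbgn_style_for_class(cls)
    expect_true(!is.null(st$group), info = cls)
  }
  expect_error(sbgn_style_for_class("not-a-class"), "class")
})

test_that("SBGN classes resolve from SBO terms with sensible fallbacks", {
  species <- data.frame(id = c("P", "S", "X"), name = c("P", "S", "X"),
                        compartment = "c", sbo = c("SBO:0000245",
                                                   "SBO:0000247", NA),
                        stringsAsFactors = FALSE)
  doc <- new_document(new_model("m",
    compartments = data.frame(id = "c", name = "c", stringsAsFactors = FALSE),
    species = species,
    reactions = list(new_reaction("R1", reactants = "P", products = "S",
                                  modifiers = "X"))))
  doc <- build_layout(doc, layout_params(iterations = 15, seed = 1))
  els <- layout_elements(doc$layout)
  expect_equal(sbmlviz:::sbgn_class_of(doc, els[["sg_P"]]), "macromolecule")
  expect_equal(sbmlviz:::sbgn_class_of(doc, els[["sg_S"]]), "simple-chemical")
  expect_equal(sbmlviz:::sbgn_class_of(doc, els[["rg_R1"]]), "process")
  mod_id <- names(Filter(function(e) identical(e$role, "modifier"), els))[1]
  expect_equal(sbmlviz:::sbgn_class_of(doc, els[[mod_id]]), "catalysis")
})

test_that("select_elements finds elements by effective attribute", {
  doc <- default_render(toy_layout_doc())
  doc <- batch_set(doc, c("sg_A", "sg_B"), "fill", "crimson")
  hits <- select_elements(doc, "fill", "#DC143C")
  expect_setequal(hits, c("sg_A", "sg_B"))
})

test_that("batch overrides survive a write/read round trip", {
  doc <- default_render(toy_layout_doc())
  doc <- batch_set(doc, "sg_A", "fill", "#0A0B0C")
  doc2 <- read_document(write_document(doc))
  expect_equal(effective_style(doc2, "sg_A")$fill, "#0A0B0C")
})

test_that("batch_set validates its inputs", {
  doc <- default_render(toy_layout_doc())
  expect_error(batch_set(doc, "nope", "fill", "#000000"), "nope")
  expect_error(batch_set(doc, "sg_A", "sparkle", "#000000"), "attribute")
  expect_error(batch_set(doc, "sg_A", "stroke_width", -1), "non-negative")
  expect_identical(batch_set(doc, character(), "fill", "#000000"), doc)
})

test_that("custom JSON templates load and apply", {
  tf <- tempfile(fileext = ".json")
  writeLines('{
    "name": "demo",
    "defaults": {"background": "#FAFAFA"},
    "class_styles": {
      "SPECIESGLYPH": {"fill": "lavender", "stroke": "#333333",
                       "shape": "ellipse"},
      "product": {"end_head": "arrow_filled"}
    }
  }', tf)
  doc <- apply_template(toy_layout_doc(), load_template(tf))
  expect_equal(doc$render$background_color, "#FAFAFA")
  expect_equal(effective_style(doc, "sg_A")$fill, "#E6E6FA")
  els <- layout_elements(doc$layout)
  prod_id <- names(Filter(function(e) identical(e$role, "product"), els))[1]
  expect_equal(effective_style(doc, prod_id)$end_head, "arrow_filled")
  expect_equal(style_coverage(doc), 1)
  expect_equal(nrow(validate_layout(doc)), 0)
  tf2 <- tempfile(fileext = ".json")
  writeLines("{}", tf2)
  expect_error(load_template(tf2), "name")
})
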