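test_that("gradient interpolation matches the per-channel oracle", {
  gr <- new_gradient("g", data.frame(offset = c(0, 1),
                                     color = c("#000000", "#FF0000"),
                                     stringsAsFactors = FALSE))
  expect_equal(value_to_color(0, gr), "#000000")
  expect_equal(value_to_color(0.5, gr), "#800000")  # 127.5 rounds half up
  expect_equal(value_to_color(1, gr), "#FF0000")
  multi <- default_gradient()
  set.seed(42)
  for (f in runif(200)) {
    expect_equal(value_to_color(f, multi), oracle_gradient_color(f, multi$stops),
                 info = sprintf("fraction %.6f", f))
  }
  expect_error(value_to_color(-0.01, gr), "fraction")
  expect_error(value_to_color(1.01, gr), "fraction")
})

test_that("interpolation on a monotone gradient is monotone per channel", {
  gr <- new_gradient("g", data.frame(offset = c(0, 1),
                                     color = c("#000000", "#FF0000"),
                                     stringsAsFactors = FALSE))
  set.seed(9)
  fr <- sort(runif(300))
  red <- vapply(fr, function(f) strtoi(substr(value_to_color(f, gr), 2, 3), 16L),
                numeric(1))
  expect_true(all(diff(red) >= 0))
})

test_that("normalization clips, scales linearly and handles degeneracy", {
  v <- c(a = 0, b = 5, c = 10)
  expect_equal(unname(normalize_values(v)), c(0, 0.5, 1))
  expect_equal(unname(normalize_values(v, c(0, 20))), c(0, 0.25, 0.5))
  expect_equal(unname(normalize_values(v, c(2, 8))), c(0, 0.5, 1))  # clipped
  expect_equal(unname(normalize_values(c(x = 3, y = 3))), c(0.5, 0.5))
  expect_error(normalize_values(numeric()), "empty")
  expect_error(normalize_values(c(a = NA_real_)), "finite")
})

test_that("reaction color overlays recolor the whole reaction arc set", {
  doc <- default_render(toy_layout_doc(seed = 2))
  doc2 <- overlay_reaction_values(doc, c(R1 = 0, R2 = 1),
                                  overlay_spec("reactions", "color"))
  g1 <- effective_style(doc2, "rg_R1")
  g2 <- effective_style(doc2, "rg_R2")
  expect_equal(g1$stroke, "#4575B4")  # gradient start
  expect_equal(g2$stroke, "#D73027")  # gradient end
  # reference glyphs follow their reaction
  els <- layout_elements(doc2$layout)
  for (id in names(els)) {
    el <- els[[id]]
    if (el$type != "speciesreference") next
    want <- if (el$reaction_glyph == "rg_R1") "#4575B4" else "#D73027"
    expect_equal(effective_style(doc2, id)$stroke, want, info = id)
  }
  expect_equal(nrow(validate_layout(doc2)), 0)
})

test_that("width overlays scale stroke width into the output range", {
  doc <- default_render(toy_layout_doc(seed = 2))
  doc2 <- overlay_reaction_values(doc, c(R1 = 2, R2 = 6),
                                  overlay_spec("reactions", "width",
                                               out_range = c(1, 9)))
  expect_equal(effective_style(doc2, "rg_R1")$stroke_width, 1)
  expect_equal(effective_style(doc2, "rg_R2")$stroke_width, 9)
})

test_that("species color overlays color all alias glyphs identically", {
  hub_doc <- toy_model(c("H", paste0("X", 1:25)),
                       lapply(1:25, function(i)
                         new_reaction(paste0("R", i), reactants = "H",
                                      products = paste0("X", i))))
  doc <- build_layout(hub_doc, layout_params(iterations = 5, seed = 1))
  doc <- default_render(doc)
  vals <- stats::setNames(c(1, runif(25)), c("H", paste0("X", 1:25)))
  doc <- overlay_species_values(doc, vals, overlay_spec("species", "color"))
  h_ids <- vapply(Filter(function(g) identical(g$species_id, "H"),
                         doc$layout$species_glyphs),
                  function(g) g$glyph_id, character(1))
  expect_length(h_ids, 3)
  fills <- vapply(h_ids, function(id) effective_style(doc, id)$fill, character(1))
  expect_equal(unname(unique(fills)), "#D73027")
})

test_that("species size overlays rescale node boxes within the range", {
  doc <- default_render(toy_layout_doc(seed = 3))
  doc2 <- overlay_species_values(doc, c(A = 0, B = 5, C = 10),
                                 overlay_spec("species", "size",
                                              out_range = c(0.5, 2)))
  w <- function(d, id) unname(layout_elements(d$layout)[[id]]$element$bbox[3])
  expect_equal(w(doc2, "sg_A"), 60 * 0.5, tolerance = 1e-9)
  expect_equal(w(doc2, "sg_B"), 60 * 1.25, tolerance = 1e-9)
  expect_equal(w(doc2, "sg_C"), 60 * 2, tolerance = 1e-9)
  expect_equal(nrow(validate_layout(doc2)), 0)
})

test_that("symmetric overlays center zero at the gradient midpoint", {
  doc <- default_render(toy_layout_doc(seed = 2))
  doc2 <- overlay_reaction_values(doc, c(R1 = 0, R2 = -4),
                                  overlay_spec("reactions", "color",
                                               symmetric = TRUE))
  expect_equal(effective_style(doc2, "rg_R1")$stroke, "#DDDDDD")
  expect_equal(effective_style(doc2, "rg_R2")$stroke, "#4575B4")
})

test_that("missing-id policies behave as declared", {
  doc <- default_render(toy_layout_doc(seed = 2))
  vals <- c(R1 = 1, Rghost = 2)
  expect_error(overlay_reaction_values(doc, vals,
                                       overlay_spec("reactions", "color")),
               "Rghost")
  skip_doc <- overlay_reaction_values(doc, vals,
                                      overlay_spec("reactions", "color",
                                                   missing_policy = "skip"))
  expect_equal(nrow(validate_layout(skip_doc)), 0)
  dim_doc <- overlay_reaction_values(doc, c(R1 = 1),
                                     overlay_spec("reactions", "color",
                                                  missing_policy = "dim"))
  expect_equal(effective_style(dim_doc, "rg_R2")$stroke, "#CCCCCC")
})

test_that("the color bar round-trips and labels its value range", {
  doc <- default_render(toy_layout_doc(seed = 2))
  doc <- add_colorbar(doc, default_gradient(), c(-2, 2))
  extra <- vapply(doc$layout$extra_glyphs, function(g) g$glyph_id, character(1))
  expect_true("colorbar" %in% extra)
  labels <- vapply(Filter(function(t) t$target_glyph_id == "colorbar",
                          doc$layout$text_glyphs),
                   function(t) t$text, character(1))
  expect_true(all(c("-2", "0", "2") %in% labels))
  doc2 <- read_document(write_document(doc))
  extra2 <- vapply(doc2$layout$extra_glyphs, function(g) g$glyph_id, character(1))
  expect_true("colorbar" %in% extra2)
  expect_true("flux_gradient" %in% names(doc2$render$gradients))
})

test_that("value maps parse comma and tab files with comments", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("# flux values", "id,value", "R1,0.25", "R2,-3"), tf)
  v <- read_value_map(tf)
  expect_equal(v, c(R1 = 0.25, R2 = -3))
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tvalue", "S1\t7"), tf2)
  expect_equal(read_value_map(tf2), c(S1 = 7))
})
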