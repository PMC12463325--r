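test_that("horizontal alignment puts substrate left, product right", {
  doc <- toy_layout_doc(seed = 2)
  doc <- align_reaction(doc, "R1", "horizontal")
  a <- glyph_center(doc, "sg_A")
  b <- glyph_center(doc, "sg_B")
  ctr <- glyph_center(doc, "rg_R1")
  expect_lt(a[1], b[1])
  expect_equal(a[2], b[2], tolerance = 1e-9)
  expect_equal(ctr[2], a[2], tolerance = 1e-9)
  expect_equal(ctr[1], (a[1] + b[1]) / 2, tolerance = 1e-9)
})

test_that("vertical alignment puts substrate on top and keeps the chord length", {
  doc <- toy_layout_doc(seed = 5)
  before <- sqrt(sum((glyph_center(doc, "sg_A") - glyph_center(doc, "sg_B"))^2))
  doc <- align_reaction(doc, "R1", "vertical")
  a <- glyph_center(doc, "sg_A")
  b <- glyph_center(doc, "sg_B")
  expect_lt(a[2], b[2])
  expect_equal(a[1], b[1], tolerance = 1e-9)
  expect_equal(sqrt(sum((a - b)^2)), before, tolerance = 1e-9)
  # the reaction centroid sits on the chord midpoint
  expect_equal(glyph_center(doc, "rg_R1"), (a + b) / 2, tolerance = 1e-9)
  expect_equal(nrow(validate_layout(doc)), 0)
})

test_that("circular arrangement puts centroids exactly on the circle", {
  doc <- generate_model(20, seed = 3)
  doc <- build_layout(doc, layout_params(iterations = 10, seed = 3))
  arc <- arc_spec(center = c(400, 300), radius = 120)
  doc <- arrange_reactions_circle(doc, c("R1", "R2", "R3", "R4", "R5"), arc)
  for (r in paste0("R", 1:5)) {
    d <- sqrt(sum((glyph_center(doc, paste0("rg_", r)) - c(400, 300))^2))
    expect_equal(d, 120, tolerance = 1e-6)
  }
  expect_equal(nrow(validate_layout(doc)), 0)
})

test_that("four reactions on a full circle sit at the compass points", {
  doc <- generate_model(20, seed = 3)
  doc <- build_layout(doc, layout_params(iterations = 10, seed = 3))
  doc <- arrange_reactions_circle(doc, c("R1", "R2", "R3", "R4"),
                                  arc_spec(center = c(400, 300), radius = 100))
  # 0 degrees is up, positive angles clockwise
  expect_equal(glyph_center(doc, "rg_R1"), c(400, 200), tolerance = 1e-9)
  expect_equal(glyph_center(doc, "rg_R2"), c(500, 300), tolerance = 1e-9)
  expect_equal(glyph_center(doc, "rg_R3"), c(400, 400), tolerance = 1e-9)
  expect_equal(glyph_center(doc, "rg_R4"), c(300, 300), tolerance = 1e-9)
})

test_that("partial arcs spread reactions over the span inclusively", {
  doc <- generate_model(20, seed = 4)
  doc <- build_layout(doc, layout_params(iterations = 10, seed = 4))
  arc <- arc_spec(center = c(300, 300), radius = 150, start_angle = 90,
                  span = 180)
  doc <- arrange_reactions_circle(doc, c("R1", "R2", "R3"), arc)
  # angles 90, 180, 270: right, down, left of center
  expect_equal(glyph_center(doc, "rg_R1"), c(450, 300), tolerance = 1e-9)
  expect_equal(glyph_center(doc, "rg_R2"), c(300, 450), tolerance = 1e-9)
  expect_equal(glyph_center(doc, "rg_R3"), c(150, 300), tolerance = 1e-9)
})

test_that("counterclockwise arrangement mirrors the angular direction", {
  doc <- generate_model(20, seed = 4)
  doc <- build_layout(doc, layout_params(iterations = 10, seed = 4))
  arc <- arc_spec(center = c(400, 300), radius = 100,
                  direction = "counterclockwise")
  doc <- arrange_reactions_circle(doc, c("R1", "R2"), arc)
  expect_equal(glyph_center(doc, "rg_R1"), c(400, 200), tolerance = 1e-9)
  expect_equal(glyph_center(doc, "rg_R2"), c(400, 400), tolerance = 1e-9)
})

test_that("chained reactions sharing a species are merged on the circle", {
  doc <- toy_model(c("A", "B", "C"),
                   list(new_reaction("R1", reactants = "A", products = "B"),
                        new_reaction("R2", reactants = "B", products = "C")))
  doc <- build_layout(doc, layout_params(iterations = 10, seed = 1))
  n_b_before <- length(Filter(function(g) identical(g$species_id, "B"),
                              doc$layout$species_glyphs))
  doc <- arrange_reactions_circle(doc, c("R1", "R2"),
                                  arc_spec(center = c(400, 300), radius = 120,
                                           span = 180))
  # product of R1 and substrate of R2 collapse onto one shared glyph
  b_glyphs <- Filter(function(g) identical(g$species_id, "B"),
                     doc$layout$species_glyphs)
  expect_length(b_glyphs, 1)
  expect_lte(length(b_glyphs), n_b_before)
  expect_equal(nrow(validate_layout(doc)), 0)
})

test_that("moving a species drags its label and reattaches curves", {
  doc <- toy_layout_doc(seed = 6)
  doc <- move_species_glyph(doc, "sg_A", c(50, 60))
  expect_equal(glyph_center(doc, "sg_A"), c(50, 60), tolerance = 1e-9)
  tg <- Filter(function(t) t$target_glyph_id == "sg_A", doc$layout$text_glyphs)[[1]]
  expect_equal(unname(tg$bbox[1] + tg$bbox[3] / 2), 50, tolerance = 1e-9)
  # incident curve endpoints now touch the new boundary ellipse
  sg <- doc$layout$species_glyphs[[
    which(vapply(doc$layout$species_glyphs, function(g) g$glyph_id,
                 character(1)) == "sg_A")]]
  for (rg in doc$layout$reaction_glyphs)
    for (ref in rg$reference_glyphs) {
      if (ref$species_glyph_id != "sg_A") next
      pt <- if (ref$role %in% c("product", "side-product"))
        ref$curve[[length(ref$curve)]]$end else ref$curve[[1]]$start
      ctr <- c(sg$bbox[1] + sg$bbox[3] / 2, sg$bbox[2] + sg$bbox[4] / 2)
      u <- (pt - ctr) / (c(sg$bbox[3], sg$bbox[4]) / 2)
      expect_equal(sum(u^2), 1, tolerance = 1e-6)
    }
  expect_equal(nrow(validate_layout(doc)), 0)
})

test_that("moving a species leaves unrelated curves untouched", {
  doc <- toy_layout_doc(seed = 6)
  r2_before <- doc$layout$reaction_glyphs[[2]]
  doc <- move_species_glyph(doc, "sg_A", c(50, 60))
  expect_identical(doc$layout$reaction_glyphs[[2]], r2_before)
})

test_that("arrangement errors name the unknown reaction", {
  doc <- toy_layout_doc()
  expect_error(align_reaction(doc, "nope", "horizontal"), "nope")
  expect_error(arrange_reactions_circle(doc, c("R1", "R1"),
                                        arc_spec(c(0, 0), 10)), "duplicate")
  expect_error(arrange_reactions_circle(doc, character(), arc_spec(c(0, 0), 10)))
})

test_that("arc specifications are validated", {
  expect_error(arc_spec(c(0, 0), -5))
  expect_error(arc_spec(c(0, 0), 10, span = 0))
  expect_error(arc_spec(c(0, 0), 10, span = 361))
  expect_error(arc_spec(c(0, 0), 10, direction = "sideways"))
})
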