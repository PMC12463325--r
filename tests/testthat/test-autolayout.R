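test_that("one relaxation step matches the brute-force force evaluation", {
  maxdev <- 0
  for (s in 1:25) {
    doc <- generate_model(12, seed = s)
    g <- add_emptyset_nodes(build_graph(doc))
    expect_lte(length(g$nodes), 20)
    p <- layout_params(seed = s)
    pos <- place_initial(g, p)
    got <- fr_step(g, pos, 40, p)
    want <- brute_force_fr(g, pos, 40, p)
    maxdev <- max(maxdev, max(abs(got - want)))
  }
  expect_lt(maxdev, 1e-9)
})

test_that("two connected nodes settle near the ideal edge length", {
  for (s in 1:5) {
    doc <- toy_model(c("A", "B"))
    g <- build_graph(doc)
    g$edges <- list(sbmlviz:::new_network_edge("e1", "n_A", "n_B", "substrate"))
    p <- layout_params(iterations = 500, seed = s)
    pos <- run_force_layout(g, p)
    d <- sqrt(sum((pos[1, ] - pos[2, ])^2))
    k <- p$k_scale * sqrt(p$canvas_width * p$canvas_height / 2)
    expect_lt(abs(d - k) / k, 0.05)
  }
})

test_that("initial placement is deterministic, inside the padded canvas", {
  doc <- generate_model(40, seed = 2)
  g <- add_emptyset_nodes(build_graph(doc))
  p <- layout_params(seed = 5)
  a <- place_initial(g, p)
  b <- place_initial(g, p)
  expect_identical(a, b)
  expect_true(all(a[, 1] >= p$padding & a[, 1] <= p$canvas_width - p$padding))
  expect_true(all(a[, 2] >= p$padding & a[, 2] <= p$canvas_height - p$padding))
  c2 <- place_initial(g, layout_params(seed = 6))
  expect_false(identical(a, c2))
})

test_that("positions stay within the canvas after every iteration", {
  doc <- generate_model(40, seed = 9)
  g <- add_emptyset_nodes(build_graph(doc))
  p <- layout_params(iterations = 60, seed = 9)
  pos <- run_force_layout(g, p)
  expect_true(all(pos[, 1] >= 0 & pos[, 1] <= p$canvas_width))
  expect_true(all(pos[, 2] >= 0 & pos[, 2] <= p$canvas_height))
})

test_that("coincident nodes are separated deterministically", {
  doc <- toy_model(c("A", "B"))
  g <- build_graph(doc)
  p <- layout_params(seed = 1)
  pos <- rbind(n_A = c(100, 100), n_B = c(100, 100))
  out1 <- fr_step(g, pos, 30, p)
  out2 <- fr_step(g, pos, 30, p)
  expect_identical(out1, out2)
  expect_gt(sqrt(sum((out1[1, ] - out1[2, ])^2)), 0)
})

test_that("uni-uni reactions are straightened through the midpoint", {
  for (s in c(2, 7, 11)) {
    doc <- toy_model(c("A", "B"),
                     list(new_reaction("R1", reactants = "A", products = "B")))
    doc <- build_layout(doc, layout_params(iterations = 40, seed = s))
    a <- glyph_center(doc, "sg_A")
    b <- glyph_center(doc, "sg_B")
    ctr <- glyph_center(doc, "rg_R1")
    expect_lt(max(abs(ctr - (a + b) / 2)), 1e-9)
    # control points exactly on the chord
    for (rg in doc$layout$reaction_glyphs)
      for (ref in rg$reference_glyphs)
        for (seg in ref$curve) {
          expect_lt(abs(cross2(seg$start, seg$end, seg$bp1)), 1e-6)
          expect_lt(abs(cross2(seg$start, seg$end, seg$bp2)), 1e-6)
          # all four points on the species-to-species chord
          expect_lt(abs(cross2(a, b, seg$start)), 1e-6)
          expect_lt(abs(cross2(a, b, seg$end)), 1e-6)
        }
  }
})

test_that("a bi-bi reaction is not straightened", {
  doc <- toy_model(c("A", "B", "C", "D"),
                   list(new_reaction("R1", reactants = c("A", "B"),
                                     products = c("C", "D"))))
  g <- add_emptyset_nodes(build_graph(doc))
  expect_length(sbmlviz:::uniuni_centroids(g), 0)
})

test_that("build_layout emits a glyph for every species and reaction", {
  doc <- generate_model(40, seed = 4)
  doc <- build_layout(doc, layout_params(iterations = 20, seed = 4))
  l <- doc$layout
  drawn_species <- unique(vapply(Filter(function(g) !is.na(g$species_id),
                                        l$species_glyphs),
                                 function(g) g$species_id, character(1)))
  expect_setequal(drawn_species, doc$model$species$id)
  expect_length(l$reaction_glyphs, 10)
  # every reaction glyph covers all participants of its reaction
  for (rg in l$reaction_glyphs) {
    r <- Filter(function(x) x$id == rg$reaction_id, doc$model$reactions)[[1]]
    expect_length(rg$reference_glyphs,
                  nrow(r$reactants) + nrow(r$products) + nrow(r$modifiers))
  }
  expect_equal(nrow(validate_layout(doc)), 0)
})

test_that("every glyph lies inside the layout dimensions", {
  doc <- generate_model(60, seed = 8)
  doc <- build_layout(doc, layout_params(iterations = 25, seed = 8))
  l <- doc$layout
  for (el in layout_elements(l)) {
    if (is.null(el$element$bbox)) next
    b <- el$element$bbox
    expect_gte(b[1], 0); expect_gte(b[2], 0)
    expect_lte(b[1] + b[3], l$width + 1e-9)
    expect_lte(b[2] + b[4], l$height + 1e-9)
  }
})

test_that("the layout pipeline is deterministic end to end", {
  doc <- generate_model(32, seed = 6)
  a <- build_layout(doc, layout_params(iterations = 15, seed = 6))
  b <- build_layout(doc, layout_params(iterations = 15, seed = 6))
  expect_identical(a, b)
})

test_that("hub species are split into alias glyphs during layout", {
  hub_doc <- toy_model(c("H", paste0("X", 1:25)),
                       lapply(1:25, function(i)
                         new_reaction(paste0("R", i), reactants = "H",
                                      products = paste0("X", i))))
  doc <- build_layout(hub_doc, layout_params(iterations = 10, seed = 1,
                                             alias_threshold = 10))
  h_glyphs <- Filter(function(g) identical(g$species_id, "H"),
                     doc$layout$species_glyphs)
  expect_length(h_glyphs, 3)
  expect_setequal(vapply(h_glyphs, function(g) g$alias_index, integer(1)), 0:2)
})

test_that("curves attach on the species boundary ellipse", {
  doc <- toy_layout_doc(seed = 3)
  els <- layout_elements(doc$layout)
  for (rg in doc$layout$reaction_glyphs) {
    for (ref in rg$reference_glyphs) {
      sg <- els[[ref$species_glyph_id]]$element
      ctr <- c(sg$bbox[1] + sg$bbox[3] / 2, sg$bbox[2] + sg$bbox[4] / 2)
      # species-side endpoint of the curve
      pt <- if (ref$role %in% c("product", "side-product"))
        ref$curve[[length(ref$curve)]]$end else ref$curve[[1]]$start
      u <- (pt - ctr) / (c(sg$bbox[3], sg$bbox[4]) / 2)
      expect_equal(sum(u^2), 1, tolerance = 1e-6)
    }
  }
})

test_that("invalid layout parameters are rejected", {
  expect_error(layout_params(iterations = -1))
  expect_error(layout_params(canvas_width = 0))
  expect_error(layout_params(k_scale = -2))
})
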