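test_that("the SVG export contains every layout element by id", {
  doc <- default_render(toy_layout_doc(seed = 1))
  svg <- to_svg(doc)
  expect_match(svg, "^<\\?xml")
  expect_match(svg, "<svg")
  for (id in names(layout_elements(doc$layout)))
    expect_match(svg, paste0('id="', id, '"'), fixed = TRUE,
                 label = sprintf("element %s in SVG", id))
})

test_that("SVG dimensions follow the layout and export scale", {
  doc <- default_render(toy_layout_doc(seed = 1))
  svg <- to_svg(doc)
  w <- doc$layout$width
  h <- doc$layout$height
  expect_match(svg, sprintf('width="%s"', sbmlviz:::fmt_num(w)), fixed = TRUE)
  expect_match(svg, sprintf('height="%s"', sbmlviz:::fmt_num(h)), fixed = TRUE)
})

test_that("species labels appear as text in the SVG", {
  doc <- default_render(toy_layout_doc(seed = 1))
  svg <- to_svg(doc)
  expect_match(svg, ">A</text>", fixed = TRUE)
  expect_match(svg, ">B</text>", fixed = TRUE)
})

test_that("arrow markers are attached to product curves only", {
  doc <- default_render(toy_layout_doc(seed = 1))
  svg <- to_svg(doc)
  expect_match(svg, "marker-end")
  expect_match(svg, '<marker id="arrow_filled"', fixed = TRUE)
  # exactly one decorated curve per product reference; substrates are bare
  els <- layout_elements(doc$layout)
  n_products <- sum(vapply(els, function(e)
    identical(e$role, "product"), logical(1)))
  expect_equal(lengths(regmatches(svg, gregexpr("marker-end", svg))),
               n_products)
})

test_that("gradient fills become SVG linearGradient defs", {
  doc <- default_render(toy_layout_doc(seed = 1))
  doc <- add_colorbar(doc, default_gradient(), c(0, 1))
  svg <- to_svg(doc)
  expect_match(svg, '<linearGradient id="flux_gradient"', fixed = TRUE)
  expect_match(svg, 'fill="url(#flux_gradient)"', fixed = TRUE)
})

test_that("raster exports honor format signatures and scale", {
  skip_if_not_installed("png")
  doc <- default_render(toy_layout_doc(seed = 1))
  b_png <- to_bytes(doc, export_options("png"))
  expect_identical(b_png[1:8],
                   as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)))
  img <- png::readPNG(b_png)
  expect_equal(dim(img)[2], ceiling(doc$layout$width))
  expect_equal(dim(img)[1], ceiling(doc$layout$height))
  img2 <- png::readPNG(to_bytes(doc, export_options("png", scale = 2)))
  expect_equal(dim(img2)[2], ceiling(doc$layout$width * 2))
  b_jpg <- to_bytes(doc, export_options("jpeg"))
  expect_identical(b_jpg[1:2], as.raw(c(0xFF, 0xD8)))
  b_pdf <- to_bytes(doc, export_options("pdf"))
  expect_identical(rawToChar(b_pdf[1:5]), "%PDF-")
})

test_that("export_figure infers the format from the file extension", {
  doc <- default_render(toy_layout_doc(seed = 1))
  for (ext in c("svg", "png", "jpeg", "pdf")) {
    tf <- tempfile(fileext = paste0(".", ext))
    export_figure(doc, tf)
    expect_gt(file.size(tf), 100)
  }
  expect_error(export_figure(doc, tempfile(fileext = ".bmp")), "format")
})

test_that("exporting a document without render data applies the defaults", {
  doc <- toy_layout_doc(seed = 1)
  expect_null(doc$render)
  svg <- to_svg(doc)
  expect_match(svg, "rect")
})

test_that("SVG output is deterministic", {
  doc <- default_render(toy_layout_doc(seed = 1))
  expect_identical(to_svg(doc), to_svg(doc))
})

test_that("invalid export options are rejected", {
  expect_error(export_options("gif"))
  expect_error(export_options("png", scale = 0), "scale")
})
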