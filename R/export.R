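# Rendering a document's layout + render data to SVG and to raster/vector
# figures (png, jpeg, pdf) via R's graphics devices.

EXPORT_FORMATS <- c("svg", "png", "jpeg", "pdf")

# Paint value -> SVG attribute value ("none", hex, or gradient reference).
svg_paint <- function(v, render) {
  if (is.null(v)) return("none")
  if (v %in% names(render$gradients)) return(sprintf("url(#%s)", v))
  if (v %in% names(render$colors)) return(render$colors[[v]])
  v
}

svg_prims <- function(prims, bbox, g, render) {
  bx <- bbox[1]; by <- bbox[2]; bw <- bbox[3]; bh <- bbox[4]
  stroke <- svg_paint(g$stroke, render)
  fill <- svg_paint(g$fill, render)
  sw <- g$stroke_width %||% 1
  vapply(prims, function(p) {
    switch(p$kind,
      rectangle = sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" rx="%s" ry="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
        fmt_num(bx + p$x * bw), fmt_num(by + p$y * bh),
        fmt_num(p$w * bw), fmt_num(p$h * bh),
        fmt_num(p$rx * bw), fmt_num(p$ry * bh), fill, stroke, fmt_num(sw)),
      ellipse = sprintf(
        '<ellipse cx="%s" cy="%s" rx="%s" ry="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
        fmt_num(bx + p$cx * bw), fmt_num(by + p$cy * bh),
        fmt_num(p$rx * bw), fmt_num(p$ry * bh), fill, stroke, fmt_num(sw)),
      polygon = sprintf(
        '<polygon points="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
        paste(apply(p$points, 1, function(q)
          paste0(fmt_num(bx + q[1] * bw), ",", fmt_num(by + q[2] * bh))),
          collapse = " "), fill, stroke, fmt_num(sw)),
      curve = sprintf(
        '<path d="%s" fill="none" stroke="%s" stroke-width="%s"/>',
        paste0("M ", paste(apply(p$points, 1, function(q)
          paste0(fmt_num(bx + q[1] * bw), " ", fmt_num(by + q[2] * bh))),
          collapse = " L ")), stroke, fmt_num(sw)),
      text = "",
      "")
  }, character(1))
}

#' Render a document to SVG text
#'
#' The canvas equals the layout dimensions. Draw order: background,
#' compartments, reaction curves (with line-ending markers), reaction
#' centers, species, additional graphical objects (color bar), text. Each
#' render primitive maps to its SVG counterpart (rectangle to rect with
#' rx/ry, ellipse, polygon, render-curve to path, gradients to
#' linearGradient defs, line endings to marker defs). If render data is
#' absent, the default style set is attached first.
#'
#' @param doc a `sbml_document` with a layout
#' @return SVG 1.1 text
#' @export
to_svg <- function(doc) {
  if (is.null(doc$layout))
    stopf("document has no layout; run build_layout() first")
  if (is.null(doc$render)) doc <- default_render(doc)
  l <- doc$layout
  r <- doc$render
  els <- layout_elements(l)
  sidx <- style_index(doc)
  out <- character()
  w <- function(...) out[[length(out) + 1]] <<- paste0(...)

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_num(l$width), fmt_num(l$height), fmt_num(l$width), fmt_num(l$height)))
  w("<defs>")
  for (g in r$gradients) {
    w(sprintf('<linearGradient id="%s" x1="0%%" y1="100%%" x2="0%%" y2="0%%">',
              g$gradient_id))
    for (i in seq_len(nrow(g$stops)))
      w(sprintf('<stop offset="%s%%" stop-color="%s"/>',
                fmt_num(g$stops$offset[i] * 100), g$stops$color[i]))
    w("</linearGradient>")
  }
  for (le in r$line_endings) {
    b <- le$bbox
    w(sprintf('<marker id="%s" viewBox="0 0 %s %s" refX="%s" refY="%s" markerWidth="%s" markerHeight="%s" orient="%s" markerUnits="userSpaceOnUse">',
              le$ending_id, fmt_num(b[3]), fmt_num(b[4]),
              fmt_num(-b[1]), fmt_num(-b[2]), fmt_num(b[3]), fmt_num(b[4]),
              if (le$rotational_mapping) "auto" else "0"))
    for (p in svg_prims(le$group$primitives, c(0, 0, b[3], b[4]), le$group, r))
      if (nzchar(p)) w(p)
    w("</marker>")
  }
  w("</defs>")
  bg <- svg_paint(r$background_color, r)
  w(sprintf('<rect x="0" y="0" width="%s" height="%s" fill="%s"/>',
            fmt_num(l$width), fmt_num(l$height), bg))

  shape_group <- function(glyph, type_label) {
    g <- effective_style(doc, glyph$glyph_id, els, sidx)
    prims <- g$primitives
    if (length(prims) == 0) prims <- list(prim_rectangle())
    body <- svg_prims(prims, glyph$bbox, g, r)
    body <- body[nzchar(body)]
    w(sprintf('<g id="%s" class="%s">', glyph$glyph_id, type_label))
    for (p in body) w(p)
    if (length(body) == 0)
      w(sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="none"/>',
                fmt_num(glyph$bbox[1]), fmt_num(glyph$bbox[2]),
                fmt_num(glyph$bbox[3]), fmt_num(glyph$bbox[4])))
    w("</g>")
  }

  for (g in l$compartment_glyphs) shape_group(g, "compartment")

  for (rg in l$reaction_glyphs) {
    for (ref in rg$reference_glyphs) {
      g <- effective_style(doc, ref$glyph_id, els, sidx)
      d <- character()
      for (seg in ref$curve) {
        d <- c(d, sprintf("M %s %s", fmt_num(seg$start[1]), fmt_num(seg$start[2])))
        if (is.null(seg$bp1))
          d <- c(d, sprintf("L %s %s", fmt_num(seg$end[1]), fmt_num(seg$end[2])))
        else
          d <- c(d, sprintf("C %s %s %s %s %s %s",
                            fmt_num(seg$bp1[1]), fmt_num(seg$bp1[2]),
                            fmt_num(seg$bp2[1]), fmt_num(seg$bp2[2]),
                            fmt_num(seg$end[1]), fmt_num(seg$end[2])))
      }
      heads <- ""
      if (!is.null(g$start_head) && g$start_head != "none")
        heads <- paste0(heads, sprintf(' marker-start="url(#%s)"', g$start_head))
      if (!is.null(g$end_head) && g$end_head != "none")
        heads <- paste0(heads, sprintf(' marker-end="url(#%s)"', g$end_head))
      w(sprintf('<g id="%s" class="speciesreference %s">', ref$glyph_id,
                ref$role))
      w(sprintf('<path d="%s" fill="none" stroke="%s" stroke-width="%s"%s/>',
                paste(d, collapse = " "), svg_paint(g$stroke, r),
                fmt_num(g$stroke_width %||% 1), heads))
      w("</g>")
    }
  }
  for (rg in l$reaction_glyphs) shape_group(rg, "reaction")
  for (g in l$species_glyphs) shape_group(g, "species")
  for (g in l$extra_glyphs) shape_group(g, "graphicalobject")

  for (tg in l$text_glyphs) {
    g <- effective_style(doc, tg$glyph_id, els, sidx)
    anchor <- switch(g$text_anchor %||% "middle",
                     "start" = "start", "end" = "end", "middle")
    cx <- tg$bbox[1] + tg$bbox[3] / 2
    cy <- tg$bbox[2] + tg$bbox[4] / 2
    if (anchor == "start") cx <- tg$bbox[1]
    w(sprintf('<g id="%s" class="text">', tg$glyph_id))
    w(sprintf('<text x="%s" y="%s" text-anchor="%s" dominant-baseline="middle" font-family="%s" font-size="%s" fill="%s">%s</text>',
              fmt_num(cx), fmt_num(cy), anchor,
              g$font_family %||% "sans-serif", fmt_num(g$font_size %||% 11),
              svg_paint(g$stroke, r) , xml_escape(tg$text)))
    w("</g>")
  }
  w("</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Export options
#' @param format one of `"svg"`, `"png"`, `"jpeg"`, `"pdf"`
#' @param scale pixels per layout point (> 0, default 1)
#' @param background optional background color override
#' @export
export_options <- function(format = "svg", scale = 1, background = NULL) {
  if (!(format %in% EXPORT_FORMATS))
    stopf("unsupported format '%s'; supported formats: %s", format,
          paste(EXPORT_FORMATS, collapse = ", "))
  if (!is.numeric(scale) || scale <= 0) stopf("scale must be > 0")
  list(format = format, scale = scale,
       background = if (is.null(background)) NULL else resolve_color(background))
}

#' Render a document to bytes in the requested format
#'
#' SVG output is the UTF-8 encoding of [to_svg()]; png/jpeg rasterize the
#' same drawing at `scale` pixels per layout point (pixel dimensions =
#' `ceiling(layout dims * scale)`); pdf is vector.
#'
#' @param doc a `sbml_document` with a layout
#' @param opts an [export_options()]
#' @return a raw vector
#' @export
to_bytes <- function(doc, opts = export_options()) {
  if (is.character(opts)) opts <- export_options(opts)
  if (!is.null(opts$background) && !is.null(doc$render))
    doc$render$background_color <- opts$background
  if (opts$format == "svg")
    return(charToRaw(enc2utf8(to_svg(doc))))
  if (is.null(doc$layout)) stopf("document has no layout; run build_layout() first")
  if (is.null(doc$render)) doc <- default_render(doc)
  path <- tempfile(fileext = paste0(".", opts$format))
  on.exit(unlink(path), add = TRUE)
  W <- doc$layout$width; H <- doc$layout$height
  px_w <- ceiling(W * opts$scale); px_h <- ceiling(H * opts$scale)
  switch(opts$format,
    png = grDevices::png(path, width = px_w, height = px_h, res = 72 * opts$scale),
    jpeg = grDevices::jpeg(path, width = px_w, height = px_h, res = 72 * opts$scale,
                           quality = 95),
    pdf = grDevices::pdf(path, width = W * opts$scale / 72,
                         height = H * opts$scale / 72))
  ok <- tryCatch({ draw_document(doc); TRUE },
                 finally = grDevices::dev.off())
  if (!ok) stopf("drawing failed")
  readBin(path, "raw", n = file.size(path))
}

#' Export a figure to a file
#' @param doc a `sbml_document`
#' @param path output file; format inferred from the extension unless given
#' @param format optional explicit format
#' @param scale pixels per layout point
#' @return `path`, invisibly
#' @export
export_figure <- function(doc, path, format = NULL, scale = 1) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "jpg") "jpeg" else ext
  }
  bytes <- to_bytes(doc, export_options(format, scale))
  writeBin(bytes, path)
  invisible(path)
}

# ---- device drawing (raster/pdf path) --------------------------------------

dev_paint <- function(v, render, default = NA) {
  if (is.null(v) || identical(v, "none")) return(default)
  if (v %in% names(render$colors)) return(render$colors[[v]])
  if (v %in% names(render$gradients)) {
    # devices lack gradient paint; use the midpoint color
    return(value_to_color(0.5, render$gradients[[v]]))
  }
  v
}

bezier_points <- function(seg, n = 24) {
  t <- seq(0, 1, length.out = n)
  if (is.null(seg$bp1)) {
    cbind(seg$start[1] + t * (seg$end[1] - seg$start[1]),
          seg$start[2] + t * (seg$end[2] - seg$start[2]))
  } else {
    b <- function(i) (1 - t)^3 * seg$start[i] + 3 * (1 - t)^2 * t * seg$bp1[i] +
      3 * (1 - t) * t^2 * seg$bp2[i] + t^3 * seg$end[i]
    cbind(b(1), b(2))
  }
}

draw_document <- function(doc) {
  l <- doc$layout; r <- doc$render
  els <- layout_elements(l)
  sidx <- style_index(doc)
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, l$width), ylim = c(l$height, 0), asp = 1)
  graphics::rect(0, 0, l$width, l$height, border = NA,
                 col = dev_paint(r$background_color, r, "#FFFFFF"))

  draw_prims <- function(bbox, g) {
    stroke <- dev_paint(g$stroke, r)
    fill <- dev_paint(g$fill, r)
    lwd <- max(0.1, g$stroke_width %||% 1)
    prims <- g$primitives
    if (length(prims) == 0) prims <- list(prim_rectangle())
    for (p in prims) {
      bx <- bbox[1]; by <- bbox[2]; bw <- bbox[3]; bh <- bbox[4]
      switch(p$kind,
        rectangle = graphics::rect(bx + p$x * bw, by + p$y * bh,
                                   bx + (p$x + p$w) * bw, by + (p$y + p$h) * bh,
                                   col = fill, border = stroke, lwd = lwd),
        ellipse = {
          th <- seq(0, 2 * pi, length.out = 48)
          graphics::polygon(bx + p$cx * bw + p$rx * bw * cos(th),
                            by + p$cy * bh + p$ry * bh * sin(th),
                            col = fill, border = stroke, lwd = lwd)
        },
        polygon = graphics::polygon(bx + p$points[, 1] * bw,
                                    by + p$points[, 2] * bh,
                                    col = fill, border = stroke, lwd = lwd),
        curve = graphics::lines(bx + p$points[, 1] * bw, by + p$points[, 2] * bh,
                                col = if (is.na(stroke)) "#000000" else stroke,
                                lwd = lwd),
        text = NULL)
    }
  }

  for (g in l$compartment_glyphs)
    draw_prims(g$bbox, effective_style(doc, g$glyph_id, els, sidx))

  for (rg in l$reaction_glyphs) for (ref in rg$reference_glyphs) {
    g <- effective_style(doc, ref$glyph_id, els, sidx)
    col <- dev_paint(g$stroke, r, "#000000")
    lwd <- max(0.1, g$stroke_width %||% 1)
    pts <- do.call(rbind, lapply(ref$curve, bezier_points))
    if (is.null(pts) || nrow(pts) < 2) next
    graphics::lines(pts[, 1], pts[, 2], col = col, lwd = lwd)
    # arrowheads as filled triangles at the decorated end
    draw_head <- function(at, prev) {
      v <- at - prev
      nv <- sqrt(sum(v^2)); if (nv == 0) return()
      v <- v / nv; o <- c(-v[2], v[1]) * 4
      base <- at - v * 10
      graphics::polygon(c(at[1], base[1] + o[1], base[1] - o[1]),
                        c(at[2], base[2] + o[2], base[2] - o[2]),
                        col = col, border = col)
    }
    if (!is.null(g$end_head) && g$end_head != "none")
      draw_head(pts[nrow(pts), ], pts[nrow(pts) - 1, ])
    if (!is.null(g$start_head) && g$start_head != "none")
      draw_head(pts[1, ], pts[2, ])
  }
  for (rg in l$reaction_glyphs)
    draw_prims(rg$bbox, effective_style(doc, rg$glyph_id, els, sidx))
  for (g in l$species_glyphs)
    draw_prims(g$bbox, effective_style(doc, g$glyph_id, els, sidx))
  for (g in l$extra_glyphs)
    draw_prims(g$bbox, effective_style(doc, g$glyph_id, els, sidx))
  for (tg in l$text_glyphs) {
    g <- effective_style(doc, tg$glyph_id, els, sidx)
    cen <- bbox_center(tg$bbox)
    graphics::text(cen[1], cen[2], tg$text,
                   col = dev_paint(g$stroke, r, "#000000"),
                   cex = (g$font_size %||% 11) / 12)
  }
  invisible(NULL)
}
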