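# Quantitative data overlays: map reaction fluxes / species concentrations
# onto gradient color, curve thickness or node size, plus a color bar.
# Overlays are written as id-selector style overrides so the base template
# survives untouched.

#' Default overlay gradient: muted blue through light gray to vivid red
#' @export
default_gradient <- function() {
  new_gradient("flux_gradient",
               data.frame(offset = c(0, 0.5, 1),
                          color = c("#4575B4", "#DDDDDD", "#D73027"),
                          stringsAsFactors = FALSE))
}

#' Overlay specification
#'
#' @param target `"reactions"` or `"species"`
#' @param channel `"color"`, `"width"` (reactions) or `"size"` (species)
#' @param gradient a [new_gradient()] (color channel)
#' @param out_range numeric `(min, max)`: stroke width in pt for `width`,
#'   scale factor of the default node width for `size`
#' @param value_range optional `(vmin, vmax)` normalization override;
#'   observed min/max otherwise
#' @param missing_policy how to treat value ids absent from the model:
#'   `"error"`, `"skip"`, or `"dim"` (style them with the dim color)
#' @param symmetric center zero at fraction 0.5 with range +/- max(|v|)
#'   (signed fluxes of reversible reactions)
#' @export
overlay_spec <- function(target = c("reactions", "species"),
                         channel = c("color", "width", "size"),
                         gradient = default_gradient(),
                         out_range = c(1, 10),
                         value_range = NULL,
                         missing_policy = c("error", "skip", "dim"),
                         symmetric = FALSE) {
  target <- match.arg(target)
  channel <- match.arg(channel)
  missing_policy <- match.arg(missing_policy)
  if (out_range[1] > out_range[2]) stopf("out_range min must be <= max")
  if (!is.null(value_range) && value_range[1] > value_range[2])
    stopf("value_range min must be <= max")
  list(target = target, channel = channel, gradient = gradient,
       out_range = out_range, value_range = value_range,
       missing_policy = missing_policy, symmetric = isTRUE(symmetric))
}

#' Normalize a value map to fractions in [0, 1]
#'
#' Linear min-max scaling over `value_range` when given, else over the
#' observed range; out-of-range values are clipped. A degenerate range
#' (vmin == vmax) maps every value to 0.5.
#'
#' @param values named numeric vector (element id -> value)
#' @param value_range optional `(vmin, vmax)`
#' @return named numeric vector of fractions
#' @export
normalize_values <- function(values, value_range = NULL) {
  if (length(values) == 0) stopf("empty value map")
  if (any(!is.finite(values))) stopf("value map contains non-finite values")
  if (is.null(value_range)) value_range <- range(values)
  if (value_range[1] > value_range[2]) stopf("vmin must be <= vmax")
  if (value_range[1] == value_range[2])
    return(stats::setNames(rep(0.5, length(values)), names(values)))
  clamp((values - value_range[1]) / (value_range[2] - value_range[1]), 0, 1)
}

#' Interpolate a gradient color for a fraction in [0, 1]
#'
#' Finds the bracketing stops and linearly interpolates each 8-bit RGB
#' channel, rounding half up. Fractions 0 and 1 return the first and last
#' stop colors exactly.
#'
#' @param fraction a number in [0, 1] (normalize first)
#' @param gradient a [new_gradient()]
#' @return hex color "#RRGGBB"
#' @export
value_to_color <- function(fraction, gradient = default_gradient()) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stopf("fraction must be in [0, 1]; got %s (normalize values first)",
          format(fraction))
  st <- gradient$stops
  n <- nrow(st)
  if (fraction <= st$offset[1]) return(substr(st$color[1], 1, 7))
  if (fraction >= st$offset[n]) return(substr(st$color[n], 1, 7))
  hi <- which(st$offset >= fraction)[1]
  lo <- hi - 1
  span <- st$offset[hi] - st$offset[lo]
  t <- if (span == 0) 1 else (fraction - st$offset[lo]) / span
  rgb_of <- function(hex) strtoi(c(substr(hex, 2, 3), substr(hex, 4, 5),
                                   substr(hex, 6, 7)), 16L)
  a <- rgb_of(st$color[lo]); b <- rgb_of(st$color[hi])
  mixed <- floor(a + t * (b - a) + 0.5)  # round half up
  sprintf("#%02X%02X%02X", mixed[1], mixed[2], mixed[3])
}

# Resolve the value map against model ids per the missing policy. Unknown
# value ids error or are dropped; under "dim", model elements of the target
# class that carry no value are grayed out by the caller.
check_ids <- function(values, known, policy, what) {
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0 && policy == "error")
    stopf("value map names unknown %s id(s): %s", what,
          paste(unknown, collapse = ", "))
  list(values = values[setdiff(names(values), unknown)],
       dim_ids = if (policy == "dim") setdiff(known, names(values)) else character())
}

# Install the overlay gradient's stop colors in the render block (named
# color definitions) so the document stays self-contained.
ensure_gradient <- function(doc, gradient) {
  st <- gradient$stops
  cids <- character(nrow(st))
  for (i in seq_len(nrow(st))) {
    cid <- sprintf("%s_stop%d", gradient$gradient_id, i)
    doc$render$colors[[cid]] <- st$color[i]
    cids[i] <- cid
  }
  g <- gradient
  g$stops$color_id <- cids
  doc$render$gradients[[gradient$gradient_id]] <- g
  doc
}

#' Overlay reaction values (fluxes) onto the diagram
#'
#' Color channel: each reaction's curve stroke is set to the gradient color
#' of its normalized value. Width channel: the stroke width is scaled
#' linearly into `out_range`. Both are written as id-selector overrides on
#' the reaction glyph and its species-reference glyphs, so the base template
#' styles are preserved and removing the overrides restores them.
#'
#' @param doc a `sbml_document` with layout and render data
#' @param values named numeric vector: reaction id -> flux
#' @param spec an [overlay_spec()] with `target = "reactions"`
#' @return the updated document
#' @export
overlay_reaction_values <- function(doc, values, spec = overlay_spec("reactions", "color")) {
  if (is.null(doc$layout) || is.null(doc$render))
    stopf("document needs layout and render data (run build_layout + default_render)")
  if (spec$target != "reactions") stopf("spec target must be 'reactions'")
  rxn_ids <- vapply(doc$model$reactions, function(r) r$id, character(1))
  chk <- check_ids(values, rxn_ids, spec$missing_policy, "reaction")
  kept <- chk$values
  els <- layout_elements(doc$layout)
  # reaction id -> its glyph id plus all species-reference glyph ids
  gid_map <- list()
  for (rg in doc$layout$reaction_glyphs) {
    gid_map[[rg$reaction_id]] <-
      c(gid_map[[rg$reaction_id]], rg$glyph_id,
        vapply(rg$reference_glyphs, function(x) x$glyph_id, character(1)))
  }
  for (rid in chk$dim_ids) {
    gids <- gid_map[[rid]]
    if (length(gids) > 0) doc <- batch_set(doc, gids, "stroke", "#CCCCCC", els)
  }
  if (length(kept) == 0) return(doc)
  vr <- spec$value_range
  if (spec$symmetric && is.null(vr)) vr <- c(-1, 1) * max(abs(kept))
  fr <- normalize_values(kept, vr)
  if (spec$channel == "color") doc <- ensure_gradient(doc, spec$gradient)
  for (rid in names(fr)) {
    gids <- gid_map[[rid]]
    if (length(gids) == 0) next
    if (spec$channel == "color") {
      doc <- batch_set(doc, gids, "stroke",
                       value_to_color(fr[[rid]], spec$gradient), els)
    } else if (spec$channel == "width") {
      w <- spec$out_range[1] + fr[[rid]] * (spec$out_range[2] - spec$out_range[1])
      doc <- batch_set(doc, gids, "stroke_width", w, els)
    } else stopf("channel '%s' does not apply to reactions", spec$channel)
  }
  doc
}

#' Overlay species values (concentrations) onto the diagram
#'
#' Color channel: the fill of every alias glyph of the species is set
#' identically to the gradient color. Size channel: each species glyph's
#' bounding box is rescaled about its center to
#' `out_min + fraction * (out_max - out_min)` times the default node width
#' (aspect preserved) and incident curves are re-attached to the new
#' boundary.
#'
#' @param doc a `sbml_document` with layout and render data
#' @param values named numeric vector: species id -> concentration
#' @param spec an [overlay_spec()] with `target = "species"`
#' @return the updated document
#' @export
overlay_species_values <- function(doc, values, spec = overlay_spec("species", "color")) {
  if (is.null(doc$layout) || is.null(doc$render))
    stopf("document needs layout and render data (run build_layout + default_render)")
  if (spec$target != "species") stopf("spec target must be 'species'")
  chk <- check_ids(values, doc$model$species$id, spec$missing_policy, "species")
  kept <- chk$values
  els <- layout_elements(doc$layout)
  # species id -> ids of all its alias glyphs
  gid_map <- list()
  for (g in doc$layout$species_glyphs) {
    if (!is.na(g$species_id))
      gid_map[[g$species_id]] <- c(gid_map[[g$species_id]], g$glyph_id)
  }
  for (sid in chk$dim_ids) {
    gids <- gid_map[[sid]]
    if (length(gids) > 0) doc <- batch_set(doc, gids, "fill", "#CCCCCC", els)
  }
  if (length(kept) == 0) return(doc)
  vr <- spec$value_range
  if (spec$symmetric && is.null(vr)) vr <- c(-1, 1) * max(abs(kept))
  fr <- normalize_values(kept, vr)
  if (spec$channel == "color") doc <- ensure_gradient(doc, spec$gradient)
  for (sid in names(fr)) {
    gids <- gid_map[[sid]]
    if (length(gids) == 0) next
    if (spec$channel == "color") {
      doc <- batch_set(doc, gids, "fill",
                       value_to_color(fr[[sid]], spec$gradient), els)
    } else if (spec$channel == "size") {
      scale <- spec$out_range[1] + fr[[sid]] * (spec$out_range[2] - spec$out_range[1])
      for (gid in gids) {
        g <- find_species_glyph(doc$layout, gid)
        center <- bbox_center(g$bbox)
        new_w <- DEFAULT_SPECIES_W * scale
        new_h <- g$bbox[4] * new_w / g$bbox[3]
        doc <- move_species_glyph(doc, gid, center,
                                  new_size = c(new_w, new_h))
      }
    } else stopf("channel '%s' does not apply to species", spec$channel)
  }
  doc
}

#' Color bar specification
#'
#' @param position top-left corner `(x, y)` in layout pt
#' @param size `(width, height)` in pt
#' @param orientation `"vertical"` or `"horizontal"`
#' @param tick_count number of tick labels (>= 2, linearly spaced)
#' @param label_format sprintf format for tick labels
#' @export
colorbar_spec <- function(position = c(20, 20), size = c(20, 160),
                          orientation = c("vertical", "horizontal"),
                          tick_count = 5L, label_format = "%g") {
  orientation <- match.arg(orientation)
  if (tick_count < 2) stopf("tick_count must be >= 2")
  list(position = position, size = size, orientation = orientation,
       tick_count = as.integer(tick_count), label_format = label_format)
}

#' Add a color bar for a gradient encoding
#'
#' Adds a gradient-filled rectangle as an additional graphical object plus
#' `tick_count` text glyphs labeled by linear interpolation of
#' `value_range`. Everything is stored as ordinary layout and render
#' elements, so the bar round-trips through write/read with the document.
#' The highest value sits at the top of a vertical bar (at the right of a
#' horizontal one).
#'
#' @param doc a `sbml_document` with a layout
#' @param gradient a [new_gradient()]
#' @param value_range numeric `(vmin, vmax)`
#' @param bar a [colorbar_spec()]
#' @return the updated document
#' @export
add_colorbar <- function(doc, gradient = default_gradient(),
                         value_range = c(0, 1), bar = colorbar_spec()) {
  if (is.null(doc$layout)) stopf("document has no layout")
  if (value_range[1] > value_range[2]) stopf("vmin must be <= vmax")
  if (is.null(doc$render)) doc <- default_render(doc)
  doc <- ensure_gradient(doc, gradient)
  bid <- "colorbar"
  k <- 0L
  existing <- vapply(doc$layout$extra_glyphs, function(g) g$glyph_id, character(1))
  while (paste0(bid, if (k > 0) k else "") %in% existing) k <- k + 1L
  bid <- paste0(bid, if (k > 0) k else "")
  bbox <- c(bar$position[1], bar$position[2], bar$size[1], bar$size[2])
  doc$layout$extra_glyphs[[length(doc$layout$extra_glyphs) + 1]] <-
    new_extra_glyph(bid, bbox, metaid = paste0("colorbar_", bid))
  doc$render$styles[[length(doc$render$styles) + 1]] <-
    new_style(paste0("style_", bid),
              new_group(stroke = "#000000", stroke_width = 1,
                        fill = gradient$gradient_id,
                        primitives = list(prim_rectangle())),
              id_list = bid)
  ticks <- seq(0, 1, length.out = bar$tick_count)
  for (i in seq_along(ticks)) {
    v <- value_range[1] + ticks[i] * (value_range[2] - value_range[1])
    label <- sprintf(bar$label_format, v)
    if (bar$orientation == "vertical") {
      # fraction 0 (vmin) at the bottom
      ty <- bbox[2] + (1 - ticks[i]) * bbox[4] - 7
      tb <- c(bbox[1] + bbox[3] + 4, ty, 40, 14)
    } else {
      tx <- bbox[1] + ticks[i] * bbox[3] - 20
      tb <- c(tx, bbox[2] + bbox[4] + 4, 40, 14)
    }
    doc$layout$text_glyphs[[length(doc$layout$text_glyphs) + 1]] <-
      new_text_glyph(sprintf("%s_tick%d", bid, i), bid, label, tb)
  }
  doc$layout <- fit_dimensions(doc$layout, 10)
  doc
}

#' Read a delimited value map (id, value)
#'
#' Expects a header `id,value` (comma or tab, auto-detected); lines starting
#' with `#` are ignored.
#'
#' @param path file path
#' @return named numeric vector
#' @export
read_value_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1) stopf("value map file '%s' is empty", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("value map must have two columns (id, value)")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
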