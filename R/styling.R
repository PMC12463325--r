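# Style generation and editing: named HTML colors, the default style set,
# SBGN Process Description and Escher-like templates, effective-style
# resolution (cascade), dynamic selection and batch editing.

# Render typeList vocabulary used by this package.
TYPE_VOCAB <- c(compartment = "COMPARTMENTGLYPH", species = "SPECIESGLYPH",
                reaction = "REACTIONGLYPH", speciesreference = "SPECIESREFERENCEGLYPH",
                text = "TEXTGLYPH", graphicalobject = "GRAPHICALOBJECT")

STYLE_ATTRS <- c("stroke", "stroke_width", "fill", "font_family", "font_size",
                 "text_anchor", "start_head", "end_head")

#' Resolve an HTML color name or hex string to canonical hex
#'
#' Case-insensitive lookup over the 148 standard HTML color names; hex input
#' ("#rrggbb" or "#rrggbbaa") is normalized to uppercase. Unknown names raise
#' an error listing the nearest matches.
#'
#' @param name a color name (e.g. "white") or hex string (e.g. "#ff0000")
#' @return canonical hex string "#RRGGBB" (or "#RRGGBBAA")
#' @export
resolve_color <- function(name) {
  if (length(name) != 1 || is.na(name)) stopf("color must be a single string")
  if (grepl("^#", name)) {
    up <- toupper(name)
    if (!grepl("^#[0-9A-F]{6}([0-9A-F]{2})?$", up))
      stopf("'%s' is not a valid hex color", name)
    return(up)
  }
  if (identical(name, "none")) return("none")
  key <- tolower(name)
  if (key %in% names(HTML_COLORS)) return(unname(HTML_COLORS[[key]]))
  dists <- utils::adist(key, names(HTML_COLORS))
  near <- names(HTML_COLORS)[order(dists)][1:3]
  stopf("unknown color name '%s'; nearest matches: %s", name,
        paste(near, collapse = ", "))
}

# ---- line ending library ---------------------------------------------------

ending_arrow_filled <- function(color = "#000000") {
  new_line_ending("arrow_filled", c(-12, -6, 12, 12),
                  new_group(stroke = color, stroke_width = 1, fill = color,
                            primitives = list(prim_polygon(rbind(c(0, 0), c(1, 0.5), c(0, 1))))))
}
ending_arrow_open <- function(color = "#000000") {
  new_line_ending("arrow_open", c(-12, -6, 12, 12),
                  new_group(stroke = color, stroke_width = 1, fill = "#FFFFFF",
                            primitives = list(prim_polygon(rbind(c(0, 0), c(1, 0.5), c(0, 1))))))
}
ending_bar <- function(color = "#000000") {
  new_line_ending("bar_head", c(-2, -8, 4, 16),
                  new_group(stroke = color, stroke_width = 1, fill = color,
                            primitives = list(prim_rectangle(0.35, 0, 0.3, 1))))
}
ending_circle_open <- function(color = "#000000") {
  new_line_ending("circle_open", c(-10, -5, 10, 10),
                  new_group(stroke = color, stroke_width = 1, fill = "#FFFFFF",
                            primitives = list(prim_ellipse(0.5, 0.5, 0.5, 0.5))))
}
ending_diamond_open <- function(color = "#000000") {
  new_line_ending("diamond_open", c(-12, -6, 12, 12),
                  new_group(stroke = color, stroke_width = 1, fill = "#FFFFFF",
                            primitives = list(prim_polygon(rbind(c(0, 0.5), c(0.5, 0),
                                                                 c(1, 0.5), c(0.5, 1))))))
}

default_endings <- function() {
  le <- list(ending_arrow_filled(), ending_arrow_open(), ending_bar(),
             ending_circle_open(), ending_diamond_open())
  stats::setNames(le, vapply(le, function(x) x$ending_id, character(1)))
}

#' Attach the default render information to a laid-out document
#'
#' Builds a fresh render block with role-based styles for all
#' species-reference roles (product arcs end in a filled triangle, inhibitors
#' in a bar, activators in an open circle), type-based styles for species
#' (rounded rectangle), reactions, compartments (thin-stroked rectangle) and
#' text (centered), plus a catch-all default, so every layout element is
#' matched by at least one style. Calling it again replaces the block.
#'
#' @param doc a `sbml_document` with a layout
#' @return the document with render information
#' @export
default_render <- function(doc) {
  if (is.null(doc$layout)) stopf("document has no layout; run build_layout() first")
  r <- new_render("render1", "#FFFFFF")
  r$colors <- list(black = "#000000", white = "#FFFFFF",
                   species_fill = "#FFE699", species_stroke = "#B38B00",
                   compartment_stroke = "#808080")
  r$line_endings <- default_endings()
  s <- list()
  line <- function(..., width = 2) new_group(stroke = "black", stroke_width = width, ...)
  s[["role_substrate"]] <- new_style("role_substrate", line(),
                                     role_list = c("substrate", "side-substrate"))
  s[["role_product"]] <- new_style("role_product", line(end_head = "arrow_filled"),
                                   role_list = c("product", "side-product"))
  s[["role_modifier"]] <- new_style("role_modifier", line(width = 1.5),
                                    role_list = "modifier")
  s[["role_activator"]] <- new_style("role_activator",
                                     line(width = 1.5, end_head = "circle_open"),
                                     role_list = "activator")
  s[["role_inhibitor"]] <- new_style("role_inhibitor",
                                     line(width = 1.5, end_head = "bar_head"),
                                     role_list = "inhibitor")
  s[["role_undefined"]] <- new_style("role_undefined", line(width = 1),
                                     role_list = "undefined")
  s[["type_species"]] <- new_style(
    "type_species",
    new_group(stroke = "species_stroke", stroke_width = 1.5, fill = "species_fill",
              primitives = list(prim_rectangle(rx = 0.15, ry = 0.25))),
    type_list = "SPECIESGLYPH")
  s[["type_reaction"]] <- new_style(
    "type_reaction",
    new_group(stroke = "black", stroke_width = 2, fill = "white",
              primitives = list(prim_ellipse())),
    type_list = "REACTIONGLYPH")
  s[["type_compartment"]] <- new_style(
    "type_compartment",
    new_group(stroke = "compartment_stroke", stroke_width = 1, fill = "none",
              primitives = list(prim_rectangle(rx = 0.02, ry = 0.02))),
    type_list = "COMPARTMENTGLYPH")
  s[["type_text"]] <- new_style(
    "type_text",
    new_group(stroke = "black", font_family = "sans-serif", font_size = 11,
              text_anchor = "middle", primitives = list(prim_text())),
    type_list = "TEXTGLYPH")
  s[["type_graphical"]] <- new_style(
    "type_graphical",
    new_group(stroke = "black", stroke_width = 1.5, fill = "white",
              primitives = list(prim_ellipse(),
                                prim_curve(rbind(c(0.85, 0.0), c(0.15, 1.0))))),
    type_list = "GRAPHICALOBJECT")
  s[["default"]] <- new_style("default",
                              new_group(stroke = "black", stroke_width = 1),
                              type_list = "ANY")
  r$styles <- unname(s)
  doc$render <- r
  doc
}

# ---- SBGN Process Description ----------------------------------------------

SBGN_CLASSES <- c("macromolecule", "simple-chemical", "nucleic-acid-feature",
                  "complex", "source-and-sink", "process", "association",
                  "dissociation", "compartment", "consumption", "production",
                  "catalysis", "inhibition", "stimulation", "modulation")

#' Style recipe for an SBGN Process Description class
#'
#' Returns the prescribed glyph or arc styling for the supported PD subset:
#' macromolecule = rounded rectangle, simple chemical = ellipse, complex =
#' cut-corner octagon, source-and-sink = circle with a diagonal bar, process
#' = small square, production = filled-triangle end head, catalysis =
#' open-circle head, inhibition = bar head, stimulation = open-triangle head,
#' modulation = open-diamond head.
#'
#' @param cls one of the supported SBGN PD classes (see `SBGN_CLASSES`)
#' @return a list with `group` (a render group) and, for arc classes,
#'   `end_head` (the line ending id it requires)
#' @export
sbgn_style_for_class <- function(cls) {
  if (!(cls %in% SBGN_CLASSES))
    stopf("SBGN class '%s' is not supported (supported: %s)", cls,
          paste(SBGN_CLASSES, collapse = ", "))
  node <- function(prims, fill = "#FFFFFF", width = 1.5)
    list(group = new_group(stroke = "#000000", stroke_width = width,
                           fill = fill, primitives = prims))
  arc <- function(end_head = NULL, width = 1.5)
    list(group = new_group(stroke = "#000000", stroke_width = width,
                           end_head = end_head),
         end_head = end_head)
  oct <- rbind(c(0.15, 0), c(0.85, 0), c(1, 0.25), c(1, 0.75),
               c(0.85, 1), c(0.15, 1), c(0, 0.75), c(0, 0.25))
  switch(cls,
    "macromolecule" = node(list(prim_rectangle(rx = 0.1, ry = 0.25)), fill = "#C4E4C4"),
    "simple-chemical" = node(list(prim_ellipse()), fill = "#D9F2FA"),
    "nucleic-acid-feature" = node(list(prim_rectangle(rx = 0, ry = 0.3)), fill = "#E6E6FA"),
    "complex" = node(list(prim_polygon(oct)), fill = "#F0E0D0"),
    "source-and-sink" = node(list(prim_ellipse(),
                                  prim_curve(rbind(c(0.85, 0.0), c(0.15, 1.0))))),
    "process" = node(list(prim_rectangle(0, 0, 1, 1)), fill = "#FFFFFF"),
    "association" = node(list(prim_ellipse()), fill = "#000000"),
    "dissociation" = node(list(prim_ellipse(),
                               prim_ellipse(0.5, 0.5, 0.3, 0.3))),
    "compartment" = node(list(prim_rectangle(rx = 0.05, ry = 0.05)),
                         fill = "none", width = 3),
    "consumption" = arc(),
    "production" = arc("arrow_filled"),
    "catalysis" = arc("circle_open"),
    "inhibition" = arc("bar_head"),
    "stimulation" = arc("arrow_open"),
    "modulation" = arc("diamond_open"))
}

# SBGN class of a layout element: explicit class annotation on the model
# element -> SBO term mapping -> fallback by glyph type/role.
sbgn_class_of <- function(doc, el) {
  m <- doc$model
  if (el$type == "species") {
    sid <- el$element$species_id
    if (is.na(sid)) return("source-and-sink")
    i <- match(sid, m$species$id)
    cls <- if ("sbgn_class" %in% names(m$species)) m$species$sbgn_class[i] else NA
    if (!is.na(cls) && nzchar(cls)) return(cls)
    sbo <- if ("sbo" %in% names(m$species)) m$species$sbo[i] else NA
    if (!is.na(sbo)) {
      map <- c("SBO:0000245" = "macromolecule", "SBO:0000247" = "simple-chemical",
               "SBO:0000250" = "nucleic-acid-feature", "SBO:0000253" = "complex",
               "SBO:0000291" = "source-and-sink")
      if (sbo %in% names(map)) return(unname(map[[sbo]]))
    }
    return("macromolecule")
  }
  if (el$type == "reaction") return("process")
  if (el$type == "compartment") return("compartment")
  if (el$type == "graphicalobject") return("source-and-sink")
  if (el$type == "speciesreference") {
    return(switch(el$role,
                  "substrate" = , "side-substrate" = "consumption",
                  "product" = , "side-product" = "production",
                  "activator" = "stimulation",
                  "inhibitor" = "inhibition",
                  "modifier" = "catalysis",
                  "consumption"))
  }
  NA_character_
}

# ---- templates -------------------------------------------------------------

TEMPLATE_NAMES <- c("default", "sbgn-pd", "escher")

#' Apply a predefined style template
#'
#' Replaces the document's render information with the template's styles.
#' `"default"` is the standard style set of [default_render()]; `"sbgn-pd"`
#' resolves each element's SBGN Process Description class (explicit class
#' annotation, then SBO term, then glyph-type fallback) through
#' [sbgn_style_for_class()] and styles it accordingly; `"escher"` applies
#' thick colored reaction curves, bold labels, circular species nodes and
#' mid-weight filled arrowheads, in the manner of metabolic-map drawings.
#' A template loaded from a JSON file via [load_template()] can be passed
#' instead of a name.
#'
#' @param doc a `sbml_document` with a layout
#' @param template one of `"default"`, `"sbgn-pd"`, `"escher"`, or a
#'   template object from [load_template()]
#' @return the restyled document
#' @export
apply_template <- function(doc, template) {
  if (is.null(doc$layout)) stopf("document has no layout; run build_layout() first")
  if (is.list(template)) return(apply_custom_template(doc, template))
  if (!(template %in% TEMPLATE_NAMES))
    stopf("unknown template '%s'; available templates: %s", template,
          paste(TEMPLATE_NAMES, collapse = ", "))
  switch(template,
         "default" = default_render(doc),
         "sbgn-pd" = apply_sbgn_template(doc),
         "escher" = apply_escher_template(doc))
}

apply_sbgn_template <- function(doc) {
  r <- new_render("render_sbgn", "#FFFFFF")
  r$line_endings <- default_endings()
  els <- layout_elements(doc$layout)
  # one style per SBGN class actually present, selecting elements by id
  by_class <- list()
  for (id in names(els)) {
    cls <- sbgn_class_of(doc, els[[id]])
    if (is.na(cls)) cls <- "macromolecule"
    by_class[[cls]] <- c(by_class[[cls]], id)
  }
  styles <- list()
  for (cls in names(by_class)) {
    recipe <- sbgn_style_for_class(cls)
    styles[[length(styles) + 1]] <- new_style(
      paste0("sbgn_", gsub("-", "_", cls)), recipe$group,
      id_list = by_class[[cls]])
  }
  # text glyphs and the catch-all default
  styles[[length(styles) + 1]] <- new_style(
    "sbgn_label",
    new_group(stroke = "#000000", font_family = "sans-serif", font_size = 11,
              text_anchor = "middle", primitives = list(prim_text())),
    type_list = "TEXTGLYPH")
  styles[[length(styles) + 1]] <- new_style(
    "default", new_group(stroke = "#000000", stroke_width = 1),
    type_list = "ANY")
  r$styles <- styles
  doc$render <- r
  doc
}

apply_escher_template <- function(doc) {
  r <- new_render("render_escher", "#FFFFFF")
  r$colors <- list(curve = "#334E75", label = "#1F2A44", node_fill = "#B6C2D9")
  le <- ending_arrow_filled("#334E75")
  r$line_endings <- stats::setNames(list(le), le$ending_id)
  s <- list()
  s[[1]] <- new_style("escher_substrate",
                      new_group(stroke = "curve", stroke_width = 9),
                      role_list = c("substrate", "side-substrate"))
  s[[2]] <- new_style("escher_product",
                      new_group(stroke = "curve", stroke_width = 9,
                                end_head = "arrow_filled"),
                      role_list = c("product", "side-product"))
  s[[3]] <- new_style("escher_modifier",
                      new_group(stroke = "curve", stroke_width = 4),
                      role_list = c("modifier", "activator", "inhibitor", "undefined"))
  s[[4]] <- new_style("escher_species",
                      new_group(stroke = "curve", stroke_width = 2, fill = "node_fill",
                                primitives = list(prim_ellipse())),
                      type_list = "SPECIESGLYPH")
  s[[5]] <- new_style("escher_reaction",
                      new_group(stroke = "curve", stroke_width = 2, fill = "#FFFFFF",
                                primitives = list(prim_ellipse())),
                      type_list = "REACTIONGLYPH")
  s[[6]] <- new_style("escher_compartment",
                      new_group(stroke = "#D0D0D0", stroke_width = 1, fill = "none",
                                primitives = list(prim_rectangle(rx = 0.02, ry = 0.02))),
                      type_list = "COMPARTMENTGLYPH")
  s[[7]] <- new_style("escher_label",
                      new_group(stroke = "label", font_family = "sans-serif",
                                font_size = 20, text_anchor = "middle",
                                primitives = list(prim_text())),
                      type_list = "TEXTGLYPH")
  s[[8]] <- new_style("default", new_group(stroke = "curve", stroke_width = 1),
                      type_list = "ANY")
  r$styles <- s
  doc$render <- r
  doc
}

#' Load a style template from a JSON config file
#'
#' The file holds `{name, defaults{...}, class_styles{...}}` where each class
#' style maps a selector (a role, a glyph type from the Render vocabulary, or
#' "ANY") to style attributes (`stroke`, `stroke_width`, `fill`,
#' `font_family`, `font_size`, `text_anchor`, `start_head`, `end_head`) and
#' an optional `shape` (`rectangle`, `ellipse`).
#'
#' @param path path to a JSON file
#' @return a template object for [apply_template()]
#' @export
load_template <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stopf("loading JSON templates requires the jsonlite package")
  tpl <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(tpl$name)) stopf("template file must have a 'name' field")
  tpl
}

apply_custom_template <- function(doc, tpl) {
  r <- new_render(paste0("render_", tpl$name),
                  resolve_color(tpl$defaults$background %||% "#FFFFFF"))
  r$line_endings <- default_endings()
  styles <- list()
  cs <- tpl$class_styles
  for (sel in names(cs)) {
    a <- cs[[sel]]
    prims <- if (!is.null(a$shape)) {
      switch(a$shape,
             rectangle = list(prim_rectangle(rx = 0.1, ry = 0.1)),
             ellipse = list(prim_ellipse()),
             list())
    } else list()
    g <- new_group(stroke = if (!is.null(a$stroke)) resolve_color(a$stroke),
                   stroke_width = a$stroke_width,
                   fill = if (!is.null(a$fill)) resolve_color(a$fill),
                   font_family = a$font_family,
                   font_size = a$font_size, text_anchor = a$text_anchor,
                   start_head = a$start_head, end_head = a$end_head,
                   primitives = prims)
    if (sel %in% ROLES)
      styles[[length(styles) + 1]] <- new_style(paste0("tpl_", sel), g, role_list = sel)
    else
      styles[[length(styles) + 1]] <- new_style(paste0("tpl_", sel), g, type_list = sel)
  }
  styles[[length(styles) + 1]] <- new_style(
    "default", new_group(stroke = "#000000", stroke_width = 1), type_list = "ANY")
  r$styles <- styles
  doc$render <- r
  doc
}

# ---- effective-style resolution (cascade) ----------------------------------

# Precedence: id-selector > role-selector > type-selector > default (ANY).
# Within a precedence level, the later style in the list wins. Attributes
# absent at one level fall through to the next.
style_precedence <- function(style, element_id, type, role) {
  if (element_id %in% style$id_list) return(4L)
  if (!is.null(role) && role %in% style$role_list) return(3L)
  if (TYPE_VOCAB[[type]] %in% style$type_list) return(2L)
  if ("ANY" %in% style$type_list) return(1L)
  0L
}

# Inverted index over the style list: element id / role / type -> style
# indices. Avoids scanning every style's selector lists per element when
# resolving the cascade over large documents.
style_index <- function(doc) {
  by_id <- new.env(hash = TRUE, parent = emptyenv())
  by_role <- new.env(hash = TRUE, parent = emptyenv())
  by_type <- new.env(hash = TRUE, parent = emptyenv())
  any_idx <- integer()
  styles <- doc$render$styles
  for (i in seq_along(styles)) {
    s <- styles[[i]]
    for (id in s$id_list) by_id[[id]] <- c(by_id[[id]], i)
    for (r in s$role_list) by_role[[r]] <- c(by_role[[r]], i)
    for (tp in s$type_list) {
      if (tp == "ANY") any_idx <- c(any_idx, i)
      else by_type[[tp]] <- c(by_type[[tp]], i)
    }
  }
  list(by_id = by_id, by_role = by_role, by_type = by_type, any = any_idx)
}

#' Effective (post-cascade) style of a layout element
#'
#' Resolves the style cascade for one element: id-selector styles override
#' role-selector styles, which override type-selector styles, which override
#' the catch-all default. Attributes a higher-precedence style leaves unset
#' are inherited from lower precedence.
#'
#' @param doc a `sbml_document` with layout and render data
#' @param element_id a layout element id
#' @param els optional precomputed [layout_elements()] (performance)
#' @param idx optional precomputed style index (performance)
#' @return a render group with the effective attributes
#' @export
effective_style <- function(doc, element_id, els = NULL, idx = NULL) {
  if (is.null(doc$render)) stopf("document has no render information")
  if (is.null(els)) els <- layout_elements(doc$layout)
  el <- els[[element_id]]
  if (is.null(el)) stopf("unknown layout element '%s'", element_id)
  if (is.null(idx)) {
    prec <- vapply(doc$render$styles, style_precedence, integer(1),
                   element_id = element_id, type = el$type, role = el$role %||% NULL)
    cand <- which(prec > 0)
    ord <- cand[order(prec[cand], cand, decreasing = TRUE)]
  } else {
    # a style matching at several levels is listed at each; the cascade
    # merge makes duplicates harmless (its attributes are already set by
    # the time the lower level is reached)
    cand <- c(idx$by_id[[element_id]],
              if (!is.null(el$role)) idx$by_role[[el$role]],
              idx$by_type[[TYPE_VOCAB[[el$type]]]],
              idx$any)
    lev <- rep.int(4:1, c(length(idx$by_id[[element_id]]),
                          length(if (!is.null(el$role)) idx$by_role[[el$role]]),
                          length(idx$by_type[[TYPE_VOCAB[[el$type]]]]),
                          length(idx$any)))
    ord <- cand[order(lev, cand, decreasing = TRUE)]
  }
  out <- new_group()
  for (i in ord) {
    g <- doc$render$styles[[i]]$group
    for (a in c(STYLE_ATTRS))
      if (is.null(out[[a]]) && !is.null(g[[a]])) out[[a]] <- g[[a]]
    if (length(out$primitives) == 0 && length(g$primitives) > 0)
      out$primitives <- g$primitives
  }
  # resolve named colors to hex for comparison stability
  for (a in c("stroke", "fill")) {
    v <- out[[a]]
    if (!is.null(v) && !grepl("^#", v) && v != "none") {
      if (v %in% names(doc$render$colors)) out[[a]] <- doc$render$colors[[v]]
      else if (v %in% names(doc$render$gradients)) out[[a]] <- v
      else out[[a]] <- tryCatch(resolve_color(v), error = function(e) v)
    }
  }
  out
}

#' Select layout elements by an effective style attribute
#'
#' @param doc a `sbml_document` with render data
#' @param attribute one of `stroke`, `stroke_width`, `fill`, `font_family`,
#'   `font_size`, `text_anchor`, `start_head`, `end_head`
#' @param value the value to match (colors are compared in canonical hex)
#' @return character vector of matching element ids
#' @export
select_elements <- function(doc, attribute, value) {
  if (is.null(doc$render)) stopf("document has no render information")
  if (!(attribute %in% STYLE_ATTRS))
    stopf("unknown style attribute '%s' (known: %s)", attribute,
          paste(STYLE_ATTRS, collapse = ", "))
  if (attribute %in% c("stroke", "fill") && grepl("^#", value %||% ""))
    value <- toupper(value)
  els <- layout_elements(doc$layout)
  idx <- style_index(doc)
  hits <- character()
  for (id in names(els)) {
    g <- effective_style(doc, id, els, idx)
    v <- g[[attribute]]
    if (!is.null(v) && identical(as.character(v), as.character(value)))
      hits <- c(hits, id)
    else if (is.numeric(value) && !is.null(v) && isTRUE(all.equal(as.numeric(v), value)))
      hits <- c(hits, id)
  }
  hits
}

#' Batch-set a style attribute on multiple elements
#'
#' Each target element receives (or updates) an id-selector style that
#' overrides just the given attribute; all other attributes keep inheriting
#' from the previous effective style through the cascade. Removing the
#' override restores the prior rendering.
#'
#' @param doc a `sbml_document` with render data
#' @param element_ids layout element ids
#' @param attribute style attribute name (see [select_elements()])
#' @param value the new value; colors may be HTML names or hex
#' @param els optional precomputed [layout_elements()] (performance)
#' @return the updated document
#' @export
batch_set <- function(doc, element_ids, attribute, value, els = NULL) {
  if (is.null(doc$render)) stopf("document has no render information")
  if (!(attribute %in% STYLE_ATTRS))
    stopf("unknown style attribute '%s'", attribute)
  if (length(element_ids) == 0) return(doc)
  if (is.null(els)) els <- layout_elements(doc$layout)
  missing <- setdiff(element_ids, names(els))
  if (length(missing) > 0)
    stopf("unknown element id(s): %s", paste(missing, collapse = ", "))
  if (attribute %in% c("stroke", "fill") && !is.null(value))
    value <- resolve_color(value)
  if (attribute %in% c("stroke_width", "font_size") &&
      (!is.numeric(value) || value < 0))
    stopf("%s must be a non-negative number", attribute)
  style_ids <- vapply(doc$render$styles, function(s) s$style_id, character(1))
  for (id in element_ids) {
    sid <- paste0("override_", id)
    i <- match(sid, style_ids)
    if (!is.na(i)) {
      doc$render$styles[[i]]$group[[attribute]] <- value
    } else {
      g <- new_group()
      g[[attribute]] <- value
      doc$render$styles[[length(doc$render$styles) + 1]] <-
        new_style(sid, g, id_list = id)
      style_ids <- c(style_ids, sid)
    }
  }
  doc
}

#' Fraction of layout elements matched by at least one style
#'
#' @param doc a `sbml_document` with layout and render data
#' @return a number in [0, 1]; 1 means full coverage
#' @export
style_coverage <- function(doc) {
  els <- layout_elements(doc$layout)
  if (length(els) == 0) return(1)
  idx <- style_index(doc)
  matched <- vapply(names(els), function(id) {
    el <- els[[id]]
    length(idx$any) > 0 ||
      !is.null(idx$by_id[[id]]) ||
      (!is.null(el$role) && !is.null(idx$by_role[[el$role]])) ||
      !is.null(idx$by_type[[TYPE_VOCAB[[el$type]]]])
  }, logical(1))
  mean(matched)
}
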