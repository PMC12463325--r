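#' In-memory SBML document with optional layout and render data
#'
#' A `sbml_document` bundles a minimal SBML model (compartments, species,
#' reactions with reactant/product/modifier lists) together with optional
#' diagram data mirroring the SBML Level 3 Layout and Render packages. It is
#' the single unit that every operation in the package transforms.
#'
#' @param model a model as returned by [new_model()]
#' @param layout optional layout (see [new_layout()])
#' @param render optional render information; requires `layout`
#' @return an object of class `sbml_document`
#' @export
new_document <- function(model, layout = NULL, render = NULL) {
  if (!is.null(render) && is.null(layout))
    stopf("a document with render information must also carry a layout")
  structure(list(model = model, layout = layout, render = render),
            class = "sbml_document")
}

#' Construct a minimal SBML model
#'
#' @param id model identifier
#' @param compartments data.frame with columns `id`, `name`
#' @param species data.frame with columns `id`, `name`, `compartment`
#' @param reactions list of reactions from [new_reaction()]
#' @return a `sbml_model` list
#' @export
new_model <- function(id = "model",
                      compartments = data.frame(id = character(), name = character(),
                                                stringsAsFactors = FALSE),
                      species = data.frame(id = character(), name = character(),
                                           compartment = character(),
                                           stringsAsFactors = FALSE),
                      reactions = list()) {
  structure(list(id = id, compartments = compartments, species = species,
                 reactions = reactions), class = "sbml_model")
}

#' Construct a reaction
#'
#' Reactants, products and modifiers are given as data.frames keyed by species
#' id. Modifiers may carry an SBO term (e.g. "SBO:0000020" inhibitor,
#' "SBO:0000459" activator) or an annotation keyword that determines their
#' rendered role.
#'
#' @param id reaction identifier
#' @param reactants,products data.frame with columns `species`, `stoichiometry`
#' @param modifiers data.frame with columns `species`, `sbo`
#' @param name display name
#' @param reversible logical
#' @export
new_reaction <- function(id, reactants = NULL, products = NULL, modifiers = NULL,
                         name = id, reversible = FALSE) {
  empty_part <- data.frame(species = character(), stoichiometry = numeric(),
                           stringsAsFactors = FALSE)
  empty_mod <- data.frame(species = character(), sbo = character(),
                          stringsAsFactors = FALSE)
  as_part <- function(x) {
    if (is.null(x)) return(empty_part)
    if (is.character(x)) x <- data.frame(species = x, stoichiometry = 1,
                                         stringsAsFactors = FALSE)
    if (is.null(x$stoichiometry)) x$stoichiometry <- rep(1, nrow(x))
    x
  }
  as_mod <- function(x) {
    if (is.null(x)) return(empty_mod)
    if (is.character(x)) x <- data.frame(species = x, sbo = NA_character_,
                                         stringsAsFactors = FALSE)
    if (is.null(x$sbo)) x$sbo <- rep(NA_character_, nrow(x))
    x
  }
  list(id = id, name = name, reversible = reversible,
       reactants = as_part(reactants), products = as_part(products),
       modifiers = as_mod(modifiers))
}

# ---- layout types ----------------------------------------------------------

#' Construct an empty layout
#' @param layout_id identifier
#' @param width,height canvas dimensions in layout points
#' @export
new_layout <- function(layout_id = "layout1", width = 800, height = 600) {
  structure(list(layout_id = layout_id, width = width, height = height,
                 species_glyphs = list(), reaction_glyphs = list(),
                 compartment_glyphs = list(), text_glyphs = list(),
                 extra_glyphs = list()),
            class = "sbml_layout")
}

new_species_glyph <- function(glyph_id, species_id, bbox, alias_index = 0L) {
  list(glyph_id = glyph_id, species_id = species_id, bbox = bbox,
       alias_index = as.integer(alias_index))
}

new_reaction_glyph <- function(glyph_id, reaction_id, bbox,
                               reference_glyphs = list()) {
  list(glyph_id = glyph_id, reaction_id = reaction_id, bbox = bbox,
       reference_glyphs = reference_glyphs)
}

new_reference_glyph <- function(glyph_id, species_glyph_id, role,
                                curve = list()) {
  list(glyph_id = glyph_id, species_glyph_id = species_glyph_id,
       role = role, curve = curve)
}

new_compartment_glyph <- function(glyph_id, compartment_id, bbox) {
  list(glyph_id = glyph_id, compartment_id = compartment_id, bbox = bbox)
}

new_text_glyph <- function(glyph_id, target_glyph_id, text, bbox) {
  list(glyph_id = glyph_id, target_glyph_id = target_glyph_id,
       text = text, bbox = bbox)
}

new_extra_glyph <- function(glyph_id, bbox, metaid = glyph_id) {
  list(glyph_id = glyph_id, metaid = metaid, bbox = bbox)
}

# A cubic Bezier segment when bp1/bp2 are present, a line segment otherwise.
new_segment <- function(start, end, bp1 = NULL, bp2 = NULL) {
  if (is.null(bp1) != is.null(bp2))
    stopf("curve segment base points must be both present or both absent")
  list(start = start, end = end, bp1 = bp1, bp2 = bp2)
}

# ---- render types ----------------------------------------------------------

#' Construct empty render information
#' @param render_id identifier
#' @param background_color hex color for the canvas background
#' @export
new_render <- function(render_id = "render1", background_color = "#FFFFFF") {
  structure(list(render_id = render_id, background_color = background_color,
                 colors = list(), gradients = list(), line_endings = list(),
                 styles = list()),
            class = "sbml_render")
}

#' Construct a linear gradient
#' @param gradient_id identifier
#' @param stops data.frame with `offset` (fractions, first 0 and last 1,
#'   non-decreasing) and `color` (hex strings)
#' @export
new_gradient <- function(gradient_id, stops) {
  if (nrow(stops) < 2) stopf("gradient '%s' needs at least 2 stops", gradient_id)
  if (is.unsorted(stops$offset)) stopf("gradient stop offsets must be non-decreasing")
  if (stops$offset[1] != 0 || stops$offset[nrow(stops)] != 1)
    stopf("gradient stops must start at 0 and end at 1")
  stops$color <- vapply(stops$color, resolve_color, character(1))
  list(gradient_id = gradient_id, stops = stops)
}

new_line_ending <- function(ending_id, bbox, group, rotational_mapping = TRUE) {
  list(ending_id = ending_id, bbox = bbox, group = group,
       rotational_mapping = isTRUE(rotational_mapping))
}

new_group <- function(stroke = NULL, stroke_width = NULL, fill = NULL,
                      font_family = NULL, font_size = NULL, text_anchor = NULL,
                      start_head = NULL, end_head = NULL, primitives = list()) {
  list(stroke = stroke, stroke_width = stroke_width, fill = fill,
       font_family = font_family, font_size = font_size,
       text_anchor = text_anchor, start_head = start_head,
       end_head = end_head, primitives = primitives)
}

new_style <- function(style_id, group, role_list = character(),
                      type_list = character(), id_list = character()) {
  list(style_id = style_id, role_list = role_list, type_list = type_list,
       id_list = id_list, group = group)
}

# Render primitives; coordinates are fractions (0..1) of the owning bbox.
prim_rectangle <- function(x = 0, y = 0, w = 1, h = 1, rx = 0, ry = 0) {
  list(kind = "rectangle", x = x, y = y, w = w, h = h, rx = rx, ry = ry)
}
prim_ellipse <- function(cx = 0.5, cy = 0.5, rx = 0.5, ry = 0.5) {
  list(kind = "ellipse", cx = cx, cy = cy, rx = rx, ry = ry)
}
prim_polygon <- function(points) list(kind = "polygon", points = points)
prim_curve <- function(points) list(kind = "curve", points = points)
prim_text <- function(x = 0.5, y = 0.5) list(kind = "text", x = x, y = y)

# ---- traversal helpers -----------------------------------------------------

#' All layout elements as a flat named list
#'
#' @param layout the `layout` component of a `sbml_document`
#' @return named list: element id -> `list(type, element, role, reaction_glyph)`
#' @export
layout_elements <- function(layout) {
  out <- list()
  add <- function(glyphs, type) {
    for (g in glyphs) out[[g$glyph_id]] <<- list(type = type, element = g)
  }
  add(layout$compartment_glyphs, "compartment")
  add(layout$species_glyphs, "species")
  add(layout$reaction_glyphs, "reaction")
  for (rg in layout$reaction_glyphs)
    for (ref in rg$reference_glyphs)
      out[[ref$glyph_id]] <- list(type = "speciesreference", element = ref,
                                  role = ref$role, reaction_glyph = rg$glyph_id)
  add(layout$text_glyphs, "text")
  add(layout$extra_glyphs, "graphicalobject")
  out
}

find_species_glyph <- function(layout, glyph_id) {
  for (g in layout$species_glyphs) if (g$glyph_id == glyph_id) return(g)
  NULL
}

#' @export
print.sbml_document <- function(x, ...) {
  m <- x$model
  cat(sprintf("SBML document '%s': %d species, %d reactions, %d compartments\n",
              m$id, nrow(m$species), length(m$reactions), nrow(m$compartments)))
  if (!is.null(x$layout)) {
    l <- x$layout
    cat(sprintf("  layout %gx%g pt: %d species glyphs, %d reaction glyphs, %d text glyphs\n",
                l$width, l$height, length(l$species_glyphs),
                length(l$reaction_glyphs), length(l$text_glyphs)))
  } else cat("  no layout\n")
  if (!is.null(x$render))
    cat(sprintf("  render: %d styles, %d colors, %d line endings\n",
                length(x$render$styles), length(x$render$colors),
                length(x$render$line_endings)))
  else cat("  no render information\n")
  invisible(x)
}
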