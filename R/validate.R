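#' Validate a document's layout and render cross-references and invariants
#'
#' Checks every structural invariant of the layout and render data: glyph id
#' uniqueness, non-negative bounding boxes, finite coordinates, resolution of
#' all cross-references (species/reaction/compartment ids against the model,
#' species-reference glyphs against species glyphs, text targets, style color,
#' gradient and line-ending references), canonical hex colors and gradient
#' stop ordering. Issues are returned, never thrown, so the function can be
#' used as a post-condition on arbitrary content.
#'
#' @param doc a `sbml_document`
#' @return a data.frame with columns `severity`, `message`, `element_id`;
#'   zero rows iff the document is valid
#' @export
validate_layout <- function(doc) {
  issues <- list()
  add <- function(severity, message, element_id) {
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, message = message, element_id = element_id,
      stringsAsFactors = FALSE)
  }
  result <- function() {
    if (length(issues) == 0)
      return(data.frame(severity = character(), message = character(),
                        element_id = character(), stringsAsFactors = FALSE))
    do.call(rbind, issues)
  }

  layout <- doc$layout
  if (is.null(layout)) {
    if (!is.null(doc$render))
      add("error", "render information present without a layout", doc$render$render_id)
    return(result())
  }

  model <- doc$model
  check_bbox <- function(b, id) {
    if (!is.numeric(b) || length(b) != 4 || any(!is.finite(b)))
      add("error", "bounding box must be four finite numbers", id)
    else if (b[3] < 0 || b[4] < 0)
      add("error", sprintf("negative bounding box size (%g x %g)", b[3], b[4]), id)
  }

  id_env <- new.env(parent = emptyenv(), size = 4096L)
  all_ids <- character()
  seen <- function(id) {
    if (!is.null(id_env[[id]])) add("error", "duplicate glyph id", id)
    id_env[[id]] <- TRUE
    all_ids <<- c(all_ids, id)
  }

  sg_ids <- vapply(layout$species_glyphs, function(g) g$glyph_id, character(1))
  for (g in layout$species_glyphs) {
    seen(g$glyph_id); check_bbox(g$bbox, g$glyph_id)
    if (!is.na(g$species_id) && !(g$species_id %in% model$species$id))
      add("error", sprintf("species glyph references unknown species '%s'",
                           g$species_id), g$glyph_id)
    if (g$alias_index < 0)
      add("error", "alias index must be >= 0", g$glyph_id)
  }
  for (g in layout$compartment_glyphs) {
    seen(g$glyph_id); check_bbox(g$bbox, g$glyph_id)
    if (!(g$compartment_id %in% model$compartments$id))
      add("error", sprintf("compartment glyph references unknown compartment '%s'",
                           g$compartment_id), g$glyph_id)
  }
  for (rg in layout$reaction_glyphs) {
    seen(rg$glyph_id); check_bbox(rg$bbox, rg$glyph_id)
    rxn_ids <- vapply(model$reactions, function(r) r$id, character(1))
    if (!(rg$reaction_id %in% rxn_ids))
      add("error", sprintf("reaction glyph references unknown reaction '%s'",
                           rg$reaction_id), rg$glyph_id)
    for (ref in rg$reference_glyphs) {
      seen(ref$glyph_id)
      if (!(ref$species_glyph_id %in% sg_ids))
        add("error", sprintf("reference glyph points to unknown species glyph '%s'",
                             ref$species_glyph_id), ref$glyph_id)
      if (!(ref$role %in% ROLES))
        add("error", sprintf("unknown role '%s'", ref$role), ref$glyph_id)
      for (seg in ref$curve) {
        if (!is_finite_point(seg$start) || !is_finite_point(seg$end))
          add("error", "non-finite curve endpoint", ref$glyph_id)
        if (is.null(seg$bp1) != is.null(seg$bp2))
          add("error", "curve segment with exactly one base point", ref$glyph_id)
      }
    }
  }
  for (g in layout$extra_glyphs) {
    seen(g$glyph_id); check_bbox(g$bbox, g$glyph_id)
  }
  glyph_targets <- c(all_ids)
  for (g in layout$text_glyphs) {
    seen(g$glyph_id); check_bbox(g$bbox, g$glyph_id)
    if (!(g$target_glyph_id %in% glyph_targets))
      add("error", sprintf("text glyph targets unknown glyph '%s'",
                           g$target_glyph_id), g$glyph_id)
  }

  render <- doc$render
  if (!is.null(render)) {
    hex_re <- "^#[0-9A-F]{6}([0-9A-F]{2})?$"
    for (cid in names(render$colors)) {
      if (!grepl(hex_re, render$colors[[cid]]))
        add("error", sprintf("color value '%s' is not canonical hex",
                             render$colors[[cid]]), cid)
    }
    color_ids <- names(render$colors)
    grad_ids <- names(render$gradients)
    ending_ids <- names(render$line_endings)
    paint_ok <- function(v) {
      is.null(v) || v == "none" || grepl(hex_re, v) ||
        v %in% color_ids || v %in% grad_ids
    }
    for (g in render$gradients) {
      st <- g$stops
      if (nrow(st) < 2) add("error", "gradient with fewer than 2 stops", g$gradient_id)
      else {
        if (is.unsorted(st$offset) || st$offset[1] != 0 || st$offset[nrow(st)] != 1)
          add("error", "gradient stops must be non-decreasing from 0 to 1", g$gradient_id)
      }
    }
    for (le in render$line_endings) {
      if (length(le$group$primitives) < 1)
        add("error", "line ending group has no primitive", le$ending_id)
    }
    style_ids <- character()
    element_ids <- names(layout_elements(layout))
    for (s in render$styles) {
      if (s$style_id %in% style_ids) add("error", "duplicate style id", s$style_id)
      style_ids <- c(style_ids, s$style_id)
      g <- s$group
      if (!paint_ok(g$stroke))
        add("error", sprintf("stroke '%s' does not resolve", g$stroke), s$style_id)
      if (!paint_ok(g$fill))
        add("error", sprintf("fill '%s' does not resolve", g$fill), s$style_id)
      if (!is.null(g$stroke_width) && g$stroke_width < 0)
        add("error", "negative stroke width", s$style_id)
      for (h in c(g$start_head, g$end_head)) {
        if (!is.null(h) && h != "none" && !(h %in% ending_ids))
          add("error", sprintf("line ending '%s' does not resolve", h), s$style_id)
      }
      bad_ids <- setdiff(s$id_list, element_ids)
      for (id in bad_ids)
        add("error", sprintf("style id-selector references unknown element '%s'", id),
            s$style_id)
    }
  }
  result()
}
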