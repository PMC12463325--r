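# Post-layout geometric editing: horizontal/vertical alignment of single
# reactions, circular arrangement of reaction sets, and direct species
# moves with curve re-attachment.

#' Circular-arc specification
#'
#' Angles follow the pathway-map reading convention: 0 degrees points up
#' (12 o'clock) and positive angles run clockwise, in y-down screen
#' coordinates.
#'
#' @param center arc center `(x, y)` in layout pt
#' @param radius arc radius in pt (> 0)
#' @param start_angle first position, degrees
#' @param direction `"clockwise"` or `"counterclockwise"`
#' @param span arc span in degrees, in (0, 360]; 360 is a full circle
#' @export
arc_spec <- function(center = c(400, 300), radius = 200, start_angle = 0,
                     direction = c("clockwise", "counterclockwise"),
                     span = 360) {
  direction <- match.arg(direction)
  if (radius <= 0) stopf("radius must be > 0")
  if (span <= 0 || span > 360) stopf("span must be in (0, 360]")
  list(center = center, radius = radius, start_angle = start_angle,
       direction = direction, span = span)
}

# Rebuild a network-graph view of an existing layout, so curve generation
# can be reapplied after geometric edits. Node ids are the glyph ids.
layout_to_graph <- function(doc) {
  l <- doc$layout
  nodes <- list()
  compartment_of <- character()
  for (g in l$species_glyphs) {
    kind <- if (is.na(g$species_id)) "emptyset" else "species"
    nodes[[g$glyph_id]] <- new_network_node(g$glyph_id, kind,
                                            g$species_id, g$alias_index,
                                            w = g$bbox[3], h = g$bbox[4])
  }
  edges <- list()
  for (rg in l$reaction_glyphs) {
    nodes[[rg$glyph_id]] <- new_network_node(rg$glyph_id, "centroid",
                                             rg$reaction_id,
                                             w = rg$bbox[3], h = rg$bbox[4])
    for (ref in rg$reference_glyphs)
      edges[[ref$glyph_id]] <- new_network_edge(ref$glyph_id,
                                                ref$species_glyph_id,
                                                rg$glyph_id, ref$role)
  }
  pos <- matrix(0, nrow = length(nodes), ncol = 2,
                dimnames = list(names(nodes), c("x", "y")))
  for (g in c(l$species_glyphs, l$reaction_glyphs))
    pos[g$glyph_id, ] <- bbox_center(g$bbox)
  list(graph = structure(list(nodes = nodes, edges = edges,
                              compartment_of = compartment_of),
                         class = "network_graph"),
       pos = pos)
}

# Regenerate curves, then copy only the curves of the given reference glyph
# ids back into the layout (locality: everything else stays untouched).
refresh_curves <- function(doc, ref_ids) {
  lg <- layout_to_graph(doc)
  curves <- generate_curves(lg$graph, lg$pos, layout_params())
  for (i in seq_along(doc$layout$reaction_glyphs)) {
    rg <- doc$layout$reaction_glyphs[[i]]
    for (j in seq_along(rg$reference_glyphs)) {
      id <- rg$reference_glyphs[[j]]$glyph_id
      if (id %in% ref_ids && !is.null(curves[[id]]))
        doc$layout$reaction_glyphs[[i]]$reference_glyphs[[j]]$curve <- curves[[id]]
    }
  }
  doc
}

find_reaction_glyph_idx <- function(doc, reaction_id) {
  for (i in seq_along(doc$layout$reaction_glyphs))
    if (doc$layout$reaction_glyphs[[i]]$reaction_id == reaction_id) return(i)
  avail <- vapply(doc$layout$reaction_glyphs, function(g) g$reaction_id, character(1))
  stopf("unknown reaction '%s'; available reactions: %s", reaction_id,
        paste(avail, collapse = ", "))
}

# First substrate-role and product-role reference glyphs of a reaction glyph
# (the "main" pair; additional participants are side species).
main_refs <- function(rg) {
  sub <- NULL; prod <- NULL
  for (ref in rg$reference_glyphs) {
    if (is.null(sub) && is_substrate_role(ref$role)) sub <- ref
    if (is.null(prod) && is_product_role(ref$role)) prod <- ref
  }
  if (is.null(sub) || is.null(prod))
    stopf("reaction glyph '%s' lacks a substrate or product to align", rg$glyph_id)
  list(sub = sub, prod = prod)
}

set_species_center <- function(doc, glyph_id, center) {
  for (i in seq_along(doc$layout$species_glyphs)) {
    g <- doc$layout$species_glyphs[[i]]
    if (g$glyph_id != glyph_id) next
    doc$layout$species_glyphs[[i]]$bbox <- bbox_from_center(center, g$bbox[3], g$bbox[4])
    for (j in seq_along(doc$layout$text_glyphs)) {
      t <- doc$layout$text_glyphs[[j]]
      if (t$target_glyph_id == glyph_id)
        doc$layout$text_glyphs[[j]]$bbox <- bbox_from_center(center, t$bbox[3], t$bbox[4])
    }
    return(doc)
  }
  stopf("unknown species glyph '%s'", glyph_id)
}

#' Align a reaction horizontally or vertically
#'
#' Moves the main substrate and main product (the first listed of each) onto
#' a horizontal (equal y) or vertical (equal x) line through the reaction
#' centroid, preserving the current substrate-product chord length. The
#' substrate lands left (horizontal) or on top (vertical). Side species and
#' modifiers are re-fanned by the standard curve rules; only this reaction's
#' curves are regenerated.
#'
#' @param doc a `sbml_document` with a layout
#' @param reaction_id the reaction to align
#' @param orientation `"horizontal"` or `"vertical"`
#' @return the updated document
#' @export
align_reaction <- function(doc, reaction_id,
                           orientation = c("horizontal", "vertical")) {
  if (is.null(doc$layout)) stopf("document has no layout")
  orientation <- match.arg(orientation)
  i <- find_reaction_glyph_idx(doc, reaction_id)
  rg <- doc$layout$reaction_glyphs[[i]]
  mr <- main_refs(rg)
  sg <- find_species_glyph(doc$layout, mr$sub$species_glyph_id)
  pg <- find_species_glyph(doc$layout, mr$prod$species_glyph_id)
  S <- bbox_center(sg$bbox); P <- bbox_center(pg$bbox)
  C <- bbox_center(rg$bbox)
  L <- sqrt(sum((S - P)^2))
  if (L == 0) L <- sg$bbox[3] * 3
  if (orientation == "horizontal") {
    S2 <- c(C[1] - L / 2, C[2]); P2 <- c(C[1] + L / 2, C[2])
  } else {
    S2 <- c(C[1], C[2] - L / 2); P2 <- c(C[1], C[2] + L / 2)
  }
  doc <- set_species_center(doc, sg$glyph_id, S2)
  doc <- set_species_center(doc, pg$glyph_id, P2)
  ref_ids <- vapply(rg$reference_glyphs, function(x) x$glyph_id, character(1))
  doc <- refresh_curves(doc, ref_ids)
  doc$layout <- fit_dimensions(doc$layout, 10)
  doc
}

#' Arrange reactions along a circular arc
#'
#' The n reaction centroids are placed on the arc at equal angular spacing
#' (span/n for a full circle, span/(n-1) for a partial arc), in list order
#' from `start_angle` along `direction`. Each reaction's main substrate and
#' product go on the arc half a spacing before and after its centroid, so
#' consecutive reactions chain through shared species; when the main product
#' of one reaction is the same species as the main substrate of the next,
#' the two get a single merged glyph. Curves of the named reactions are
#' regenerated; everything else is untouched.
#'
#' @param doc a `sbml_document` with a layout
#' @param reaction_ids ordered reaction ids (non-empty, no duplicates)
#' @param arc an [arc_spec()]
#' @return the updated document
#' @export
arrange_reactions_circle <- function(doc, reaction_ids, arc = arc_spec()) {
  if (is.null(doc$layout)) stopf("document has no layout")
  if (length(reaction_ids) == 0) stopf("reaction_ids must be non-empty")
  if (anyDuplicated(reaction_ids)) stopf("duplicate reaction ids")
  n <- length(reaction_ids)
  idxs <- vapply(reaction_ids, function(r) find_reaction_glyph_idx(doc, r), integer(1))
  sgn <- if (arc$direction == "clockwise") 1 else -1
  full <- arc$span >= 360
  step <- if (n == 1) 0 else if (full) arc$span / n else arc$span / (n - 1)
  on_arc <- function(deg) arc$center + arc$radius * angle_to_unit(deg)

  angles <- arc$start_angle + sgn * step * (seq_len(n) - 1)
  mains <- lapply(idxs, function(i) main_refs(doc$layout$reaction_glyphs[[i]]))

  # merge shared species glyphs between consecutive reactions first
  species_of_glyph <- function(gid) {
    g <- find_species_glyph(doc$layout, gid)
    if (is.null(g)) NA_character_ else g$species_id
  }
  merged_from <- character()  # old glyph id -> surviving glyph id
  pairs <- if (full && n > 1) seq_len(n) else seq_len(max(n - 1, 0))
  for (i in pairs) {
    j <- if (i == n) 1L else i + 1L
    prod_g <- mains[[i]]$prod$species_glyph_id
    sub_g <- mains[[j]]$sub$species_glyph_id
    if (prod_g == sub_g) next
    sp_p <- species_of_glyph(prod_g)
    sp_s <- species_of_glyph(sub_g)
    if (is.na(sp_p) || is.na(sp_s) || sp_p != sp_s) next
    # re-point every reference to sub_g at prod_g, then drop sub_g
    for (a in seq_along(doc$layout$reaction_glyphs)) {
      refs <- doc$layout$reaction_glyphs[[a]]$reference_glyphs
      for (b in seq_along(refs))
        if (refs[[b]]$species_glyph_id == sub_g)
          doc$layout$reaction_glyphs[[a]]$reference_glyphs[[b]]$species_glyph_id <- prod_g
    }
    keep <- vapply(doc$layout$species_glyphs,
                   function(g) g$glyph_id != sub_g, logical(1))
    doc$layout$species_glyphs <- doc$layout$species_glyphs[keep]
    keep_t <- vapply(doc$layout$text_glyphs,
                     function(t) t$target_glyph_id != sub_g, logical(1))
    doc$layout$text_glyphs <- doc$layout$text_glyphs[keep_t]
    merged_from[[sub_g]] <- prod_g
    mains <- lapply(idxs, function(ii) main_refs(doc$layout$reaction_glyphs[[ii]]))
  }

  step_sp <- if (n == 1) 90 else step  # a lone reaction still spreads its chord
  for (i in seq_len(n)) {
    rg_i <- idxs[i]
    rg <- doc$layout$reaction_glyphs[[rg_i]]
    doc$layout$reaction_glyphs[[rg_i]]$bbox <-
      bbox_from_center(on_arc(angles[i]), rg$bbox[3], rg$bbox[4])
    doc <- set_species_center(doc, mains[[i]]$sub$species_glyph_id,
                              on_arc(angles[i] - sgn * step_sp / 2))
    doc <- set_species_center(doc, mains[[i]]$prod$species_glyph_id,
                              on_arc(angles[i] + sgn * step_sp / 2))
  }

  ref_ids <- unlist(lapply(idxs, function(i)
    vapply(doc$layout$reaction_glyphs[[i]]$reference_glyphs,
           function(x) x$glyph_id, character(1))))
  doc <- refresh_curves(doc, ref_ids)
  doc$layout <- fit_dimensions(doc$layout, 10)
  doc
}

#' Move a species glyph (with curve re-attachment)
#'
#' Recenters the glyph's bounding box on `new_center` (optionally resizing
#' it), moves its text glyph with it, and regenerates the curves of every
#' incident reference glyph so their endpoints sit on the new node boundary.
#' Nothing else moves; non-incident curves are bit-identical before and
#' after.
#'
#' @param doc a `sbml_document` with a layout
#' @param glyph_id a species glyph id
#' @param new_center `(x, y)` in layout pt
#' @param new_size optional `(width, height)` in pt
#' @return the updated document
#' @export
move_species_glyph <- function(doc, glyph_id, new_center, new_size = NULL) {
  if (is.null(doc$layout)) stopf("document has no layout")
  g <- find_species_glyph(doc$layout, glyph_id)
  if (is.null(g)) stopf("unknown species glyph '%s'", glyph_id)
  if (!is.null(new_size)) {
    for (i in seq_along(doc$layout$species_glyphs))
      if (doc$layout$species_glyphs[[i]]$glyph_id == glyph_id)
        doc$layout$species_glyphs[[i]]$bbox <-
          bbox_from_center(new_center, new_size[1], new_size[2])
  }
  doc <- set_species_center(doc, glyph_id, new_center)
  incident <- character()
  for (rg in doc$layout$reaction_glyphs)
    for (ref in rg$reference_glyphs)
      if (ref$species_glyph_id == glyph_id)
        incident <- c(incident, ref$glyph_id)
  if (length(incident) > 0) doc <- refresh_curves(doc, incident)
  doc$layout <- fit_dimensions(doc$layout, 10)
  doc
}
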