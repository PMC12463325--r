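# Biochemistry-aware force-directed auto-layout: an adapted
# Fruchterman-Reingold simulation over the reaction hypergraph, followed by
# UniUni straightening, role-aware Bezier curve generation and compartment
# sizing.

#' Layout parameters
#'
#' @param iterations relaxation iterations (default 50)
#' @param seed integer seed; every random choice (initial placement, jitter)
#'   is fully determined by it
#' @param canvas_width,canvas_height canvas size in layout points
#' @param k_scale multiplier on the ideal edge length
#'   k = k_scale * sqrt(canvas_area / node_count)
#' @param initial_temperature displacement cap at the first iteration, in pt;
#'   cools linearly to zero (default canvas_width / 10)
#' @param padding margin kept around the diagram, in pt
#' @param alias_threshold maximum incident edges per species node before
#'   alias glyphs are created (see [create_aliases()])
#' @param species_w,species_h,centroid_w,centroid_h default node sizes in pt
#' @param compartment_pull weight of the weak attraction of each node toward
#'   its compartment's running centroid, as a fraction of edge attraction;
#'   active only when the model has two or more compartments
#' @return a `layout_params` list
#' @export
layout_params <- function(iterations = 50L, seed = 0L,
                          canvas_width = 800, canvas_height = 600,
                          k_scale = 1.0, initial_temperature = canvas_width / 10,
                          padding = 20, alias_threshold = 10L,
                          species_w = DEFAULT_SPECIES_W, species_h = DEFAULT_SPECIES_H,
                          centroid_w = DEFAULT_CENTROID_W, centroid_h = DEFAULT_CENTROID_H,
                          compartment_pull = 0.1) {
  if (iterations < 0) stopf("iterations must be >= 0")
  if (canvas_width <= 0 || canvas_height <= 0) stopf("canvas must be positive")
  if (k_scale <= 0) stopf("k_scale must be > 0")
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 canvas_width = canvas_width, canvas_height = canvas_height,
                 k_scale = k_scale, initial_temperature = initial_temperature,
                 padding = padding, alias_threshold = as.integer(alias_threshold),
                 species_w = species_w, species_h = species_h,
                 centroid_w = centroid_w, centroid_h = centroid_h,
                 compartment_pull = compartment_pull),
            class = "layout_params")
}

graph_matrix <- function(graph) {
  ids <- names(graph$nodes)
  n <- length(ids)
  m <- matrix(0, nrow = n, ncol = 2, dimnames = list(ids, c("x", "y")))
  m
}

#' Random initial placement
#'
#' Positions are uniform over the canvas minus padding, fully determined by
#' `params$seed`. Alias nodes of a split species are then moved to the mean
#' position of the reaction centroids in their edge partition, which keeps
#' each alias near its partner reactions from the start.
#'
#' @param graph a `network_graph`
#' @param params a [layout_params()]
#' @return a position matrix (node ids x (x, y)), node centers in pt
#' @export
place_initial <- function(graph, params) {
  ids <- names(graph$nodes)
  n <- length(ids)
  pos <- graph_matrix(graph)
  if (n == 0) return(pos)
  pad <- params$padding
  pos[, 1] <- with_seed(params$seed, runif(n, pad, params$canvas_width - pad))
  pos[, 2] <- with_seed(params$seed + 1L, runif(n, pad, params$canvas_height - pad))

  # alias seeding: mean of partner centroids
  by_species <- list()
  for (nd in graph$nodes)
    if (nd$kind == "species" && !is.na(nd$model_id))
      by_species[[nd$model_id]] <- c(by_species[[nd$model_id]], nd$node_id)
  multi <- Filter(function(v) length(v) > 1, by_species)
  if (length(multi) > 0) {
    partners <- list()
    for (e in graph$edges)
      partners[[e$species_node]] <- c(partners[[e$species_node]], e$centroid_node)
    for (grp in multi) for (nid in grp) {
      cs <- partners[[nid]]
      if (length(cs) > 0)
        pos[nid, ] <- colMeans(pos[cs, , drop = FALSE])
    }
  }
  pos
}

ideal_k <- function(params, n) {
  params$k_scale * sqrt(params$canvas_width * params$canvas_height / max(n, 1))
}

# Deterministic jitter direction for coincident nodes.
jitter_dir <- function(seed, i, j) {
  a <- 2 * pi * ((seed * 0.6180339887 + i * 0.7548776662 + j * 0.5698402910) %% 1)
  c(cos(a), sin(a))
}

#' One synchronous Fruchterman-Reingold iteration
#'
#' Repulsion k^2/d acts between every node pair and attraction d^2/k along
#' every edge, with k the ideal edge length from [layout_params()]. Each
#' node's total displacement is capped at `temperature` and the result is
#' clamped to the canvas. Coincident nodes are separated along a
#' deterministically seeded unit direction (epsilon = 1e-4 pt). When the
#' model has two or more compartments, a weak pull
#' (`params$compartment_pull` of edge attraction) draws each node toward its
#' compartment's running centroid to keep compartments separable.
#'
#' @param graph a `network_graph`
#' @param pos position matrix from [place_initial()]
#' @param temperature displacement cap, pt (>= 0)
#' @param params a [layout_params()]
#' @return the updated position matrix
#' @export
fr_step <- function(graph, pos, temperature, params) {
  ids <- names(graph$nodes)
  n <- length(ids)
  if (n <= 1) return(pos)
  k <- ideal_k(params, n)
  eps <- 1e-4

  x <- pos[, 1]; y <- pos[, 2]
  dx <- outer(x, x, "-")        # dx[i, j] = x_i - x_j
  dy <- outer(y, y, "-")
  d2 <- dx * dx + dy * dy

  zero <- which(d2 == 0 & row(d2) != col(d2), arr.ind = TRUE)
  if (nrow(zero) > 0) {
    for (r in seq_len(nrow(zero))) {
      i <- zero[r, 1]; j <- zero[r, 2]
      u <- jitter_dir(params$seed, min(i, j), max(i, j)) * eps
      if (i < j) { dx[i, j] <- u[1]; dy[i, j] <- u[2] }
      else { dx[i, j] <- -u[1]; dy[i, j] <- -u[2] }
      d2[i, j] <- eps * eps
    }
  }
  diag(d2) <- 1  # avoid 0/0; the numerator is zero on the diagonal anyway

  # repulsion: disp_i += sum_j (delta_ij / d) * k^2 / d = k^2 * delta / d^2
  coef <- k * k / d2
  diag(coef) <- 0
  disp_x <- rowSums(dx * coef)
  disp_y <- rowSums(dy * coef)

  # attraction along edges: d^2 / k toward the partner
  if (length(graph$edges) > 0) {
    iu <- match(vapply(graph$edges, function(e) e$species_node, character(1)), ids)
    iv <- match(vapply(graph$edges, function(e) e$centroid_node, character(1)), ids)
    ex <- x[iu] - x[iv]
    ey <- y[iu] - y[iv]
    ed <- sqrt(ex * ex + ey * ey)
    bad <- which(ed == 0)
    if (length(bad) > 0) {
      for (b in bad) {
        u <- jitter_dir(params$seed, min(iu[b], iv[b]), max(iu[b], iv[b])) * eps
        ex[b] <- u[1]; ey[b] <- u[2]; ed[b] <- eps
      }
    }
    f <- ed / k  # (d^2/k) / d
    ax <- ex * f
    ay <- ey * f
    for (t in seq_along(iu)) {  # accumulate; edge lists can repeat node pairs
      disp_x[iu[t]] <- disp_x[iu[t]] - ax[t]
      disp_y[iu[t]] <- disp_y[iu[t]] - ay[t]
      disp_x[iv[t]] <- disp_x[iv[t]] + ax[t]
      disp_y[iv[t]] <- disp_y[iv[t]] + ay[t]
    }
  }

  # weak compartment cohesion (multi-compartment models only)
  comps <- graph$compartment_of
  if (params$compartment_pull > 0 && length(comps) > 0 &&
      length(unique(comps)) > 1) {
    cw <- params$compartment_pull
    have <- intersect(names(comps), ids)
    for (cmp in unique(comps)) {
      members <- have[comps[have] == cmp]
      if (length(members) < 2) next
      cx <- mean(x[members]); cy <- mean(y[members])
      ddx <- cx - x[members]; ddy <- cy - y[members]
      dd <- sqrt(ddx * ddx + ddy * ddy)
      nz <- dd > 0
      f <- numeric(length(dd))
      f[nz] <- cw * dd[nz] / k
      disp_x[members] <- disp_x[members] + ddx * f
      disp_y[members] <- disp_y[members] + ddy * f
    }
  }

  len <- sqrt(disp_x * disp_x + disp_y * disp_y)
  scale <- ifelse(len > 0, pmin(len, temperature) / pmax(len, 1e-300), 0)
  pos[, 1] <- clamp(x + disp_x * scale, 0, params$canvas_width)
  pos[, 2] <- clamp(y + disp_y * scale, 0, params$canvas_height)
  pos
}

#' Run the full force simulation
#'
#' [place_initial()] followed by `params$iterations` synchronous
#' [fr_step()]s with linearly decaying temperature
#' (`initial_temperature` down to zero). Deterministic given the seed.
#'
#' @inheritParams fr_step
#' @return the final position matrix
#' @export
run_force_layout <- function(graph, params) {
  pos <- place_initial(graph, params)
  it <- params$iterations
  if (it == 0) return(pos)
  t0 <- params$initial_temperature
  for (i in seq_len(it)) {
    temp <- t0 * (1 - (i - 1) / it)
    pos <- fr_step(graph, pos, temp, params)
  }
  pos
}

# Role classification helpers.
is_substrate_role <- function(role) role %in% c("substrate", "side-substrate")
is_product_role <- function(role) role %in% c("product", "side-product")
is_modifier_role <- function(role) role %in% c("modifier", "activator", "inhibitor")

# Centroids of UniUni reactions: exactly one substrate edge and one product
# edge (modifier edges permitted).
uniuni_centroids <- function(graph) {
  subs <- list(); prods <- list()
  for (e in graph$edges) {
    if (is_substrate_role(e$role))
      subs[[e$centroid_node]] <- c(subs[[e$centroid_node]], e$edge_id)
    if (is_product_role(e$role))
      prods[[e$centroid_node]] <- c(prods[[e$centroid_node]], e$edge_id)
  }
  out <- character()
  for (nd in graph$nodes) {
    if (nd$kind != "centroid") next
    if (length(subs[[nd$node_id]]) == 1 && length(prods[[nd$node_id]]) == 1)
      out <- c(out, nd$node_id)
  }
  out
}

#' Straighten UniUni reactions
#'
#' Every centroid of a one-reactant, one-product reaction is moved onto the
#' midpoint of its two species endpoints, so the reaction draws as a direct
#' reactant-to-product line. All other centroids are untouched.
#'
#' @param graph a `network_graph`
#' @param pos position matrix covering the graph
#' @return the updated position matrix
#' @export
straighten_uniuni <- function(graph, pos) {
  uu <- uniuni_centroids(graph)
  if (length(uu) == 0) return(pos)
  ends <- list()
  for (e in graph$edges)
    if ((is_substrate_role(e$role) || is_product_role(e$role)) &&
        e$centroid_node %in% uu)
      ends[[e$centroid_node]] <- c(ends[[e$centroid_node]], e$species_node)
  for (cid in uu)
    pos[cid, ] <- (pos[ends[[cid]][1], ] + pos[ends[[cid]][2], ]) / 2
  pos
}

# Exact intersection of the ray from an ellipse's center at angle `a` with
# the ellipse boundary inscribed in a (w, h) box.
ellipse_point <- function(center, w, h, a) {
  d <- c(cos(a), sin(a))
  s <- 1 / sqrt((d[1] / (w / 2))^2 + (d[2] / (h / 2))^2)
  center + s * d
}

# Spread a set of angles so that pairwise separation >= min_sep (radians),
# moving only unpinned entries, by symmetric relaxation passes.
spread_angles <- function(angles, pinned, min_sep) {
  m <- length(angles)
  if (m < 2) return(angles)
  ord <- order(angles)
  a <- angles[ord]
  pin <- pinned[ord]
  for (pass in 1:60) {
    moved <- FALSE
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      gap <- if (i == m) (a[j] + 2 * pi) - a[i] else a[j] - a[i]
      if (gap < min_sep - 1e-12) {
        push <- (min_sep - gap) / 2
        if (!pin[i] && !pin[j]) { a[i] <- a[i] - push; a[j] <- a[j] + push }
        else if (pin[i] && !pin[j]) a[j] <- a[j] + 2 * push
        else if (!pin[i] && pin[j]) a[i] <- a[i] - 2 * push
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  out <- numeric(m)
  out[ord] <- a
  out
}

#' Generate role-aware Bezier curves for every edge
#'
#' Each edge gets one cubic Bezier segment between a species-boundary
#' attachment point and the reaction centroid. At the centroid, tangents
#' occupy angular slots by biochemical role: substrate curves enter through
#' the half-plane facing the substrate mass center, product curves through
#' the opposite half-plane (fanned evenly within +/-60 degrees of the axis
#' when a role has several edges), and modifiers come in perpendicular to
#' the substrate-product axis. On a species node with several incident
#' edges, attachment points start at the boundary intersections toward each
#' centroid and are then minimally rotated apart until separated by at least
#' 15 degrees; attachments of straightened UniUni edges are pinned so those
#' curves stay exactly collinear with the reactant-product chord (control
#' points on the chord). Product curves run centroid-to-species so that an
#' end-head arrow marks the product.
#'
#' @param graph a `network_graph`
#' @param pos position matrix (post [straighten_uniuni()])
#' @param params a [layout_params()]
#' @return named list: edge id -> list of curve segments
#' @export
generate_curves <- function(graph, pos, params) {
  uu <- uniuni_centroids(graph)
  edges <- graph$edges
  nodes <- graph$nodes

  # --- centroid-side tangent angle per edge -------------------------------
  by_centroid <- list()
  for (e in edges) by_centroid[[e$centroid_node]] <- c(by_centroid[[e$centroid_node]], e$edge_id)
  tangent <- numeric(0)  # named by edge id; angle of outward tangent at centroid

  fan_offsets <- function(m, half = pi / 3) {
    if (m == 1) 0 else seq(-half, half, length.out = m)
  }
  for (cid in names(by_centroid)) {
    eids <- by_centroid[[cid]]
    roles <- vapply(eids, function(id) edges[[id]]$role, character(1))
    sub_ids <- eids[is_substrate_role(roles)]
    prod_ids <- eids[is_product_role(roles)]
    mod_ids <- eids[is_modifier_role(roles)]
    cpos <- pos[cid, ]
    if (length(sub_ids) > 0) {
      sp <- pos[vapply(sub_ids, function(id) edges[[id]]$species_node, character(1)), ,
                drop = FALSE]
      mc <- colMeans(sp)
      axis <- atan2(mc[2] - cpos[2], mc[1] - cpos[1])
      if (!is.finite(axis) || all(mc == cpos)) axis <- 0
    } else axis <- 0
    off <- fan_offsets(length(sub_ids))
    for (i in seq_along(sub_ids)) tangent[[sub_ids[i]]] <- axis + off[i]
    off <- fan_offsets(length(prod_ids))
    for (i in seq_along(prod_ids)) tangent[[prod_ids[i]]] <- axis + pi + off[i]
    for (i in seq_along(mod_ids)) {
      side <- if (i %% 2 == 1) pi / 2 else -pi / 2
      extra <- (ceiling(i / 2) - 1) * deg2rad(20)
      tangent[[mod_ids[i]]] <- axis + side + extra
    }
  }

  # --- species-side attachment angles with congestion spreading ------------
  by_species <- list()
  for (e in edges) by_species[[e$species_node]] <- c(by_species[[e$species_node]], e$edge_id)
  attach_angle <- numeric(0)
  min_sep <- deg2rad(15)
  for (sid in names(by_species)) {
    eids <- by_species[[sid]]
    spos <- pos[sid, ]
    desired <- vapply(eids, function(id) {
      cpos <- pos[edges[[id]]$centroid_node, ]
      atan2(cpos[2] - spos[2], cpos[1] - spos[1])
    }, numeric(1))
    pinned <- vapply(eids, function(id) edges[[id]]$centroid_node %in% uu, logical(1))
    final <- spread_angles(desired, pinned, min_sep)
    for (i in seq_along(eids)) attach_angle[[eids[i]]] <- final[i]
  }

  # --- curve construction --------------------------------------------------
  out <- list()
  for (e in edges) {
    snode <- nodes[[e$species_node]]
    spos <- pos[e$species_node, ]
    cpos <- pos[e$centroid_node, ]
    straight <- e$centroid_node %in% uu &&
      (is_substrate_role(e$role) || is_product_role(e$role))
    if (straight) {
      dirv <- cpos - spos
      L <- sqrt(sum(dirv^2))
      a <- if (L > 0) atan2(dirv[2], dirv[1]) else 0
      p0 <- ellipse_point(spos, snode$w, snode$h, a)
      p3 <- cpos
      if (is_product_role(e$role)) { tmp <- p0; p0 <- p3; p3 <- tmp }
      bp1 <- p0 + (p3 - p0) / 3
      bp2 <- p0 + 2 * (p3 - p0) / 3
      out[[e$edge_id]] <- list(new_segment(p0, p3, bp1, bp2))
      next
    }
    aa <- attach_angle[[e$edge_id]]
    attach <- ellipse_point(spos, snode$w, snode$h, aa)
    L <- sqrt(sum((cpos - attach)^2))
    u <- c(cos(aa), sin(aa))                       # outward at the species
    ta <- if (e$edge_id %in% names(tangent)) tangent[[e$edge_id]]
          else atan2(attach[2] - cpos[2], attach[1] - cpos[1])
    tv <- c(cos(ta), sin(ta))                      # outward at the centroid
    c_sp <- attach + (L / 3) * u
    c_ct <- cpos + (L / 3) * tv
    if (is_product_role(e$role))
      out[[e$edge_id]] <- list(new_segment(cpos, attach, c_ct, c_sp))
    else
      out[[e$edge_id]] <- list(new_segment(attach, cpos, c_sp, c_ct))
  }
  out
}

node_to_glyph_id <- function(node) {
  if (node$kind == "emptyset") return(paste0("sg_", node$node_id))
  paste0("sg_", substring(node$node_id, 3))
}

#' Generate complete layout data for a model
#'
#' Runs the full auto-layout pipeline: hypergraph construction
#' ([build_graph()]), empty-set source/sink insertion
#' ([add_emptyset_nodes()]), hub aliasing ([create_aliases()]), the force
#' simulation ([run_force_layout()]), UniUni straightening and role-aware
#' curve generation, then emits glyphs: a species glyph plus text glyph per
#' species node (label = species name, falling back to the id), a reaction
#' glyph with reference glyphs carrying the curves per reaction, and a
#' compartment glyph sized to the padded bounding box of its members.
#' Canvas dimensions grow if needed so every bounding box is enclosed.
#'
#' @param doc a `sbml_document` with a model
#' @param params a [layout_params()]
#' @param regenerate replace an existing layout? When `FALSE` and a layout
#'   is already present, the document is returned unchanged.
#' @return the document with a complete layout
#' @export
build_layout <- function(doc, params = layout_params(), regenerate = TRUE) {
  if (is.null(doc$model)) stopf("document has no model")
  if (!is.null(doc$layout) && !regenerate) return(doc)

  graph <- build_graph(doc)
  graph <- add_emptyset_nodes(graph)
  graph <- create_aliases(graph, params$alias_threshold)
  pos <- run_force_layout(graph, params)
  pos <- straighten_uniuni(graph, pos)
  curves <- generate_curves(graph, pos, params)

  layout <- new_layout("layout1", params$canvas_width, params$canvas_height)
  m <- doc$model
  sp_names <- stats::setNames(m$species$name, m$species$id)

  node_glyph <- character()  # node id -> glyph id
  for (nd in graph$nodes) {
    if (nd$kind == "centroid") next
    gid <- node_to_glyph_id(nd)
    node_glyph[[nd$node_id]] <- gid
    bbox <- bbox_from_center(pos[nd$node_id, ], nd$w, nd$h)
    layout$species_glyphs[[length(layout$species_glyphs) + 1]] <-
      new_species_glyph(gid, if (nd$kind == "emptyset") NA_character_ else nd$model_id,
                        bbox, nd$alias_index)
    if (nd$kind == "species") {
      label <- if (nd$model_id %in% names(sp_names)) sp_names[[nd$model_id]] else nd$model_id
      if (is.na(label) || label == "") label <- nd$model_id
      layout$text_glyphs[[length(layout$text_glyphs) + 1]] <-
        new_text_glyph(paste0("tg_", substring(gid, 4)), gid, label, bbox)
    }
  }

  for (nd in graph$nodes) {
    if (nd$kind != "centroid") next
    refs <- list()
    for (e in graph$edges) {
      if (e$centroid_node != nd$node_id) next
      refs[[length(refs) + 1]] <- new_reference_glyph(
        paste0("srg_", e$edge_id), node_glyph[[e$species_node]], e$role,
        curves[[e$edge_id]])
    }
    layout$reaction_glyphs[[length(layout$reaction_glyphs) + 1]] <-
      new_reaction_glyph(paste0("rg_", nd$model_id), nd$model_id,
                         bbox_from_center(pos[nd$node_id, ], nd$w, nd$h), refs)
  }

  layout <- size_compartments(layout, graph, m, params$padding)
  layout <- fit_dimensions(layout, params$padding)
  doc$layout <- layout
  doc$render <- NULL
  doc
}

# Compartment glyphs sized to the padded bounding box of their member glyphs
# (species nodes via the model; centroids via their first participant).
size_compartments <- function(layout, graph, model, padding) {
  if (nrow(model$compartments) == 0) return(layout)
  member_of <- character()
  for (nd in graph$nodes) {
    if (nd$kind == "species")
      member_of[[node_to_glyph_id(nd)]] <- graph$compartment_of[[nd$node_id]]
  }
  first_sp <- list()
  for (e in graph$edges) {
    cid <- e$centroid_node
    if (is.null(first_sp[[cid]]) && graph$nodes[[e$species_node]]$kind == "species")
      first_sp[[cid]] <- e$species_node
  }
  for (nd in graph$nodes) {
    if (nd$kind == "centroid" && !is.null(first_sp[[nd$node_id]]))
      member_of[[paste0("rg_", nd$model_id)]] <-
        graph$compartment_of[[first_sp[[nd$node_id]]]]
  }
  boxes <- list()
  for (g in c(layout$species_glyphs, layout$reaction_glyphs))
    boxes[[g$glyph_id]] <- g$bbox
  for (i in seq_len(nrow(model$compartments))) {
    cmp <- model$compartments$id[i]
    members <- names(member_of)[member_of == cmp]
    members <- intersect(members, names(boxes))
    if (length(members) == 0) {
      bb <- c(0, 0, 2 * padding, 2 * padding)
    } else {
      bm <- do.call(rbind, boxes[members])
      x0 <- min(bm[, 1]); y0 <- min(bm[, 2])
      x1 <- max(bm[, 1] + bm[, 3]); y1 <- max(bm[, 2] + bm[, 4])
      bb <- c(x0 - padding, y0 - padding, (x1 - x0) + 2 * padding, (y1 - y0) + 2 * padding)
    }
    layout$compartment_glyphs[[length(layout$compartment_glyphs) + 1]] <-
      new_compartment_glyph(paste0("cg_", cmp), cmp, bb)
  }
  layout
}

# Grow (never shrink) the layout dimensions so all boxes are enclosed; if any
# box starts at negative coordinates, everything is translated into view.
fit_dimensions <- function(layout, padding = 20) {
  els <- layout_elements(layout)
  boxes <- Filter(Negate(is.null),
                  lapply(els, function(e) e$element$bbox))
  if (length(boxes) == 0) return(layout)
  bm <- do.call(rbind, boxes)
  shift_x <- max(0, padding - min(bm[, 1]))
  shift_y <- max(0, padding - min(bm[, 2]))
  if (shift_x > 0 || shift_y > 0)
    layout <- translate_layout(layout, shift_x, shift_y)
  bm[, 1] <- bm[, 1] + shift_x
  bm[, 2] <- bm[, 2] + shift_y
  layout$width <- max(layout$width, max(bm[, 1] + bm[, 3]) + padding)
  layout$height <- max(layout$height, max(bm[, 2] + bm[, 4]) + padding)
  layout
}

translate_layout <- function(layout, dx, dy) {
  shift_bbox <- function(b) c(b[1] + dx, b[2] + dy, b[3], b[4])
  shift_pt <- function(p) if (is.null(p)) NULL else p + c(dx, dy)
  layout$species_glyphs <- lapply(layout$species_glyphs, function(g) {
    g$bbox <- shift_bbox(g$bbox); g })
  layout$compartment_glyphs <- lapply(layout$compartment_glyphs, function(g) {
    g$bbox <- shift_bbox(g$bbox); g })
  layout$text_glyphs <- lapply(layout$text_glyphs, function(g) {
    g$bbox <- shift_bbox(g$bbox); g })
  layout$extra_glyphs <- lapply(layout$extra_glyphs, function(g) {
    g$bbox <- shift_bbox(g$bbox); g })
  layout$reaction_glyphs <- lapply(layout$reaction_glyphs, function(rg) {
    rg$bbox <- shift_bbox(rg$bbox)
    rg$reference_glyphs <- lapply(rg$reference_glyphs, function(ref) {
      ref$curve <- lapply(ref$curve, function(seg) {
        new_segment(shift_pt(seg$start), shift_pt(seg$end),
                    shift_pt(seg$bp1), shift_pt(seg$bp2))
      })
      ref
    })
    rg
  })
  layout
}
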