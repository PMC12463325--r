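# Reaction hypergraph: species nodes plus one centroid node per reaction,
# joined by role-labeled edges. Aliasing splits hub species over several
# nodes; emancipated empty-set nodes stand in for missing sources/sinks.

DEFAULT_SPECIES_W <- 60
DEFAULT_SPECIES_H <- 36
DEFAULT_CENTROID_W <- 10
DEFAULT_CENTROID_H <- 10

new_network_node <- function(node_id, kind, model_id = NA_character_,
                             alias_index = 0L, w = DEFAULT_SPECIES_W,
                             h = DEFAULT_SPECIES_H) {
  list(node_id = node_id, kind = kind, model_id = model_id,
       alias_index = as.integer(alias_index), w = w, h = h)
}

new_network_edge <- function(edge_id, species_node, centroid_node, role,
                             stoichiometry = 1) {
  list(edge_id = edge_id, species_node = species_node,
       centroid_node = centroid_node, role = role,
       stoichiometry = stoichiometry)
}

#' Build the reaction hypergraph of a model
#'
#' Every species becomes one node, every reaction a dedicated centroid node,
#' and every participation (reactant, product, modifier) one role-labeled
#' edge between the species node and the centroid. Modifier roles are refined
#' to `inhibitor` (SBO:0000020 or an "inhibitor" annotation keyword) or
#' `activator` (SBO:0000459 / "activator"); otherwise they stay `modifier`.
#' Node and edge order follows model document order, so the graph is
#' deterministic.
#'
#' @param doc a `sbml_document` with a model
#' @return a `network_graph`: list with `nodes`, `edges`, `compartment_of`
#' @export
build_graph <- function(doc) {
  m <- doc$model
  if (is.null(m)) stopf("document has no model")
  nodes <- list()
  edges <- list()
  compartment_of <- character()
  if (nrow(m$species) > 0) {
    for (i in seq_len(nrow(m$species))) {
      id <- m$species$id[i]
      nid <- paste0("n_", id)
      nodes[[nid]] <- new_network_node(nid, "species", id)
      compartment_of[[nid]] <- m$species$compartment[i]
    }
  }
  eidx <- 0L
  for (r in m$reactions) {
    cid <- paste0("c_", r$id)
    nodes[[cid]] <- new_network_node(cid, "centroid", r$id,
                                     w = DEFAULT_CENTROID_W, h = DEFAULT_CENTROID_H)
    add_edge <- function(species, role, stoich = 1) {
      eidx <<- eidx + 1L
      eid <- sprintf("e%d", eidx)
      edges[[eid]] <<- new_network_edge(eid, paste0("n_", species), cid, role, stoich)
    }
    if (nrow(r$reactants) > 0)
      for (i in seq_len(nrow(r$reactants)))
        add_edge(r$reactants$species[i], "substrate", r$reactants$stoichiometry[i])
    if (nrow(r$products) > 0)
      for (i in seq_len(nrow(r$products)))
        add_edge(r$products$species[i], "product", r$products$stoichiometry[i])
    if (nrow(r$modifiers) > 0)
      for (i in seq_len(nrow(r$modifiers)))
        add_edge(r$modifiers$species[i], modifier_role(r$modifiers$sbo[i]))
  }
  structure(list(nodes = nodes, edges = edges, compartment_of = compartment_of),
            class = "network_graph")
}

modifier_role <- function(sbo) {
  if (is.na(sbo) || is.null(sbo)) return("modifier")
  s <- tolower(sbo)
  if (grepl("sbo:0000020", s) || grepl("inhibitor", s)) return("inhibitor")
  if (grepl("sbo:0000459", s) || grepl("activator", s)) return("activator")
  "modifier"
}

#' Add emancipated empty-set (source/sink) nodes
#'
#' Every reaction centroid with no substrate edge gains a fresh empty-set
#' node joined by a substrate edge, and symmetrically for missing products,
#' so boundary reactions like "(empty) -> A" get a visible source glyph. One
#' node per deficit; empty-set nodes are never shared between reactions.
#'
#' @param graph a `network_graph`
#' @return the augmented graph
#' @export
add_emptyset_nodes <- function(graph) {
  substrate_roles <- c("substrate", "side-substrate")
  product_roles <- c("product", "side-product")
  counts <- list()
  for (e in graph$edges) {
    k <- e$centroid_node
    if (is.null(counts[[k]])) counts[[k]] <- c(sub = 0L, prod = 0L)
    if (e$role %in% substrate_roles) counts[[k]]["sub"] <- counts[[k]]["sub"] + 1L
    if (e$role %in% product_roles) counts[[k]]["prod"] <- counts[[k]]["prod"] + 1L
  }
  eidx <- length(graph$edges)
  n_empty <- 0L
  for (n in graph$nodes) {
    if (n$kind != "centroid") next
    cnt <- counts[[n$node_id]] %||% c(sub = 0L, prod = 0L)
    for (side in c("sub", "prod")) {
      if (cnt[side] > 0L) next
      n_empty <- n_empty + 1L
      nid <- sprintf("empty_%d", n_empty)
      graph$nodes[[nid]] <- new_network_node(nid, "emptyset", w = 24, h = 24)
      eidx <- eidx + 1L
      eid <- sprintf("e%d", eidx)
      graph$edges[[eid]] <- new_network_edge(
        eid, nid, n$node_id, if (side == "sub") "substrate" else "product")
    }
  }
  graph
}

#' Split hub species into alias nodes
#'
#' A species node whose incident edge count k exceeds `degree_threshold` is
#' replaced by `ceiling(k / degree_threshold)` alias nodes (alias_index
#' 0..m-1). Its edges are partitioned over the aliases as evenly as possible
#' (load difference at most 1), assigned in input order, so the multiset of
#' (reaction, role, species) participations and the total edge count are
#' conserved. Empty-set nodes are never aliased. The operation is idempotent
#' at a fixed threshold.
#'
#' @param graph a `network_graph`
#' @param degree_threshold maximum incident edges per species node (>= 1);
#'   the default of 10 lets typical hub metabolites (ATP, NADH) split while
#'   pathway intermediates stay single
#' @return the graph with alias nodes
#' @export
create_aliases <- function(graph, degree_threshold = 10L) {
  if (!is.numeric(degree_threshold) || degree_threshold < 1)
    stopf("degree_threshold must be >= 1 (got %s)", format(degree_threshold))
  t <- as.integer(degree_threshold)

  # incident edges per species-side node, in input order
  incident <- list()
  for (e in graph$edges) {
    k <- e$species_node
    incident[[k]] <- c(incident[[k]], e$edge_id)
  }

  new_nodes <- list()
  for (n in graph$nodes) {
    if (n$kind != "species") { new_nodes[[n$node_id]] <- n; next }
    eids <- incident[[n$node_id]]
    k <- length(eids)
    if (k <= t) { new_nodes[[n$node_id]] <- n; next }
    m <- ceiling(k / t)
    # balanced partition: sizes differ by at most one
    base <- k %/% m
    extra <- k %% m
    sizes <- rep(base, m) + c(rep(1L, extra), rep(0L, m - extra))
    at <- 1L
    for (a in seq_len(m) - 1L) {
      nid <- if (a == 0L) n$node_id else sprintf("%s_alias%d", n$node_id, a)
      nn <- n
      nn$node_id <- nid
      nn$alias_index <- a
      new_nodes[[nid]] <- nn
      if (n$node_id %in% names(graph$compartment_of))
        graph$compartment_of[[nid]] <- graph$compartment_of[[n$node_id]]
      take <- eids[seq.int(at, length.out = sizes[a + 1L])]
      at <- at + sizes[a + 1L]
      for (eid in take) graph$edges[[eid]]$species_node <- nid
    }
  }
  graph$nodes <- new_nodes
  graph
}

# Incident edge ids per node (both endpoints), preserving input order.
incident_edges <- function(graph) {
  inc <- list()
  for (e in graph$edges) {
    inc[[e$species_node]] <- c(inc[[e$species_node]], e$edge_id)
    inc[[e$centroid_node]] <- c(inc[[e$centroid_node]], e$edge_id)
  }
  inc
}
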