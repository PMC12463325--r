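test_that("the hypergraph has one node per species and per reaction", {
  doc <- toy_model(c("A", "B", "C"),
                   list(new_reaction("R1", reactants = c("A", "B"), products = "C")))
  g <- build_graph(doc)
  kinds <- vapply(g$nodes, function(n) n$kind, character(1))
  expect_equal(sum(kinds == "species"), 3)
  expect_equal(sum(kinds == "centroid"), 1)
  expect_length(g$edges, 3)
  roles <- vapply(g$edges, function(e) e$role, character(1))
  expect_equal(sort(unname(roles)), c("product", "substrate", "substrate"))
})

test_that("modifier roles are refined by SBO term", {
  doc <- toy_model(c("A", "B", "M1", "M2", "M3"), list(
    new_reaction("R1", reactants = "A", products = "B",
                 modifiers = data.frame(
                   species = c("M1", "M2", "M3"),
                   sbo = c("SBO:0000020", "SBO:0000459", NA),
                   stringsAsFactors = FALSE))))
  g <- build_graph(doc)
  roles <- vapply(g$edges, function(e) e$role, character(1))
  sp <- vapply(g$edges, function(e) e$species_node, character(1))
  expect_equal(unname(roles[sp == "n_M1"]), "inhibitor")
  expect_equal(unname(roles[sp == "n_M2"]), "activator")
  expect_equal(unname(roles[sp == "n_M3"]), "modifier")
})

test_that("reactions without substrates or products get empty-set nodes", {
  doc <- toy_model(c("A", "B"), list(
    new_reaction("Rin", products = "A"),       # source reaction
    new_reaction("Rout", reactants = "B")))    # sink reaction
  g <- add_emptyset_nodes(build_graph(doc))
  kinds <- vapply(g$nodes, function(n) n$kind, character(1))
  expect_equal(sum(kinds == "emptyset"), 2)
  # each empty-set node is private to its reaction
  es_edges <- Filter(function(e) g$nodes[[e$species_node]]$kind == "emptyset",
                     g$edges)
  cents <- vapply(es_edges, function(e) e$centroid_node, character(1))
  expect_equal(anyDuplicated(cents), 0)
  roles <- vapply(es_edges, function(e) e$role, character(1))
  expect_setequal(roles, c("substrate", "product"))
})

test_that("aliasing caps species degree at the threshold", {
  hub_doc <- toy_model(c("H", paste0("X", 1:25)),
                       lapply(1:25, function(i)
                         new_reaction(paste0("R", i), reactants = "H",
                                      products = paste0("X", i))))
  g <- build_graph(hub_doc)
  for (t in c(1, 3, 7, 10, 12)) {
    ga <- create_aliases(g, t)
    deg <- table(vapply(ga$edges, function(e) e$species_node, character(1)))
    hub_deg <- deg[grepl("^n_H", names(deg))]
    expect_true(all(hub_deg <= t), info = sprintf("threshold %d", t))
    expect_equal(sum(hub_deg), 25)            # participation conserved
    expect_lte(max(hub_deg) - min(hub_deg), 1) # balanced loads
    expect_length(hub_deg, ceiling(25 / t))
  }
})

test_that("aliasing is idempotent and leaves low-degree species alone", {
  hub_doc <- toy_model(c("H", paste0("X", 1:25)),
                       lapply(1:25, function(i)
                         new_reaction(paste0("R", i), reactants = "H",
                                      products = paste0("X", i))))
  g <- build_graph(hub_doc)
  g1 <- create_aliases(g, 10)
  g2 <- create_aliases(g1, 10)
  expect_identical(g1, g2)
  # the X species have degree 1 and keep a single node each
  kinds <- vapply(g1$nodes, function(n) n$kind, character(1))
  x_nodes <- grep("^n_X", names(g1$nodes), value = TRUE)
  expect_length(x_nodes, 25)
})

test_that("alias edges are partitioned in input order", {
  hub_doc <- toy_model(c("H", paste0("X", 1:6)),
                       lapply(1:6, function(i)
                         new_reaction(paste0("R", i), reactants = "H",
                                      products = paste0("X", i))))
  g <- build_graph(hub_doc)
  ga <- create_aliases(g, 3)
  owner <- vapply(ga$edges, function(e) e$species_node, character(1))
  hub_edges <- grep("^n_H", owner)
  # first block of edges stays on the original node, next on alias 1
  expect_equal(unname(unique(owner[hub_edges])), c("n_H", "n_H_alias1"))
})

test_that("a degree threshold below one is rejected", {
  g <- build_graph(toy_model("A"))
  expect_error(create_aliases(g, 0), "threshold")
})
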