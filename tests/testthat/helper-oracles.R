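# Shared helpers: tiny model builders and independent brute-force oracles
# used to cross-check the optimized implementations.

# A minimal hand-built model: species ids, plus a list of reactions.
toy_model <- function(species_ids, reactions = list(), compartment = "c") {
  new_document(new_model(
    id = "toy",
    compartments = data.frame(id = compartment, name = compartment,
                              stringsAsFactors = FALSE),
    species = data.frame(id = species_ids, name = species_ids,
                         compartment = compartment, stringsAsFactors = FALSE),
    reactions = reactions))
}

# A -> B chain document with a laid-out diagram.
toy_layout_doc <- function(seed = 1, iterations = 30) {
  doc <- toy_model(c("A", "B", "C"),
                   list(new_reaction("R1", reactants = "A", products = "B"),
                        new_reaction("R2", reactants = "B", products = "C")))
  build_layout(doc, layout_params(iterations = iterations, seed = seed))
}

# Brute-force Fruchterman-Reingold step, written as the direct double loop
# over node pairs. Intentionally naive and independent from fr_step().
brute_force_fr <- function(graph, pos, temperature, params) {
  n <- nrow(pos)
  k <- params$k_scale * sqrt(params$canvas_width * params$canvas_height / max(n, 1))
  disp <- matrix(0, n, 2)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    d <- pos[i, ] - pos[j, ]
    dist <- sqrt(sum(d^2))
    if (dist < 1e-12) {
      d <- sbmlviz:::jitter_dir(params$seed, i, j) * 1e-4
      dist <- 1e-4
    }
    disp[i, ] <- disp[i, ] + d / dist * (k^2 / dist)
  }
  for (e in graph$edges) {
    i <- match(e$species_node, rownames(pos))
    j <- match(e$centroid_node, rownames(pos))
    d <- pos[i, ] - pos[j, ]
    dist <- sqrt(sum(d^2))
    if (dist < 1e-12) {
      d <- sbmlviz:::jitter_dir(params$seed, i, j) * 1e-4
      dist <- 1e-4
    }
    f <- dist^2 / k
    disp[i, ] <- disp[i, ] - d / dist * f
    disp[j, ] <- disp[j, ] + d / dist * f
  }
  out <- pos
  for (i in seq_len(n)) {
    dl <- sqrt(sum(disp[i, ]^2))
    if (dl > 0) out[i, ] <- pos[i, ] + disp[i, ] / dl * min(dl, temperature)
    out[i, 1] <- min(max(out[i, 1], 0), params$canvas_width)
    out[i, 2] <- min(max(out[i, 2], 0), params$canvas_height)
  }
  out
}

# Signed area of the triangle (p, q, r): zero iff collinear.
cross2 <- function(p, q, r) {
  (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
}

# Reference gradient interpolation: linear per channel, round half up.
oracle_gradient_color <- function(fraction, stops) {
  hi <- which(stops$offset >= fraction)[1]
  if (hi == 1) hi <- 2
  lo <- hi - 1
  t <- (fraction - stops$offset[lo]) / (stops$offset[hi] - stops$offset[lo])
  ch <- function(hex, i) strtoi(substr(hex, 2 * i, 2 * i + 1), 16L)
  v <- vapply(1:3, function(i) {
    floor(ch(stops$color[lo], i) + t * (ch(stops$color[hi], i) -
                                          ch(stops$color[lo], i)) + 0.5)
  }, numeric(1))
  sprintf("#%02X%02X%02X", v[1], v[2], v[3])
}

# Build a randomized document exercising every serializable feature:
# aliases, empty-set glyphs, modifiers, curves, text, extra glyphs, colors,
# gradients, line endings and id/role/type styles.
random_full_doc <- function(seed) {
  set.seed(seed)
  n <- sample(8:20, 1)
  doc <- generate_model(n, ratio = 4, seed = seed)
  # add a source reaction so empty-set glyphs appear
  doc$model$reactions[[length(doc$model$reactions) + 1]] <-
    new_reaction("Rsource", products = doc$model$species$id[1])
  # add a modifier to the first reaction
  doc$model$reactions[[1]]$modifiers <-
    data.frame(species = doc$model$species$id[n], sbo = "SBO:0000020",
               stringsAsFactors = FALSE)
  doc <- build_layout(doc, layout_params(iterations = sample(5:15, 1),
                                         seed = seed, alias_threshold = 4))
  doc <- default_render(doc)
  doc <- batch_set(doc, doc$layout$species_glyphs[[1]]$glyph_id,
                   "fill", sprintf("#%06X", sample(0:16777215, 1)))
  doc <- add_colorbar(doc, default_gradient(), c(0, seed))
  doc
}

# Glyph center helper.
glyph_center <- function(doc, glyph_id) {
  els <- layout_elements(doc$layout)
  el <- els[[glyph_id]]
  stopifnot(!is.null(el))
  b <- el$element$bbox
  unname(c(b[1] + b[3] / 2, b[2] + b[4] / 2))
}
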