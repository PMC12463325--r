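# Synthetic SBML models of parameterized size, emulating benchmark inputs
# with a fixed species-to-reaction ratio, plus a layout timing harness.

#' Generate a synthetic SBML model
#'
#' Produces a model with `n_species` species ("S1".."Sn") in one compartment
#' and `floor(n_species / ratio)` reactions ("R1".."Rm"). Each reaction
#' draws its reactant count and product count uniformly from {1, 2} and its
#' participants without replacement from the species pool, using the seeded
#' generator, which yields the UniUni/BiBi mix typical of biochemical
#' models. No kinetics are attached: layout needs topology only.
#'
#' @param n_species number of species (>= ratio)
#' @param ratio species per reaction (default 4)
#' @param seed integer seed; the same spec always yields the identical model
#' @return a `sbml_document` (model only, no layout)
#' @export
generate_model <- function(n_species, ratio = 4, seed = 0L) {
  if (n_species < ratio)
    stopf("n_species (%d) must be >= ratio (%g)", n_species, ratio)
  n_reactions <- floor(n_species / ratio)
  sp_ids <- paste0("S", seq_len(n_species))
  species <- data.frame(id = sp_ids, name = sp_ids,
                        compartment = "default_compartment",
                        stringsAsFactors = FALSE)
  comps <- data.frame(id = "default_compartment", name = "default_compartment",
                      stringsAsFactors = FALSE)
  reactions <- with_seed(seed, {
    lapply(seq_len(n_reactions), function(i) {
      nr <- sample(1:2, 1)
      np <- sample(1:2, 1)
      part <- sample(sp_ids, nr + np, replace = FALSE)
      new_reaction(paste0("R", i),
                   reactants = part[seq_len(nr)],
                   products = part[nr + seq_len(np)])
    })
  })
  new_document(new_model(id = sprintf("synthetic_%d_species", n_species),
                         compartments = comps, species = species,
                         reactions = reactions))
}

#' Time the auto-layout over a range of synthetic model sizes
#'
#' For each size, a synthetic model is generated and laid out `reps` times
#' with the given iteration count; the median wall-clock time is recorded.
#' Timings are reported, never asserted: they depend on the machine.
#'
#' @param sizes numeric vector of species counts
#' @param iterations relaxation iterations per layout (default 50)
#' @param reps repetitions per size (median is taken)
#' @param seed seed for model generation and placement
#' @param ratio species per reaction
#' @return data.frame with columns `n_species`, `n_reactions`, `median_s`,
#'   `reps`, `iterations`
#' @export
run_benchmark <- function(sizes, iterations = 50L, reps = 3L, seed = 0L,
                          ratio = 4) {
  if (length(sizes) == 0) stopf("sizes must be non-empty")
  rows <- lapply(sizes, function(n) {
    doc <- generate_model(n, ratio = ratio, seed = seed)
    times <- vapply(seq_len(reps), function(r) {
      as.numeric(system.time(
        build_layout(doc, layout_params(iterations = iterations, seed = seed))
      )["elapsed"])
    }, numeric(1))
    data.frame(n_species = n, n_reactions = floor(n / ratio),
               median_s = stats::median(times), reps = reps,
               iterations = iterations)
  })
  do.call(rbind, rows)
}
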