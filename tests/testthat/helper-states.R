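# Shared fixtures and independent oracles for the test suite.

# Build a split population state directly from per-subpopulation effect
# matrices (NA entries are treated as absent slots).
make_split_state <- function(pop1, pop2, generation = 0L, lineage = NULL) {
  effects <- rbind(pop1, pop2)
  present <- !is.na(effects)
  niche <- rep(1:2, c(nrow(pop1), nrow(pop2)))
  new_population_state(effects, present, niche,
                       generation = generation, lineage = lineage)
}

# A small scenario that runs in well under a second.
tiny_config <- function(...) {
  defaults <- list(pop_size = 40, n_loci = 5, burn_in = 20, generations = 30,
                   record_every = 10)
  args <- list(...)
  do.call(scenario_config, utils::modifyList(defaults, args))
}

# Exact distribution over unordered survivor sets under sequential weighted
# draws without replacement: enumerate every ordered draw path and accumulate
# its probability. Independent of the package's sampler.
enum_survivor_sets <- function(weights, k) {
  n <- length(weights)
  probs <- new.env(parent = emptyenv())
  recurse <- function(chosen, remaining, p) {
    if (length(chosen) == k) {
      key <- paste(sort(chosen), collapse = ",")
      probs[[key]] <- (if (is.null(probs[[key]])) 0 else probs[[key]]) + p
      return(invisible())
    }
    wsum <- sum(weights[remaining])
    for (i in remaining) {
      recurse(c(chosen, i), setdiff(remaining, i), p * weights[i] / wsum)
    }
  }
  recurse(integer(0), seq_len(n), 1)
  keys <- ls(probs)
  list(sets = lapply(strsplit(keys, ","), as.integer),
       probs = vapply(keys, function(k_) probs[[k_]], numeric(1)),
       keys = keys)
}
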