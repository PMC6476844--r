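#' Construct a population state
#'
#' The complete evolving state of the simulation: an `N x L` matrix of allele
#' effect sizes, a parallel presence mask (absent slots are "empty" loci that
#' contribute zero to the phenotype and are exempt from mutation and
#' recombination), and a fixed niche assignment per individual. Effect values
#' of absent slots are stored as `NA` so that a genuine effect-0 allele of
#' the evolving model is never confused with an empty slot.
#'
#' @param effects Numeric `N x L` matrix of effect sizes (`NA` where absent).
#' @param present Logical `N x L` matrix; `TRUE` where a gene copy exists.
#' @param niche Integer vector of length `N`; `0` before the split, `1` or
#'   `2` afterwards. Individuals never move between niches.
#' @param generation Current generation index (0 = founding).
#' @param lineage Optional integer `N x L` matrix of per-copy provenance tags
#'   (origin subpopulation, assigned at the split).
#' @return A `population_state` object.
#' @export
new_population_state <- function(effects, present, niche,
                                 generation = 0L, lineage = NULL) {
  stopifnot(is.matrix(effects), is.matrix(present),
            all(dim(effects) == dim(present)),
            length(niche) == nrow(effects))
  structure(
    list(
      effects = effects,
      present = present,
      niche = as.integer(niche),
      generation = as.integer(generation),
      lineage = lineage
    ),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  n <- nrow(x$effects)
  cat(sprintf("<population_state> N = %d, L = %d, generation %d (%s)\n",
              n, ncol(x$effects), x$generation,
              if (is_split(x)) "split" else "unsplit"))
  cat(sprintf("  present copies: %d / %d; mean phenotype %.4f\n",
              sum(x$present), length(x$present), mean(phenotypes(x))))
  invisible(x)
}

#' Has the population been split into its two niches?
#' @param state A `population_state`.
#' @return `TRUE` once niche assignments have been made.
#' @export
is_split <- function(state) any(state$niche > 0L)

#' Found a homogeneous population
#'
#' Every run starts from a fully homogeneous population that is optimal for
#' niche 1: all loci present, every effect equal to `optima[1] / n_loci`
#' (equivalently `sign(optima[1]) * allele_size` for the fixed model), so
#' every founder's phenotype equals the niche-1 optimum exactly.
#'
#' @param config A `scenario_config`.
#' @return A `population_state` at generation 0, not yet split.
#' @export
founder_population <- function(config) {
  validate_scenario(config)
  n <- config$pop_size
  l <- config$n_loci
  a0 <- if (config$effect_model == "fixed") {
    sign(config$optima[1]) * config$allele_size
  } else {
    config$optima[1] / l
  }
  effects <- matrix(a0, nrow = n, ncol = l)
  present <- matrix(TRUE, nrow = n, ncol = l)
  lineage <- if (config$lineage_tags) matrix(0L, nrow = n, ncol = l) else NULL
  new_population_state(effects, present, niche = rep(0L, n),
                       generation = 0L, lineage = lineage)
}

#' Split the metapopulation into its two niche subpopulations
#'
#' Assigns the first half of the rows to niche 1 and the second half to
#' niche 2. Assignments are permanent: the model has no migration of cells,
#' only of DNA. If lineage tags are enabled, every present copy is stamped
#' with its subpopulation of origin at this moment.
#'
#' @param state A `population_state` (unsplit).
#' @param config The `scenario_config` of the run.
#' @return The split `population_state`.
#' @export
split_population <- function(state, config) {
  if (is_split(state)) stop("population is already split", call. = FALSE)
  n <- nrow(state$effects)
  state$niche <- rep(1:2, each = n %/% 2L)
  if (config$lineage_tags) {
    tags <- matrix(rep(state$niche, ncol(state$effects)), nrow = n)
    tags[!state$present] <- NA_integer_
    state$lineage <- tags
  }
  state
}

#' Individual phenotypes
#'
#' The phenotype of each cell is the sum of the effect sizes of its present
#' gene copies; absent loci contribute exactly zero and the trait has no
#' environmental component.
#'
#' @param state A `population_state`.
#' @return Numeric vector of length `N`.
#' @export
phenotypes <- function(state) {
  e <- state$effects
  if (!all(state$present)) e[!state$present] <- 0
  rowSums(e)
}

#' Gaussian stabilizing-selection fitness
#'
#' `W(p) = exp(-(p - x)^2 / (2 * sel_width))`: fitness declines as a Gaussian
#' in the distance between the phenotype `p` and the niche optimum `x`, with
#' width (variance) `sel_width`. Fitness equals 1 exactly at the optimum and
#' is symmetric about it. With the default width of 2 and ten loci of effect
#' 0.1, a single maladapted allele costs about 1% of fitness; the same total
#' effect concentrated in one locus costs 63%.
#'
#' @param p Phenotype value(s).
#' @param x Niche optimum.
#' @param sel_width Selection width (variance); must be > 0.
#' @return Relative fitness in `(0, 1]`, vectorized over `p`.
#' @export
stabilizing_fitness <- function(p, x, sel_width) {
  if (!is.numeric(sel_width) || length(sel_width) != 1L || is.na(sel_width) ||
      sel_width <= 0) {
    stop("`sel_width` must be a single value > 0", call. = FALSE)
  }
  exp(-(p - x)^2 / (2 * sel_width))
}

rows_of_niche <- function(state, subpop) {
  which(state$niche == as.integer(subpop))
}
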