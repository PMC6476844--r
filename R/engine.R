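# Per-generation stochastic operators and their composition.
#
# All operators are synchronous: events within one generation are drawn from
# frozen snapshots of the state (recombination donor pools in particular), so
# the outcome of a generation does not depend on the order in which events at
# different matrix positions are applied.

# Weighted sampling of `k` distinct survivors out of `length(weights)`
# offspring, equivalent in distribution to sequential weighted draws without
# replacement (exponential-key selection: the k smallest Exp(1)/w_i keys).
select_survivors <- function(weights, k) {
  n <- length(weights)
  if (k > n) stop("cannot select more survivors than offspring", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("selection weights must be finite and non-negative", call. = FALSE)
  }
  if (sum(weights > 0) < k) {
    stop("degenerate selection weights: fewer than `k` offspring have positive fitness",
         call. = FALSE)
  }
  keys <- stats::rexp(n) / weights
  order(keys)[seq_len(k)]
}

#' Reproduction, selection and drift
#'
#' Each individual divides into two identical offspring; from the resulting
#' offspring pool of size `2N`, half survive so population size stays
#' constant. Survivors are distinct offspring drawn sequentially with
#' probability proportional to Gaussian fitness around the niche optimum
#' (under divergent selection) or uniformly (neutral). After the split the
#' sampling is applied independently within each subpopulation, so both
#' subpopulation sizes are conserved every generation; before the split the
#' whole population forms a single neutral pool.
#'
#' @param state A `population_state`.
#' @param config A `scenario_config`.
#' @return The next `population_state` (generation counter unchanged;
#'   [step_generation()] increments it).
#' @export
reproduce_and_select <- function(state, config) {
  groups <- if (is_split(state)) {
    list(rows_of_niche(state, 1L), rows_of_niche(state, 2L))
  } else {
    list(seq_len(nrow(state$effects)))
  }
  selected <- integer(nrow(state$effects))
  pos <- 1L
  use_fitness <- config$selection == "divergent" && is_split(state)
  phen <- if (use_fitness) phenotypes(state) else NULL
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    k <- length(rows)
    parent_of <- rep(rows, each = 2L)
    w <- if (use_fitness) {
      rep(stabilizing_fitness(phen[rows], config$optima[g], config$sel_width),
          each = 2L)
    } else {
      rep(1, 2L * k)
    }
    surv <- select_survivors(w, k)
    selected[pos:(pos + k - 1L)] <- parent_of[surv]
    pos <- pos + k
  }
  state$effects <- state$effects[selected, , drop = FALSE]
  state$present <- state$present[selected, , drop = FALSE]
  if (!is.null(state$lineage)) {
    state$lineage <- state$lineage[selected, , drop = FALSE]
  }
  # niche is positional and group sizes are conserved, so it is unchanged
  state
}

#' Mutation
#'
#' Every *present* gene copy mutates independently with probability
#' `mut_rate`. Under the fixed model the allele flips sign (`+a <-> -a`);
#' under the evolving model the effect is replaced by a draw from a normal
#' distribution centred on the current effect with variance `mut_var`,
#' creating an (almost surely) new allele. Absent slots are never touched.
#'
#' @inheritParams reproduce_and_select
#' @return The mutated `population_state`.
#' @export
mutate_genomes <- function(state, config) {
  m <- config$mut_rate
  if (m == 0) return(state)
  hit <- which(state$present & stats::runif(length(state$present)) < m)
  if (length(hit) == 0L) return(state)
  if (config$effect_model == "fixed") {
    state$effects[hit] <- -state$effects[hit]
  } else {
    state$effects[hit] <- state$effects[hit] +
      stats::rnorm(length(hit), mean = 0, sd = sqrt(config$mut_var))
  }
  state
}

#' Build per-locus allele pools
#'
#' An allele pool holds every extant gene copy at a locus within a scope —
#' the whole metapopulation (`"global"`) or one subpopulation (`"local"`) —
#' with multiplicity. Pools are frozen snapshots: recombination and gain
#' events of a generation all draw from the pools built at the start of
#' their phase, so within-generation events are exchangeable. Absent slots
#' contribute nothing; a locus with no present copy in scope has an empty
#' pool (it is extinct there).
#'
#' @param state A `population_state`.
#' @param scope `"global"` or `"local"`.
#' @return An `allele_pools` object: for each scope group, a list with one
#'   `values` (and, with lineage tags, `tags`) vector per locus.
#' @export
build_pools <- function(state, scope = c("global", "local")) {
  scope <- match.arg(scope)
  groups <- if (scope == "global") {
    list(all = seq_len(nrow(state$effects)))
  } else {
    if (!is_split(state)) {
      stop("local pools require a split population", call. = FALSE)
    }
    list(`1` = rows_of_niche(state, 1L), `2` = rows_of_niche(state, 2L))
  }
  pools <- lapply(groups, function(rows) {
    lapply(seq_len(ncol(state$effects)), function(l) {
      keep <- rows[state$present[rows, l]]
      p <- list(values = state$effects[keep, l])
      if (!is.null(state$lineage)) p$tags <- state$lineage[keep, l]
      p
    })
  })
  structure(list(scope = scope, pools = pools), class = "allele_pools")
}

pool_set_for <- function(pools, niche) {
  if (pools$scope == "global") pools$pools[["all"]]
  else pools$pools[[as.character(niche)]]
}

#' Homologous recombination as gene conversion
#'
#' Every present gene copy independently undergoes recombination with
#' probability `rec_rate`; the resident allele is then replaced by a
#' multiplicity-weighted uniform draw from the extant-allele pool of the same
#' locus (so a copy can recombine with itself, a no-op). With a global gene
#' pool the donor may come from either subpopulation — this is the model's
#' only channel of gene flow between niches; with local pools donors come
#' from the recipient's own subpopulation. Absent slots neither donate nor
#' receive, and the presence mask is unchanged.
#'
#' @inheritParams reproduce_and_select
#' @param pools Frozen [build_pools()] snapshot with scope matching
#'   `config$gene_pool`.
#' @return The recombined `population_state`.
#' @export
recombine_genomes <- function(state, pools, config) {
  r <- config$rec_rate
  if (r == 0) return(state)
  if (pools$scope != config$gene_pool) {
    stop("pool scope does not match `config$gene_pool`", call. = FALSE)
  }
  u <- matrix(stats::runif(length(state$present)), nrow = nrow(state$present))
  groups <- if (pools$scope == "global") {
    list(list(rows = seq_len(nrow(state$effects)), set = pool_set_for(pools, NA)))
  } else {
    lapply(1:2, function(s) {
      list(rows = rows_of_niche(state, s), set = pool_set_for(pools, s))
    })
  }
  for (grp in groups) {
    rows <- grp$rows
    for (l in seq_len(ncol(state$effects))) {
      ev <- rows[state$present[rows, l] & u[rows, l] < r]
      if (length(ev) == 0L) next
      pool <- grp$set[[l]]
      npool <- length(pool$values)
      # a present copy in scope guarantees a nonempty pool in that scope
      stopifnot(npool > 0L)
      draw <- sample.int(npool, length(ev), replace = TRUE)
      state$effects[ev, l] <- pool$values[draw]
      if (!is.null(state$lineage)) state$lineage[ev, l] <- pool$tags[draw]
    }
  }
  state
}

#' Gene loss
#'
#' Every present gene copy independently becomes absent with probability
#' `loss_rate`. A lost slot has zero phenotypic contribution and — lacking
#' the homologous tracts recombination requires — is thereafter exempt from
#' mutation and recombination; only gene gain can repopulate it.
#'
#' @inheritParams reproduce_and_select
#' @return The `population_state` with losses applied.
#' @export
lose_genes <- function(state, config) {
  lam <- config$loss_rate
  if (lam == 0) return(state)
  hit <- which(state$present & stats::runif(length(state$present)) < lam)
  if (length(hit) == 0L) return(state)
  state$present[hit] <- FALSE
  state$effects[hit] <- NA_real_
  if (!is.null(state$lineage)) state$lineage[hit] <- NA_integer_
  state
}

#' Gene gain
#'
#' Every *empty* locus slot independently attempts a gain with probability
#' `gain_rate`. The slot is refilled with a copy of the same locus from
#' another individual — a multiplicity-weighted uniform draw from the scoped
#' allele pool. If no individual in scope carries the locus it has gone
#' extinct there and the slot stays empty (no event is counted).
#'
#' @inheritParams recombine_genomes
#' @return The `population_state` with gains applied.
#' @export
gain_genes <- function(state, pools, config) {
  gam <- config$gain_rate
  if (gam == 0) return(state)
  if (pools$scope != config$gene_pool) {
    stop("pool scope does not match `config$gene_pool`", call. = FALSE)
  }
  u <- matrix(stats::runif(length(state$present)), nrow = nrow(state$present))
  groups <- if (pools$scope == "global") {
    list(list(rows = seq_len(nrow(state$effects)), set = pool_set_for(pools, NA)))
  } else {
    lapply(1:2, function(s) {
      list(rows = rows_of_niche(state, s), set = pool_set_for(pools, s))
    })
  }
  for (grp in groups) {
    rows <- grp$rows
    for (l in seq_len(ncol(state$effects))) {
      pool <- grp$set[[l]]
      if (length(pool$values) == 0L) next  # locus extinct in scope
      ev <- rows[!state$present[rows, l] & u[rows, l] < gam]
      if (length(ev) == 0L) next
      draw <- sample.int(length(pool$values), length(ev), replace = TRUE)
      state$effects[ev, l] <- pool$values[draw]
      state$present[ev, l] <- TRUE
      if (!is.null(state$lineage)) state$lineage[ev, l] <- pool$tags[draw]
    }
  }
  state
}

#' Advance the population by one generation
#'
#' Applies, in order: reproduction with selection and drift; mutation;
#' homologous recombination (from pools frozen after mutation); gene loss;
#' gene gain (from pools rebuilt after loss, so donors are currently extant
#' copies). Increments the generation counter. Subpopulation sizes are
#' conserved and each parent contributes 0, 1 or 2 offspring.
#'
#' @inheritParams reproduce_and_select
#' @return The `population_state` one generation later.
#' @export
step_generation <- function(state, config) {
  state <- reproduce_and_select(state, config)
  state <- mutate_genomes(state, config)
  if (config$rec_rate > 0) {
    pools <- build_pools(state, config$gene_pool)
    state <- recombine_genomes(state, pools, config)
  }
  if (config$loss_rate > 0) state <- lose_genes(state, config)
  if (config$gain_rate > 0) {
    pools <- build_pools(state, config$gene_pool)
    state <- gain_genes(state, pools, config)
  }
  state$generation <- state$generation + 1L
  state
}

burn_in_config <- function(config) {
  bc <- config
  bc$selection <- "neutral"
  bc$loss_rate <- 0
  bc$gain_rate <- 0
  if (!config$burn_in_recombination) bc$rec_rate <- 0
  bc
}

#' Run a full simulation
#'
#' Phase 1 (burn-in): the whole founding population reproduces neutrally
#' with mutation only for `burn_in` generations, establishing standing
#' variation. Phase 2: the population is split into two fixed subpopulations
#' facing opposite niche optima and the full operator set (selection,
#' mutation, recombination, loss, gain — as configured) runs for
#' `generations` generations. Summary statistics are recorded every
#' `record_every` post-split generations and at the endpoint.
#'
#' @param config A `scenario_config`. If `config$seed` is set the RNG is
#'   seeded for exact reproducibility of the replicate.
#' @param initial_state Optional `population_state` to resume from (e.g. a
#'   snapshot of a long run); burn-in and split are skipped and the
#'   simulation continues for `config$generations` further generations.
#' @param record If `FALSE`, skip the time series (endpoint state only).
#' @return A `divergence_sim` object: list with `state` (final
#'   `population_state`), `records` (tibble time series: generation,
#'   subpopulation mean phenotypes, phenotypic divergence, `d_max`,
#'   `d_mean`, percent loci missing, extant locus count) and `config`.
#' @examples
#' sim <- run_simulation(scenario_config(pop_size = 100, burn_in = 50,
#'                                       generations = 100, seed = 1))
#' tail(sim$records, 2)
#' @export
run_simulation <- function(config, initial_state = NULL, record = TRUE) {
  validate_scenario(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(initial_state)) {
    state <- founder_population(config)
    bc <- burn_in_config(config)
    for (g in seq_len(config$burn_in)) state <- step_generation(state, bc)
    state <- split_population(state, config)
  } else {
    state <- initial_state
    if (!is_split(state)) stop("`initial_state` must be a split population",
                               call. = FALSE)
  }
  n_rec <- if (record) config$generations %/% config$record_every + 2L else 0L
  recs <- vector("list", n_rec)
  k <- 0L
  for (g in seq_len(config$generations)) {
    state <- step_generation(state, config)
    if (record && (g %% config$record_every == 0L || g == config$generations)) {
      k <- k + 1L
      recs[[k]] <- record_generation(state)
    }
  }
  if (record && k == 0L) {  # zero-generation run: record the split state
    k <- 1L
    recs[[k]] <- record_generation(state)
  }
  records <- if (record) {
    tibble::as_tibble(do.call(rbind, recs[seq_len(k)]))
  } else {
    NULL
  }
  structure(list(state = state, records = records, config = config),
            class = "divergence_sim")
}

# One time-series row as a named numeric vector (cheap inside the hot loop).
record_generation <- function(state) {
  phen <- phenotypes(state)
  m1 <- mean(phen[state$niche == 1L])
  m2 <- mean(phen[state$niche == 2L])
  prof <- divergence_profile(state)
  c(
    generation = state$generation,
    mean_phenotype_pop1 = m1,
    mean_phenotype_pop2 = m2,
    divergence = abs(m1 - m2),
    d_max = prof$d_max,
    d_mean = prof$d_mean,
    pct_missing = 100 * mean(!state$present),
    n_extant_loci = sum(colSums(state$present) > 0L)
  )
}

#' @export
print.divergence_sim <- function(x, ...) {
  cat(sprintf("<divergence_sim> %d+%d generations, N = %d, L = %d\n",
              x$config$burn_in, x$config$generations,
              x$config$pop_size, x$config$n_loci))
  if (!is.null(x$records) && nrow(x$records) > 0) {
    last <- x$records[nrow(x$records), ]
    cat(sprintf("  endpoint: divergence %.3f, d_max %.3f, %.1f%% loci missing\n",
                last$divergence, last$d_max, last$pct_missing))
  }
  invisible(x)
}
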