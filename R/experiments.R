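# Factorial experiment grids and replicate management.

#' Build a factorial scenario grid
#'
#' Forms the Cartesian product of the supplied factor levels — recombination
#' rate, gene-pool scope, selection regime, genome-content treatment and
#' effect-size model — and drops the two inadmissible combinations: neutral
#' models with gene loss (they drift toward extinction of all loci) and gain
#' without loss (the model starts with its maximum locus complement, so gain
#' alone has nothing to refill). The default fixed-effects arm yields 24
#' scenarios.
#'
#' @param rec_rates Recombination rates to cross (default `0, 0.005, 0.05`).
#' @param gene_pools `"global"` and/or `"local"`.
#' @param selections `"neutral"` and/or `"divergent"`.
#' @param gene_content Subset of `"none"`, `"loss"`, `"loss_gain"`.
#' @param effect_models `"fixed"` and/or `"evolving"`.
#' @param base A `scenario_config` supplying all non-factor parameters.
#' @param loss_rate,gain_rate Rates used where the content treatment enables
#'   them (defaults 1e-4, the study's low-turnover setting).
#' @return A tibble with one row per scenario: `scenario_id`, the factor
#'   columns, and a `config` list-column of `scenario_config` objects.
#' @examples
#' nrow(build_grid())  # 24
#' @export
build_grid <- function(rec_rates = c(0, 0.005, 0.05),
                       gene_pools = c("global", "local"),
                       selections = c("neutral", "divergent"),
                       gene_content = c("none", "loss", "loss_gain"),
                       effect_models = "fixed",
                       base = scenario_config(),
                       loss_rate = 1e-4,
                       gain_rate = 1e-4) {
  stopifnot(all(gene_pools %in% c("global", "local")),
            all(selections %in% c("neutral", "divergent")),
            all(gene_content %in% c("none", "loss", "loss_gain")),
            all(effect_models %in% c("fixed", "evolving")))
  if (any(rec_rates < 0 | rec_rates > 1)) {
    stop("`rec_rates` must lie in [0, 1]", call. = FALSE)
  }
  cells <- expand.grid(
    rec_rate = rec_rates, gene_pool = gene_pools, selection = selections,
    gene_content = gene_content, effect_model = effect_models,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  cells <- cells[!(cells$selection == "neutral" & cells$gene_content != "none"), ,
                 drop = FALSE]
  configs <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- base
    cfg$rec_rate <- cells$rec_rate[i]
    cfg$gene_pool <- cells$gene_pool[i]
    cfg$selection <- cells$selection[i]
    cfg$effect_model <- cells$effect_model[i]
    cfg$loss_rate <- if (cells$gene_content[i] == "none") 0 else loss_rate
    cfg$gain_rate <- if (cells$gene_content[i] == "loss_gain") gain_rate else 0
    validate_scenario(cfg)
    cfg
  })
  ids <- sprintf("%s_%s_%s_%s_r%g", cells$effect_model, cells$gene_pool,
                 cells$selection, cells$gene_content, cells$rec_rate)
  tibble::tibble(
    scenario_id = ids,
    rec_rate = cells$rec_rate,
    gene_pool = cells$gene_pool,
    selection = cells$selection,
    gene_content = cells$gene_content,
    effect_model = cells$effect_model,
    config = configs
  )
}

#' Run a scenario grid with replicates
#'
#' Runs every scenario of a [build_grid()] table for `replicates`
#' independent replicates. Replicate seeds are a deterministic function of
#' `(base_seed, scenario index, replicate)` —
#' `base_seed + (i - 1) * replicates + (j - 1)` — so the resulting table is
#' bit-identical for identical inputs regardless of execution order.
#'
#' @param grid A grid tibble from [build_grid()] (or any tibble with
#'   `scenario_id` and a `config` list-column).
#' @param replicates Replicates per scenario.
#' @param base_seed Base integer seed.
#' @param generations Optional override of the post-split run length for
#'   every scenario (e.g. for scaled-down sweeps).
#' @param keep_series If `TRUE`, attach the full per-replicate time series
#'   as the `"series"` attribute (a named list of tibbles).
#' @return An endpoint table: one row per (scenario, replicate) with the
#'   scenario factors, `replicate`, `seed`, and endpoint statistics
#'   (`divergence`, `d_max`, `d_mean`, `pct_missing`,
#'   `private_locus_fraction`, `n_extant_loci`,
#'   `copies_per_surviving_locus`, subpopulation mean phenotypes).
#' @export
run_grid <- function(grid, replicates = 10, base_seed = 1,
                     generations = NULL, keep_series = FALSE) {
  stopifnot(replicates >= 1, nrow(grid) >= 1)
  rows <- vector("list", nrow(grid) * replicates)
  series <- if (keep_series) list() else NULL
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    cfg <- grid$config[[i]]
    if (!is.null(generations)) cfg$generations <- as.integer(generations)
    for (j in seq_len(replicates)) {
      cfg$seed <- as.integer(base_seed + (i - 1L) * replicates + (j - 1L))
      sim <- run_simulation(cfg, record = keep_series)
      phen <- phenotypes(sim$state)
      prof <- divergence_profile(sim$state)
      gc_stats <- genome_content(sim$state)
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        scenario_id = grid$scenario_id[i],
        rec_rate = cfg$rec_rate,
        gene_pool = cfg$gene_pool,
        selection = cfg$selection,
        effect_model = cfg$effect_model,
        loss_rate = cfg$loss_rate,
        gain_rate = cfg$gain_rate,
        replicate = j,
        seed = cfg$seed,
        divergence = phenotypic_divergence(sim$state),
        d_max = prof$d_max,
        d_mean = prof$d_mean,
        pct_missing = gc_stats$pct_missing,
        private_locus_fraction = gc_stats$private_locus_fraction,
        n_extant_loci = gc_stats$n_extant_loci,
        copies_per_surviving_locus = gc_stats$copies_per_surviving_locus,
        mean_phenotype_pop1 = mean(phen[sim$state$niche == 1L]),
        mean_phenotype_pop2 = mean(phen[sim$state$niche == 2L])
      )
      if (keep_series) {
        series[[paste0(grid$scenario_id[i], "_rep", j)]] <- sim$records
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (keep_series) attr(out, "series") <- series
  out
}

#' Per-scenario endpoint means and standard errors
#'
#' Aggregates a [run_grid()] endpoint table to one row per scenario, with
#' the mean and standard error (over replicates) of each endpoint statistic.
#'
#' @param endpoints An endpoint table from [run_grid()].
#' @return A tibble, one row per `scenario_id`, columns `<stat>_mean` and
#'   `<stat>_se` plus `n_replicates`.
#' @export
endpoint_summary <- function(endpoints) {
  se <- function(v) stats::sd(v) / sqrt(length(v))
  stat_cols <- c("divergence", "d_max", "d_mean", "pct_missing",
                 "private_locus_fraction", "n_extant_loci",
                 "copies_per_surviving_locus")
  stat_cols <- intersect(stat_cols, names(endpoints))
  endpoints |>
    dplyr::group_by(.data$scenario_id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(dplyr::all_of(stat_cols),
                    list(mean = mean, se = se),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    )
}
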