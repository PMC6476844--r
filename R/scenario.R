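#' Build a simulation scenario configuration
#'
#' A scenario bundles every parameter of the divergence model: demography,
#' per-gene-copy event rates, the stabilizing-selection landscape, the
#' genetic-architecture model, and run-length bookkeeping. Defaults follow the
#' standard two-niche study conditions: a metapopulation of 2,000 haploid
#' cells (1,000 per niche after the split), 10 additive loci, mutation rate
#' 0.005 per extant gene copy per generation, selection width 2 and niche
#' optima at +1 and -1.
#'
#' @param pop_size Total number of individuals in the metapopulation (even;
#'   each subpopulation holds `pop_size / 2` after the split).
#' @param n_loci Number of loci contributing additively to the trait.
#' @param mut_rate Mutation probability per extant gene copy per generation.
#' @param rec_rate Homologous-recombination (gene-conversion) probability per
#'   extant gene copy per generation. Study values: 0, 0.005, 0.05.
#' @param loss_rate Gene-loss probability per extant gene copy per generation.
#' @param gain_rate Gene-gain probability per *empty* locus slot per
#'   generation. Gain only refills lost loci, so `gain_rate > 0` requires
#'   `loss_rate > 0`.
#' @param mut_var Variance of the Gaussian mutation kernel under
#'   `effect_model = "evolving"` (ignored by the fixed model).
#' @param sel_width Width (variance) of the Gaussian stabilizing-selection
#'   fitness function; larger values mean weaker selection.
#' @param optima Length-2 numeric vector of niche phenotypic optima
#'   `(x1, x2)`; the founder is optimal for niche 1.
#' @param effect_model `"fixed"` (two alleles of effect +a / -a per locus) or
#'   `"evolving"` (continuous effect sizes).
#' @param gene_pool `"global"` (recombination and gain donors drawn from the
#'   whole metapopulation) or `"local"` (donors drawn only from the
#'   recipient's own subpopulation).
#' @param selection `"divergent"` (survival weighted by Gaussian fitness
#'   around each niche's optimum) or `"neutral"` (uniform survival).
#' @param burn_in Pre-split generations of neutral reproduction and mutation.
#' @param generations Post-split generations to simulate.
#' @param record_every Sampling interval (generations) for the time series.
#' @param seed Integer RNG seed for one replicate, or `NULL` to use the
#'   current RNG state.
#' @param allele_size Allele magnitude `a` of the fixed model. Defaults to
#'   `abs(optima[1]) / n_loci` so that a full complement of +a alleles is
#'   optimal in niche 1.
#' @param burn_in_recombination If `TRUE`, homologous recombination at
#'   `rec_rate` is also active during burn-in. The default (`FALSE`) restricts
#'   burn-in to neutral reproduction and mutation.
#' @param lineage_tags If `TRUE`, every gene copy carries a provenance tag
#'   (origin subpopulation, assigned at the split) that is copied along with
#'   recombination and gain events; used to audit gene-flow isolation.
#'
#' @return A `scenario_config` object (validated named list).
#' @seealso [run_simulation()], [build_grid()], [read_scenario_config()]
#' @examples
#' cfg <- scenario_config(rec_rate = 0.05, gene_pool = "local", seed = 1)
#' cfg$allele_size
#' @export
scenario_config <- function(pop_size = 2000,
                            n_loci = 10,
                            mut_rate = 0.005,
                            rec_rate = 0.005,
                            loss_rate = 0,
                            gain_rate = 0,
                            mut_var = 4e-4,
                            sel_width = 2,
                            optima = c(1, -1),
                            effect_model = c("fixed", "evolving"),
                            gene_pool = c("global", "local"),
                            selection = c("divergent", "neutral"),
                            burn_in = 1000,
                            generations = 5000,
                            record_every = 10,
                            seed = NULL,
                            allele_size = NULL,
                            burn_in_recombination = FALSE,
                            lineage_tags = FALSE) {
  effect_model <- match.arg(effect_model)
  gene_pool <- match.arg(gene_pool)
  selection <- match.arg(selection)
  if (is.null(allele_size)) allele_size <- abs(optima[1]) / n_loci
  cfg <- structure(
    list(
      pop_size = as.integer(pop_size),
      n_loci = as.integer(n_loci),
      mut_rate = as.numeric(mut_rate),
      rec_rate = as.numeric(rec_rate),
      loss_rate = as.numeric(loss_rate),
      gain_rate = as.numeric(gain_rate),
      mut_var = as.numeric(mut_var),
      sel_width = as.numeric(sel_width),
      optima = as.numeric(optima),
      effect_model = effect_model,
      gene_pool = gene_pool,
      selection = selection,
      burn_in = as.integer(burn_in),
      generations = as.integer(generations),
      record_every = as.integer(record_every),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      allele_size = as.numeric(allele_size),
      burn_in_recombination = isTRUE(burn_in_recombination),
      lineage_tags = isTRUE(lineage_tags)
    ),
    class = "scenario_config"
  )
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks the structural invariants of the model: an even population that
#' splits into two equal subpopulations, event rates that are probabilities,
#' a strictly positive selection width, and gene gain only in combination
#' with gene loss (the model starts with its maximum locus complement, so
#' gain can only refill lost slots).
#'
#' @param config A `scenario_config`.
#' @return `config`, invisibly; errors on violation.
#' @export
validate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with(config, {
    if (pop_size < 2L || pop_size %% 2L != 0L) {
      stop("`pop_size` must be an even integer >= 2 (two equal subpopulations)",
           call. = FALSE)
    }
    if (n_loci < 1L) stop("`n_loci` must be >= 1", call. = FALSE)
    for (nm in c("mut_rate", "rec_rate", "loss_rate", "gain_rate")) {
      v <- config[[nm]]
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
        stop(sprintf("`%s` must be a probability in [0, 1]", nm), call. = FALSE)
      }
    }
    if (!is.numeric(sel_width) || sel_width <= 0) {
      stop("`sel_width` must be > 0", call. = FALSE)
    }
    if (!is.numeric(mut_var) || mut_var < 0) {
      stop("`mut_var` must be >= 0", call. = FALSE)
    }
    if (length(optima) != 2L || anyNA(optima)) {
      stop("`optima` must be two finite niche optima", call. = FALSE)
    }
    if (gain_rate > 0 && loss_rate == 0) {
      stop("`gain_rate` > 0 requires `loss_rate` > 0: gain only refills lost loci",
           call. = FALSE)
    }
    if (allele_size <= 0) stop("`allele_size` must be > 0", call. = FALSE)
    if (burn_in < 0L || generations < 0L) {
      stop("`burn_in` and `generations` must be >= 0", call. = FALSE)
    }
    if (record_every < 1L) stop("`record_every` must be >= 1", call. = FALSE)
  })
  invisible(config)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  demography : N = %d (2 x %d), L = %d loci\n",
              x$pop_size, x$pop_size %/% 2L, x$n_loci))
  cat(sprintf("  rates      : m = %g, r = %g, loss = %g, gain = %g\n",
              x$mut_rate, x$rec_rate, x$loss_rate, x$gain_rate))
  cat(sprintf("  selection  : %s, sigma_w^2 = %g, optima = (%g, %g)\n",
              x$selection, x$sel_width, x$optima[1], x$optima[2]))
  cat(sprintf("  genetics   : %s effects (a = %g, sigma_m^2 = %g), %s gene pool\n",
              x$effect_model, x$allele_size, x$mut_var, x$gene_pool))
  cat(sprintf("  schedule   : %d burn-in + %d generations, record every %d, seed %s\n",
              x$burn_in, x$generations, x$record_every,
              if (is.null(x$seed)) "<unset>" else x$seed))
  invisible(x)
}

scenario_field_names <- function() {
  names(formals(scenario_config))
}

#' Write a scenario configuration to YAML or JSON
#'
#' The configuration is stored as a flat key-value mapping so that factorial
#' sweeps can be driven from plain-text files. The format is chosen from the
#' file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param config A `scenario_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  validate_scenario(config)
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' Read a scenario configuration from YAML or JSON
#'
#' Unknown keys are an error rather than being ignored: a typo in a sweep
#' file would otherwise silently fall back to a default value.
#'
#' @param path Path to a configuration file written by
#'   [write_scenario_config()] or by hand.
#' @return A validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals) || !is.list(vals)) {
    stop("config file is empty or malformed: ", path, call. = FALSE)
  }
  unknown <- setdiff(names(vals), scenario_field_names())
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(scenario_config, vals)
}
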