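# The per-generation operators, each checked against an independent oracle
# (exact enumeration, closed-form moments, or forced-parameter limits).

test_that("survivor sampling matches exact sequential weighted draws without replacement", {
  # toy offspring pool: two fit (w = 1) and two maladapted (w = e^-1) offspring
  w <- c(1, 1, exp(-1), exp(-1))
  exact <- enum_survivor_sets(w, 2)
  set.seed(101)
  n_draws <- 2e4
  drawn <- replicate(n_draws, {
    paste(sort(ecodiverge:::select_survivors(w, 2)), collapse = ",")
  })
  counts <- table(factor(drawn, levels = exact$keys))
  p <- suppressWarnings(stats::chisq.test(counts, p = exact$probs)$p.value)
  expect_gt(p, 1e-3)
})

test_that("neutral survival is symmetric: each offspring survives with probability 1/2", {
  set.seed(102)
  n_draws <- 2e4
  hits <- numeric(6)
  for (i in seq_len(n_draws)) {
    s <- ecodiverge:::select_survivors(rep(1, 6), 3)
    hits[s] <- hits[s] + 1
  }
  se <- sqrt(0.5 * 0.5 / n_draws)
  expect_true(all(abs(hits / n_draws - 0.5) < 4 * se))
})

test_that("selection weights are scale invariant and degeneracy is caught", {
  w <- runif(10) + 0.1
  set.seed(7); a <- ecodiverge:::select_survivors(w, 5)
  set.seed(7); b <- ecodiverge:::select_survivors(1000 * w, 5)
  expect_identical(a, b)
  expect_error(ecodiverge:::select_survivors(rep(0, 4), 2), "degenerate")
  expect_error(ecodiverge:::select_survivors(c(1, 1, 0, 0), 3), "degenerate")
  expect_error(ecodiverge:::select_survivors(c(1, NA), 1), "finite")
})

test_that("reproduction conserves subpopulation sizes and caps family size at two", {
  cfg <- tiny_config(selection = "divergent")
  set.seed(103)
  s <- split_population(founder_population(cfg), cfg)
  s$effects[] <- sample(c(-0.2, 0.2), length(s$effects), replace = TRUE)
  s2 <- reproduce_and_select(s, cfg)
  expect_equal(tabulate(s2$niche), tabulate(s$niche))
  # each parent divides into two identical offspring, so any surviving row
  # pattern can appear at most twice per unique parent genotype more often
  # than the parent pool held it; checked directly on the sampler:
  surv <- ecodiverge:::select_survivors(rep(1, 40), 20)
  parent <- (surv - 1L) %/% 2L
  expect_lte(max(tabulate(parent + 1L)), 2L)
})

test_that("one selection step cannot decrease expected mean fitness (no mutation)", {
  # N_sub = 4 toy, exact expectation by enumerating all sequential draws
  cfg <- scenario_config(pop_size = 8, n_loci = 2, mut_rate = 0, rec_rate = 0,
                         burn_in = 0, generations = 1)
  pop1 <- matrix(c(0.5, 0.5,   0.5, -0.5,  -0.5, 0.5,  -0.5, -0.5),
                 nrow = 4, byrow = TRUE)
  pop2 <- -pop1
  s <- make_split_state(pop1, pop2)
  fit1 <- stabilizing_fitness(phenotypes(s)[1:4], cfg$optima[1], cfg$sel_width)
  w_off <- rep(fit1, each = 2)
  exact <- enum_survivor_sets(w_off, 4)
  exp_mean_fit <- sum(exact$probs * vapply(exact$sets, function(set) {
    mean(w_off[set])
  }, numeric(1)))
  expect_gte(exp_mean_fit, mean(fit1))  # selection response is non-negative
  set.seed(104)
  n_rep <- 1000
  mc <- replicate(n_rep, {
    s2 <- step_generation(s, cfg)
    mean(stabilizing_fitness(phenotypes(s2)[s2$niche == 1L],
                             cfg$optima[1], cfg$sel_width))
  })
  se <- stats::sd(mc) / sqrt(n_rep)
  expect_lt(abs(mean(mc) - exp_mean_fit), 3 * se)
})

test_that("mutation flips fixed-model alleles and leaves absent slots untouched", {
  cfg <- scenario_config(pop_size = 4, n_loci = 3, mut_rate = 1)
  s <- make_split_state(matrix(0.1, 2, 3),
                        matrix(c(0.1, NA, -0.1, NA, 0.1, -0.1), 2, 3))
  s_mut <- mutate_genomes(s, cfg)
  expect_equal(s_mut$effects[!is.na(s$effects)], -s$effects[!is.na(s$effects)])
  expect_identical(s_mut$present, s$present)
  expect_true(all(is.na(s_mut$effects[!s$present])))
  cfg0 <- scenario_config(pop_size = 4, n_loci = 3, mut_rate = 0)
  expect_identical(mutate_genomes(s, cfg0), s)
})

test_that("evolving-model mutation kernel has the configured moments", {
  n <- 1e5
  cfg <- scenario_config(pop_size = n, n_loci = 1, mut_rate = 1,
                         effect_model = "evolving", mut_var = 4e-4)
  s <- new_population_state(matrix(0.1, n, 1), matrix(TRUE, n, 1), rep(0L, n))
  set.seed(105)
  deltas <- mutate_genomes(s, cfg)$effects[, 1]
  se_mean <- sqrt(cfg$mut_var / n)
  expect_lt(abs(mean(deltas) - 0.1), 3 * se_mean)
  se_var <- cfg$mut_var * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(deltas) - cfg$mut_var), 3 * se_var)
})

test_that("allele pools count extant copies with multiplicity within their scope", {
  pop1 <- matrix(c(0.1, 0.1, -0.1, NA, NA, NA), 3, 2)   # locus 2 absent in pop1
  pop2 <- matrix(c(-0.1, -0.1, -0.1, NA, NA, NA), 3, 2) # locus 2 extinct
  s <- make_split_state(pop1, pop2)
  gl <- build_pools(s, "global")
  expect_equal(sort(gl$pools$all[[1]]$values),
               sort(c(0.1, 0.1, -0.1, -0.1, -0.1, -0.1)))
  expect_length(gl$pools$all[[2]]$values, 0)  # extinct locus: empty pool
  lo <- build_pools(s, "local")
  expect_equal(sort(lo$pools[["1"]][[1]]$values), c(-0.1, 0.1, 0.1))
  expect_equal(lo$pools[["2"]][[1]]$values, rep(-0.1, 3))
})

test_that("recombination acquires alleles at pool frequencies and spares absent slots", {
  # pool: 25% at v1, 75% at v2, frozen before any replacement happens
  n <- 2e4
  vals <- c(rep(0.3, n / 4), rep(-0.1, 3 * n / 4))
  s <- new_population_state(matrix(vals, n, 1), matrix(TRUE, n, 1), rep(0L, n))
  cfg <- scenario_config(pop_size = n, n_loci = 1, rec_rate = 1)
  pools <- build_pools(s, "global")
  set.seed(106)
  s2 <- recombine_genomes(s, pools, cfg)
  f <- mean(s2$effects[, 1] == 0.3)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(f - 0.25), 3 * se)
  expect_identical(s2$present, s$present)
  # r = 0 and monomorphic-pool limits
  cfg0 <- scenario_config(pop_size = n, n_loci = 1, rec_rate = 0)
  expect_identical(recombine_genomes(s, pools, cfg0), s)
  s_mono <- make_split_state(matrix(0.7, 2, 1), matrix(0.7, 2, 1))
  s_mix <- make_split_state(matrix(0.7, 2, 1), matrix(-0.7, 2, 1))
  mono_pools <- build_pools(s_mono, "global")
  cfg1 <- scenario_config(pop_size = 4, n_loci = 1, rec_rate = 1)
  expect_true(all(recombine_genomes(s_mix, mono_pools, cfg1)$effects == 0.7))
  # absent slots neither receive...
  s_abs <- make_split_state(matrix(c(0.1, NA), 2, 1), matrix(0.1, 2, 1))
  s_abs2 <- recombine_genomes(s_abs, build_pools(s_abs, "global"), cfg1)
  expect_true(is.na(s_abs2$effects[2, 1]))
  # ...nor donate: pool built from a state with absences excludes them
  expect_length(build_pools(s_abs, "global")$pools$all[[1]]$values, 3)
})

test_that("gene loss empties slots and forced loss zeroes every phenotype", {
  cfg <- scenario_config(pop_size = 4, n_loci = 10, loss_rate = 1)
  s <- make_split_state(matrix(0.1, 2, 10), matrix(0.1, 2, 10))
  s2 <- lose_genes(s, cfg)
  expect_false(any(s2$present))
  expect_equal(phenotypes(s2), rep(0, 4))
  cfg0 <- scenario_config(pop_size = 4, n_loci = 10, loss_rate = 0)
  expect_identical(lose_genes(s, cfg0), s)
  # losing one +0.1 slot of a full 10-locus genome drops the phenotype by 0.1
  s3 <- s
  s3$present[1, 4] <- FALSE
  s3$effects[1, 4] <- NA_real_
  expect_equal(phenotypes(s3)[1], 0.9)
})

test_that("gene gain refills empty slots from extant carriers but never extinct loci", {
  cfg <- scenario_config(pop_size = 4, n_loci = 2, loss_rate = 1e-4,
                         gain_rate = 1, gene_pool = "local", lineage_tags = TRUE)
  pop1 <- matrix(c(0.3, NA, NA, NA), 2, 2)   # locus 1 has one pop1 carrier
  pop2 <- matrix(c(-0.3, -0.3, NA, NA), 2, 2) # locus 2 extinct everywhere
  s <- make_split_state(pop1, pop2)
  s$lineage <- matrix(rep(s$niche, 2), 4, 2)
  s$lineage[!s$present] <- NA_integer_
  set.seed(107)
  s2 <- gain_genes(s, build_pools(s, "local"), cfg)
  # pop1's empty locus-1 slot refilled from its only local carrier
  expect_equal(s2$effects[2, 1], 0.3)
  expect_equal(s2$lineage[2, 1], 1L)
  # pop2 slots only gained pop2 values; extinct locus 2 stays empty
  expect_true(all(is.na(s2$effects[, 2])))
  expect_true(all(s2$lineage[3:4, 1] %in% c(2L, NA)))
  cfg0 <- scenario_config(pop_size = 4, n_loci = 2, loss_rate = 1e-4,
                          gain_rate = 0, gene_pool = "local")
  expect_identical(gain_genes(s, build_pools(s, "local"), cfg0), s)
})

test_that("a generation step conserves sizes, allele closure and mask monotonicity", {
  cfg <- tiny_config(rec_rate = 0.05, loss_rate = 0.02, gain_rate = 0,
                     selection = "divergent")
  set.seed(108)
  state <- split_population(founder_population(cfg), cfg)
  a <- cfg$allele_size
  extant_before <- rep(TRUE, cfg$n_loci)
  for (i in 1:30) {
    state <- step_generation(state, cfg)
    expect_equal(tabulate(state$niche), c(20, 20))
    vals <- state$effects[state$present]
    expect_true(all(vals %in% c(-a, a)))       # fixed-model allele closure
    extant_now <- colSums(state$present) > 0
    expect_true(all(extant_before | !extant_now))  # no resurrection when gain = 0
    extant_before <- extant_now
  }
  expect_equal(state$generation, 30L)
})

test_that("neutral dynamics keep allele frequencies a martingale over one step", {
  cfg <- scenario_config(pop_size = 40, n_loci = 1, mut_rate = 0, rec_rate = 0,
                         selection = "neutral", burn_in = 0, generations = 1)
  q0 <- 0.3
  eff <- matrix(c(rep(0.1, 12), rep(-0.1, 28)), 40, 1)
  s <- new_population_state(eff, matrix(TRUE, 40, 1), rep(0L, 40))
  set.seed(109)
  n_rep <- 4000
  freqs <- replicate(n_rep, mean(step_generation(s, cfg)$effects[, 1] == 0.1))
  se <- stats::sd(freqs) / sqrt(n_rep)
  expect_lt(abs(mean(freqs) - q0), 3 * se)
})

test_that("runs are reproducible and burn-in applies mutation only", {
  cfg <- tiny_config(rec_rate = 0.05, loss_rate = 0.01, gain_rate = 0.01,
                     seed = 11L)
  sim1 <- run_simulation(cfg)
  sim2 <- run_simulation(cfg)
  expect_identical(sim1$state, sim2$state)
  expect_identical(sim1$records, sim2$records)
  # no loss can have occurred during burn-in: run burn-in only
  cfg_burn <- tiny_config(loss_rate = 0.5, gain_rate = 0, generations = 0,
                          seed = 12L)
  sim_b <- run_simulation(cfg_burn)
  expect_equal(sim_b$records$pct_missing[1], 0)
  expect_equal(nrow(sim_b$records), 1L)  # endpoint record of the split state
})

test_that("local gene pools permit no cross-niche descent (lineage isolation)", {
  cfg <- tiny_config(rec_rate = 0.2, loss_rate = 0.02, gain_rate = 0.05,
                     gene_pool = "local", lineage_tags = TRUE, seed = 13L,
                     generations = 60)
  sim <- run_simulation(cfg, record = FALSE)
  tags <- sim$state$lineage
  niche <- sim$state$niche
  expect_true(all(tags[niche == 1L, ] %in% c(1L, NA)))
  expect_true(all(tags[niche == 2L, ] %in% c(2L, NA)))
  # and the same run with a global pool does import foreign copies
  cfg_g <- tiny_config(rec_rate = 0.2, loss_rate = 0.02, gain_rate = 0.05,
                       gene_pool = "global", lineage_tags = TRUE, seed = 13L,
                       generations = 60)
  sim_g <- run_simulation(cfg_g, record = FALSE)
  expect_gt(sum(sim_g$state$lineage[sim_g$state$niche == 1L, ] == 2L,
                na.rm = TRUE), 0)
})
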