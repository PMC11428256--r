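# small planted instance used throughout: 60 genes x 20 samples with an
# 8 x 8 noise-free planted block
small_instance <- function(seed = 1, noise_sd = 0) {
  simulate_planted_matrix(planted_module_spec(
    num_genes = 60, num_samples = 20, module_genes = 8, module_samples = 8,
    noise_sd = noise_sd, rng_seed = seed))
}

fast_ga <- function(...) {
  defaults <- list(population_size = 20, max_generations = 40,
                   num_restarts = 3, discriminating_size = 5)
  do.call(ga_params, utils::modifyList(defaults, list(...)))
}

test_that("population initialization is valid, uniform-range and reproducible", {
  sim <- small_instance()
  disc <- discretize(sim$values)
  p <- fast_ga()
  set.seed(1)
  pop1 <- initialize_population(disc, p)
  set.seed(1)
  pop2 <- initialize_population(disc, p)
  expect_identical(pop1, pop2)
  expect_length(pop1, p$population_size)
  for (ch in pop1) {
    expect_length(ch$genotype, 5)
    expect_false(anyDuplicated(ch$genotype) > 0)
    expect_true(all(ch$genotype >= 1 & ch$genotype <= 20))
    expect_true(is.na(ch$fitness))
  }
})

test_that("s_d covering all samples forces D to be the whole sample set", {
  x <- random_matrix(5, 3, seed = 2)
  disc <- discretize(x, 2)
  set.seed(2)
  pop <- initialize_population(disc, fast_ga(discriminating_size = 3))
  for (ch in pop) expect_setequal(ch$genotype, 1:3)
})

test_that("fitness is the size-adjusted msr of the induced module", {
  sim <- small_instance()
  disc <- discretize(sim$values)
  tm <- sim$truth$modules[[1]]
  geno <- tm$sample_index[1:5]
  mod <- build_module(disc, geno[1], geno, sim$values)
  fit <- evaluate_fitness(geno, disc, sim$values, alpha = 0.05, conf = 1e-6)
  expect_true(is.finite(fit))
  # independently recompute: raw msr over (genes of G) x C, then adjust
  h <- msr_oracle(sim$values, mod$genes, mod$samples)
  df <- (mod$n_genes - 1) * (mod$n_samples - 1)
  expect_equal(fit, h * mod$n_genes * mod$n_samples / qchisq(1e-6, df))
})

test_that("filtered modules receive the sentinel fitness", {
  sim <- small_instance()
  disc <- discretize(sim$values)
  tm <- sim$truth$modules[[1]]
  geno <- tm$sample_index[1:5]
  # alpha so high that the planted module's 8 samples cannot cover it
  expect_identical(evaluate_fitness(geno, disc, sim$values, alpha = 0.9), Inf)
  # min_genes above the planted gene count
  expect_identical(
    evaluate_fitness(geno, disc, sim$values, min_genes = 50L), Inf)
})

test_that("evolution without operators preserves genotypes and best fitness", {
  sim <- small_instance()
  disc <- discretize(sim$values)
  p <- fast_ga(crossover_prob = 0, mutation_prob = 0, rng_seed = NULL)
  set.seed(3)
  pop <- initialize_population(disc, p)
  pop <- lapply(pop, function(ch) {
    ch$fitness <- evaluate_fitness(ch, disc, sim$values)
    ch
  })
  nxt <- evolve_generation(pop, p, 20)
  expect_length(nxt, length(pop))
  old_genos <- vapply(pop, function(ch) paste(ch$genotype, collapse = ","),
                      character(1))
  for (ch in nxt)
    expect_true(paste(ch$genotype, collapse = ",") %in% old_genos)
  expect_equal(min(vapply(nxt, function(ch) ch$fitness, numeric(1))),
               min(vapply(pop, function(ch) ch$fitness, numeric(1))))
})

test_that("elitism never lets the best fitness regress", {
  sim <- small_instance()
  disc <- discretize(sim$values)
  p <- fast_ga()
  set.seed(4)
  pop <- initialize_population(disc, p)
  pop <- lapply(pop, function(ch) {
    ch$fitness <- evaluate_fitness(ch, disc, sim$values)
    ch
  })
  before <- min(vapply(pop, function(ch) ch$fitness, numeric(1)))
  for (g in 1:3) {
    pop <- evolve_generation(pop, p, 20)
    pop <- lapply(pop, function(ch) {
      if (is.na(ch$fitness))
        ch$fitness <- evaluate_fitness(ch, disc, sim$values)
      ch
    })
    after <- min(vapply(pop, function(ch) ch$fitness, numeric(1)))
    expect_lte(after, before)
    before <- after
  }
})

test_that("offspring genotypes stay valid under crossover and mutation", {
  sim <- small_instance()
  disc <- discretize(sim$values)
  p <- fast_ga(crossover_prob = 1, mutation_prob = 0.5)
  set.seed(5)
  pop <- initialize_population(disc, p)
  pop <- lapply(pop, function(ch) { ch$fitness <- 1; ch })
  for (g in 1:5) {
    pop <- evolve_generation(pop, p, 20)
    for (ch in pop) {
      expect_length(ch$genotype, 5)
      expect_false(anyDuplicated(ch$genotype) > 0)
      expect_true(all(ch$genotype >= 1 & ch$genotype <= 20))
    }
    pop <- lapply(pop, function(ch) { ch$fitness <- 1; ch })
  }
})

test_that("the GA recovers a noise-free planted module exactly", {
  sim <- small_instance(seed = 7)
  disc <- discretize(sim$values)
  res <- run_cgemga(disc, sim$values, fast_ga(rng_seed = 7))
  expect_gt(length(res$modules), 0)
  best <- res$modules[[1]]
  rec <- recovery_score(best, sim$truth)
  expect_equal(unname(rec), c(1, 1))
  expect_lt(best$msr, 1e-20)
})

test_that("the convergence trace is non-increasing and bounded", {
  sim <- small_instance(seed = 8)
  disc <- discretize(sim$values)
  p <- fast_ga(rng_seed = 8)
  res <- run_cgemga(disc, sim$values, p)
  tr <- res$trace$best_fitness
  expect_lte(length(tr), p$max_generations + 1)
  expect_true(all(diff(tr[is.finite(tr)]) <= 0))
  expect_true(all(diff(tr) <= 0 | is.infinite(tr[-length(tr)])))
  conv <- res$trace$convergence_generation
  expect_gte(conv, 0)
  expect_equal(tr[conv + 1], tr[length(tr)])
  if (conv > 0) expect_gt(tr[conv], tr[conv + 1])
})

test_that("identical seeds give identical results", {
  sim <- small_instance(seed = 9)
  disc <- discretize(sim$values)
  r1 <- run_cgemga(disc, sim$values, fast_ga(rng_seed = 11))
  r2 <- run_cgemga(disc, sim$values, fast_ga(rng_seed = 11))
  expect_identical(r1$modules, r2$modules)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$evaluations, r2$evaluations)
})

test_that("the best module dominates every chromosome its restart evaluated", {
  sim <- small_instance(seed = 10)
  disc <- discretize(sim$values)
  res <- run_cgemga(disc, sim$values, fast_ga(rng_seed = 10))
  best_fit <- min(vapply(res$restarts, function(r) r$best$fitness,
                         numeric(1)))
  # the pooled winner carries the overall minimum fitness
  b <- res$modules[[1]]
  expect_equal(
    corrected_fit <- evaluate_fitness(b$seed$disc_set, disc, sim$values,
                                      conf = 0.05 / (3 * 20 * 41)),
    best_fit)
})

test_that("without variation the GA degenerates to random multistart", {
  sim <- small_instance(seed = 12)
  disc <- discretize(sim$values)
  p <- fast_ga(crossover_prob = 0, mutation_prob = 0, rng_seed = 12,
               max_generations = 5)
  res <- run_cgemga(disc, sim$values, p)
  # winner must be at least as good as the best initial chromosome of some
  # restart; with no operators it is exactly the best initial chromosome
  for (r in res$restarts) {
    expect_equal(r$best$fitness, r$trace[1])
    expect_true(all(r$trace == r$trace[1]))
  }
})

test_that("a search in which every module is filtered warns and returns empty", {
  x <- random_matrix(10, 8, seed = 13)
  disc <- discretize(x, 3)
  p <- fast_ga(alpha = 1, rng_seed = 13, num_restarts = 2,
               max_generations = 3)
  expect_warning(res <- run_cgemga(disc, x, p), "discarded")
  expect_length(res$modules, 0)
  expect_false(is.null(res$warning))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(ga_params(population_size = 1), "population_size")
  expect_error(ga_params(elitism_count = 50, population_size = 50),
               "elitism_count")
  expect_error(ga_params(crossover_prob = 1.2), "crossover_prob")
  expect_error(ga_params(alpha = 0), "alpha")
})
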