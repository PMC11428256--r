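#' Parameters for the CGEMGA genetic-algorithm search
#'
#' A chromosome encodes a seed as a fixed-length, duplicate-free integer
#' vector of sample indices `[c, d_2, ..., d_sd]`; the first position is
#' the seed sample c and the whole vector is the discriminating set D
#' (c is a member of D). Fitness is the size-adjusted MSR of the induced
#' conserved module (see [run_cgemga()] for the adjustment and its
#' rationale), with a `+Inf` sentinel for modules discarded by the
#' filters.
#'
#' @param population_size chromosomes per generation n (>= 2).
#' @param max_generations generation cap MAX per restart.
#' @param crossover_prob probability of single-point crossover per pair.
#' @param mutation_prob per-locus probability of resampling a sample index
#'   uniformly among indices not already in the chromosome.
#' @param elitism_count number of lowest-fitness chromosomes copied
#'   unchanged into the next generation (>= 1, < population_size).
#' @param tournament_size tournament size for selection (lower fitness
#'   wins; ties by larger module area |G| x |C|).
#' @param alpha minimum matched-sample fraction, as in [search_params()].
#' @param discriminating_size seed set size s_d.
#' @param num_restarts independent GA restarts n_s; the final module list
#'   pools the per-restart winners.
#' @param min_genes modules with fewer conserved genes are discarded
#'   (sentinel fitness). Single-gene modules have MSR identically 0 by
#'   algebra, so they are degenerate optima of the fitness and carry no
#'   co-expression signal; 2 is the smallest informative module.
#' @param patience restart stops early after this many generations without
#'   improvement of the best fitness.
#' @param rng_seed optional integer seed for full reproducibility.
#' @return validated parameter list of class `ga_params`.
#' @export
ga_params <- function(population_size = 50L, max_generations = 100L,
                      crossover_prob = 0.8, mutation_prob = 0.1,
                      elitism_count = 1L, tournament_size = 3L,
                      alpha = 0.05, discriminating_size = 7L,
                      num_restarts = 10L, min_genes = 2L,
                      patience = 10L, rng_seed = NULL) {
  population_size <- as.integer(population_size)
  max_generations <- as.integer(max_generations)
  elitism_count <- as.integer(elitism_count)
  if (is.na(population_size) || population_size < 2L)
    stop("population_size must be >= 2")
  if (is.na(max_generations) || max_generations < 1L)
    stop("max_generations must be >= 1")
  if (crossover_prob < 0 || crossover_prob > 1)
    stop("crossover_prob must lie in [0, 1]")
  if (mutation_prob < 0 || mutation_prob > 1)
    stop("mutation_prob must lie in [0, 1]")
  if (elitism_count < 1L || elitism_count >= population_size)
    stop("elitism_count must satisfy 1 <= elitism_count < population_size")
  if (tournament_size < 2L) stop("tournament_size must be >= 2")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(population_size = population_size,
                 max_generations = max_generations,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism_count = elitism_count,
                 tournament_size = as.integer(tournament_size),
                 alpha = alpha,
                 discriminating_size = as.integer(discriminating_size),
                 num_restarts = as.integer(num_restarts),
                 min_genes = as.integer(min_genes),
                 patience = as.integer(patience),
                 rng_seed = rng_seed),
            class = "ga_params")
}

new_chromosome <- function(genotype, fitness = NA_real_, module = NULL) {
  list(genotype = as.integer(genotype), fitness = fitness, module = module)
}

#' Initialize a random GA population
#'
#' Each chromosome's genotype is a uniformly random valid seed: a seed
#' sample plus s_d - 1 further distinct sample indices. Fitness is left
#' unevaluated. Uses the current RNG state.
#'
#' @param disc a `discretized_matrix`.
#' @param params a [ga_params()] list.
#' @return list of `population_size` chromosomes.
#' @export
initialize_population <- function(disc, params) {
  m_tot <- ncol(disc$states)
  s_d <- min(params$discriminating_size, m_tot)
  lapply(seq_len(params$population_size), function(i) {
    new_chromosome(sample.int(m_tot, s_d))
  })
}

#' Fitness of a chromosome: size-adjusted MSR of its induced module
#'
#' Builds the conserved module of the encoded seed and returns its
#' size-adjusted MSR computed on the continuous values — the upper
#' confidence bound of the residual variance, `MSR |I||J| /
#' qchisq(conf, (|I|-1)(|J|-1))` — or the `+Inf` sentinel when the module
#' is filtered out: empty G, fewer than `min_genes` conserved genes, or
#' matched samples covering less than `alpha` of the samples. At fixed
#' module size the ordering is exactly the MSR ordering; across sizes the
#' adjustment removes the systematic advantage of small submatrices,
#' whose raw MSR has expectation `sigma^2 (1-1/|I|)(1-1/|J|)` under an
#' additive model with noise variance `sigma^2` and an estimation spread
#' that grows as the residual degrees of freedom shrink.
#'
#' @param chromosome a chromosome (or a bare integer genotype).
#' @param disc a `discretized_matrix`.
#' @param values expression matrix.
#' @param alpha matched-sample fraction threshold.
#' @param min_genes minimum conserved-gene count (default 2).
#' @param conf level of the chi-square upper confidence bound used to
#'   size-adjust the MSR (see Details of [run_cgemga()]); [run_cgemga()]
#'   sets it to 0.05 divided by its evaluation budget.
#' @return a single nonnegative number, possibly `Inf`.
#' @export
evaluate_fitness <- function(chromosome, disc, values, alpha = 0.05,
                             min_genes = 2L, conf = 1e-6) {
  geno <- if (is.list(chromosome)) chromosome$genotype else as.integer(chromosome)
  eval_genotype(geno, disc, values, alpha, min_genes,
                alpha_m = ncol(disc$states), conf = conf)$fitness
}

# internal: fitness plus the module it came from.
# Fitness is the size-adjusted MSR: under an additive-plus-noise model the
# raw MSR has expectation sigma^2 (1 - 1/|I|)(1 - 1/|J|) and a sampling
# spread that grows as the residual degrees of freedom shrink, so directly
# minimizing raw MSR over variable-size modules collapses onto tiny
# submatrices. The fitness is instead the upper 95% confidence bound of
# the residual variance, SS / chisq_{0.05}(df) with SS = MSR |I||J| and
# df = (|I|-1)(|J|-1): an ordering identical to MSR at fixed module size,
# but fair across sizes. Modules report the raw MSR.
eval_genotype <- function(geno, disc, values, alpha, min_genes, alpha_m,
                          conf = 1e-6) {
  mod <- build_module(disc, geno[1L], geno, values)
  fit <- if (mod$n_genes < max(1L, min_genes) ||
             mod$n_samples < alpha * alpha_m) Inf
  else corrected_msr(mod$msr, mod$n_genes, mod$n_samples, conf)
  list(fitness = fit, module = mod)
}

# size-adjusted MSR (upper confidence bound of the residual variance);
# single-row or single-column modules have no residual degrees of freedom
# (raw MSR identically 0) and map to the sentinel. The default level is
# Bonferroni-adjusted for the ~5e4 candidate modules a default search
# examines, because the search takes a minimum over that many estimates.
corrected_msr <- function(h, n_genes, n_samples, conf = 1e-6) {
  df <- (n_genes - 1) * (n_samples - 1)
  if (df < 1) return(Inf)
  h * n_genes * n_samples / stats::qchisq(conf, df)
}

# lower fitness wins; ties broken toward the larger module area
chrom_beats <- function(a, b) {
  if (a$fitness != b$fitness) return(a$fitness < b$fitness)
  sa <- if (is.null(a$module)) 0 else a$module$size
  sb <- if (is.null(b$module)) 0 else b$module$size
  sa > sb
}

tournament_pick <- function(population, k) {
  idx <- sample.int(length(population), min(k, length(population)))
  best <- idx[1L]
  for (i in idx[-1L])
    if (chrom_beats(population[[i]], population[[best]])) best <- i
  population[[best]]
}

# replace duplicate loci with random unused sample indices
repair_genotype <- function(geno, m_tot) {
  dup <- duplicated(geno)
  if (any(dup)) {
    pool <- setdiff(seq_len(m_tot), geno)
    geno[dup] <- pool[sample.int(length(pool), sum(dup))]
  }
  geno
}

mutate_genotype <- function(geno, m_tot, mutation_prob) {
  hit <- which(stats::runif(length(geno)) < mutation_prob)
  for (p in hit) {
    pool <- setdiff(seq_len(m_tot), geno)
    if (length(pool) == 0L) break
    geno[p] <- pool[sample.int(length(pool), 1L)]
  }
  geno
}

#' Produce the next GA generation
#'
#' Elites (lowest fitness) are copied unchanged; the remainder is filled by
#' tournament selection of parent pairs, single-point crossover on the
#' genotype with probability `crossover_prob`, per-locus mutation with
#' probability `mutation_prob`, and repair of any duplicate indices.
#' Offspring fitness is left unevaluated (`NA`). Population size is
#' preserved. Uses the current RNG state.
#'
#' @param population list of chromosomes with evaluated fitness.
#' @param params a [ga_params()] list.
#' @param m_tot total number of samples (genotype index range).
#' @return list of chromosomes, the same length as `population`.
#' @export
evolve_generation <- function(population, params, m_tot) {
  n <- length(population)
  ord <- order(vapply(population, function(ch) ch$fitness, numeric(1L)))
  elites <- population[ord[seq_len(params$elitism_count)]]
  offspring <- list()
  L <- length(population[[1L]]$genotype)
  while (length(offspring) < n - params$elitism_count) {
    p1 <- tournament_pick(population, params$tournament_size)
    p2 <- tournament_pick(population, params$tournament_size)
    g1 <- p1$genotype
    g2 <- p2$genotype
    crossed <- FALSE
    if (L > 1L && stats::runif(1L) < params$crossover_prob) {
      cut <- sample.int(L - 1L, 1L)
      h1 <- c(g1[seq_len(cut)], g2[(cut + 1L):L])
      h2 <- c(g2[seq_len(cut)], g1[(cut + 1L):L])
      g1 <- h1
      g2 <- h2
      crossed <- TRUE
    }
    for (g in list(g1, g2)) {
      if (length(offspring) >= n - params$elitism_count) break
      mutated <- mutate_genotype(g, m_tot, params$mutation_prob)
      changed <- crossed || !identical(mutated, g)
      geno <- repair_genotype(mutated, m_tot)
      offspring[[length(offspring) + 1L]] <-
        if (!changed && identical(geno, p1$genotype)) p1
        else if (!changed && identical(geno, p2$genotype)) p2
        else new_chromosome(geno)
    }
  }
  c(elites, offspring)
}

#' Run the CGEMGA search
#'
#' Runs `num_restarts` independent GA restarts. Each restart creates a
#' random population of seed chromosomes, evaluates the MSR fitness of the
#' module each seed induces, and evolves the population (tournament
#' selection, single-point crossover, per-locus mutation, elitism) until
#' `max_generations` or until the best fitness has stalled for `patience`
#' generations. The restart's winner is the lowest-fitness module over
#' every chromosome it evaluated (ties toward the larger |G| x |C| area),
#' where fitness is the size-adjusted MSR of [evaluate_fitness()] at a
#' confidence level Bonferroni-adjusted for the run's evaluation budget.
#' The final module list pools the restart winners in ascending fitness
#' order (ties by area, then by earlier convergence), and the convergence
#' trace of the best restart is reported.
#'
#' @param disc a `discretized_matrix`.
#' @param values the expression matrix the discretization came from.
#' @param params a [ga_params()] list.
#' @return object of class `cgemga_result`: `modules` (restart winners,
#'   best first), `trace` (list: `best_fitness` per generation, including
#'   generation 0, and `convergence_generation`, the first generation
#'   attaining the final best), `evaluations` (total fitness evaluations),
#'   `restarts` (per-restart summaries), `params`. When every restart is
#'   discarded, `modules` is empty and a warning is recorded in `warning`.
#' @export
run_cgemga <- function(disc, values, params = ga_params()) {
  stopifnot(inherits(disc, "discretized_matrix"))
  validate_expression_matrix(values)
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  m_tot <- ncol(disc$states)
  # Bonferroni level for the size-adjusted fitness: the search minimizes
  # over (up to) this many candidate modules
  conf <- 0.05 / (params$num_restarts * params$population_size *
                    (params$max_generations + 1L))
  evaluations <- 0L
  restarts <- list()
  for (r in seq_len(params$num_restarts)) {
    pop <- initialize_population(disc, params)
    pop <- lapply(pop, function(ch) {
      ev <- eval_genotype(ch$genotype, disc, values, params$alpha,
                          params$min_genes, m_tot, conf)
      new_chromosome(ch$genotype, ev$fitness, ev$module)
    })
    evaluations <- evaluations + length(pop)
    best <- pop[[1L]]
    for (ch in pop[-1L]) if (chrom_beats(ch, best)) best <- ch
    trace <- best$fitness
    stall <- 0L
    t <- 0L
    while (t < params$max_generations && stall < params$patience) {
      pop <- evolve_generation(pop, params, m_tot)
      for (i in seq_along(pop)) {
        if (is.na(pop[[i]]$fitness)) {
          ev <- eval_genotype(pop[[i]]$genotype, disc, values, params$alpha,
                              params$min_genes, m_tot, conf)
          pop[[i]]$fitness <- ev$fitness
          pop[[i]]$module <- ev$module
          evaluations <- evaluations + 1L
        }
      }
      improved <- FALSE
      for (ch in pop) if (chrom_beats(ch, best)) { best <- ch; improved <- TRUE }
      gen_best <- pop[[1L]]
      for (ch in pop[-1L]) if (chrom_beats(ch, gen_best)) gen_best <- ch
      trace <- c(trace, gen_best$fitness)
      stall <- if (improved) 0L else stall + 1L
      t <- t + 1L
    }
    conv <- which(trace == trace[length(trace)])[1L] - 1L
    restarts[[r]] <- list(best = best, trace = trace,
                          convergence_generation = conv,
                          generations = t, discarded = !is.finite(best$fitness))
  }
  kept <- Filter(function(rr) !rr$discarded, restarts)
  warning_msg <- NULL
  if (length(kept) == 0L) {
    warning_msg <- "all restarts discarded: no module passed the alpha/min_genes filters"
    warning(warning_msg)
    modules <- list()
    trace_out <- list(best_fitness = numeric(0L),
                      convergence_generation = NA_integer_)
  } else {
    # rank restart winners: lower MSR, then larger area, then earlier convergence
    ord <- order(vapply(kept, function(rr) rr$best$fitness, numeric(1L)),
                 -vapply(kept, function(rr) rr$best$module$size, numeric(1L)),
                 vapply(kept, function(rr) rr$convergence_generation, numeric(1L)))
    kept <- kept[ord]
    modules <- lapply(kept, function(rr) rr$best$module)
    trace_out <- list(best_fitness = kept[[1L]]$trace,
                      convergence_generation = kept[[1L]]$convergence_generation)
  }
  structure(list(modules = modules, trace = trace_out,
                 evaluations = evaluations, restarts = restarts,
                 params = params, warning = warning_msg),
            class = "cgemga_result")
}

#' @export
print.cgemga_result <- function(x, ...) {
  cat("cgemga_result: ", length(x$modules), " module(s) from ",
      length(x$restarts), " restart(s), ", x$evaluations,
      " fitness evaluations\n", sep = "")
  if (length(x$modules)) {
    b <- x$modules[[1L]]
    cat("  best: |G| = ", b$n_genes, ", |C| = ", b$n_samples,
        ", MSR = ", format(b$msr, digits = 4),
        " (converged at generation ", x$trace$convergence_generation,
        ")\n", sep = "")
  }
  invisible(x)
}
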