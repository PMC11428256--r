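#' Serialize discovered modules to JSON and TSV
#'
#' Writes `<prefix>_modules.json` (full records: gene ids with states,
#' sample ids, sizes, MSR, seed), `<prefix>_genes.tsv` (module, gene id,
#' state) and `<prefix>_samples.tsv` (module, sample id).
#'
#' @param modules list of `conserved_module` objects.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
write_modules <- function(modules, out_dir, prefix = "run") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    list(module = i, n_genes = m$n_genes, n_samples = m$n_samples,
         msr = m$msr, genes = m$gene_ids, states = m$states,
         samples = m$sample_ids, seed = m$seed)
  })
  json_path <- file.path(out_dir, paste0(prefix, "_modules.json"))
  jsonlite::write_json(records, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  genes_path <- file.path(out_dir, paste0(prefix, "_genes.tsv"))
  gene_rows <- do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    if (m$n_genes == 0L) return(NULL)
    data.frame(module = i, gene = m$gene_ids, state = m$states)
  }))
  if (is.null(gene_rows))
    gene_rows <- data.frame(module = integer(0L), gene = character(0L),
                            state = integer(0L))
  utils::write.table(gene_rows, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  samples_path <- file.path(out_dir, paste0(prefix, "_samples.tsv"))
  sample_rows <- do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    if (m$n_samples == 0L) return(NULL)
    data.frame(module = i, sample = m$sample_ids)
  }))
  if (is.null(sample_rows))
    sample_rows <- data.frame(module = integer(0L), sample = character(0L))
  utils::write.table(sample_rows, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, genes = genes_path, samples = samples_path))
}

#' Read modules back from a `<prefix>_modules.json` file
#'
#' @param path the JSON written by [write_modules()].
#' @return list of module records (lists with `genes`, `samples`, `msr`, ...).
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) stop("modules file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Run a biclustering search end to end and write its artifacts
#'
#' Loads the expression matrix, discretizes it, runs the selected
#' algorithm, and writes module JSON/TSV exports, the convergence trace
#' (CGEMGA) and a metadata record holding the full configuration and seed
#' so the run can be reproduced exactly.
#'
#' @param input path to the expression matrix (TSV/CSV).
#' @param out_dir output directory.
#' @param algorithm `"cgemga"` (genetic algorithm, the default) or
#'   `"cgem"` (baseline multistart with iterative sample removal).
#' @param num_states discretization states q.
#' @param method discretization method (see [discretize()]).
#' @param ga a [ga_params()] list (used when `algorithm = "cgemga"`).
#' @param search a [search_params()] list (used when `algorithm = "cgem"`).
#' @param max_modules cap on extracted modules for the baseline.
#' @param seed integer RNG seed recorded in the metadata and applied to
#'   the run (overrides any seed inside `ga`/`search`).
#' @return the search result (`cgemga_result` or `cgem_result`),
#'   invisibly, with an `artifacts` attribute listing written files.
#' @export
run_search <- function(input, out_dir, algorithm = c("cgemga", "cgem"),
                       num_states = 3L, method = "equal_width",
                       ga = ga_params(), search = search_params(),
                       max_modules = 10L, seed = NULL) {
  algorithm <- match.arg(algorithm)
  values <- read_expression_matrix(input)
  disc <- discretize(values, num_states = num_states, method = method)
  message("matrix: ", nrow(values), " genes x ", ncol(values),
          " samples; q = ", num_states, " (", method, "); algorithm = ",
          algorithm)
  if (!is.null(seed)) {
    ga$rng_seed <- seed
    search$rng_seed <- seed
  }
  if (algorithm == "cgemga") {
    res <- run_cgemga(disc, values, ga)
    modules <- res$modules
    config <- unclass(ga)
  } else {
    res <- extract_biclusters(disc, values, search, max_modules = max_modules)
    modules <- res$modules
    config <- c(unclass(search), max_modules = max_modules)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_modules(modules, out_dir, prefix = algorithm)
  if (algorithm == "cgemga" && length(res$trace$best_fitness)) {
    trace_path <- file.path(out_dir, "trace.tsv")
    utils::write.table(
      data.frame(generation = seq_along(res$trace$best_fitness) - 1L,
                 best_fitness = res$trace$best_fitness),
      trace_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, trace = trace_path)
  }
  meta <- list(input = input, algorithm = algorithm,
               num_states = num_states, method = method,
               config = config, seed = seed,
               n_genes = nrow(values), n_samples = ncol(values),
               n_modules = length(modules),
               best_msr = if (length(modules)) modules[[1L]]$msr else NA,
               package_version = as.character(utils::packageVersion("cgemga")))
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (length(modules) == 0L)
    message("no module survived the filters; empty result written")
  else
    message("best module: |G| = ", modules[[1L]]$n_genes, ", |C| = ",
            modules[[1L]]$n_samples, ", MSR = ",
            format(modules[[1L]]$msr, digits = 4))
  attr(res, "artifacts") <- c(paths, metadata = meta_path)
  invisible(res)
}

#' Evaluate discovered modules against a driver-gene census
#'
#' Builds the 2x2 contingency of found genes (union over the run's
#' modules) against the census within the gene universe, runs Fisher's
#' exact test, and writes a per-run report. With several module files
#' (independent runs) a mean +/- sd summary row is added.
#'
#' @param modules_paths character vector of `*_modules.json` paths, one
#'   per run.
#' @param census_path plain-text census file (see [read_census()]).
#' @param universe character vector of all gene ids the searches could
#'   have found, or the path of the expression matrix to take them from.
#' @param out_path optional TSV report path.
#' @param alternative sidedness of the test (default `"greater"`).
#' @return a data.frame with per-run a, b, c, d, p, msr and significance
#'   flag; the [summarize_runs()] object as attribute `summary`.
#' @export
run_evaluate <- function(modules_paths, census_path, universe,
                         out_path = NULL,
                         alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  census <- read_census(census_path)
  if (is.character(universe) && length(universe) == 1L &&
      file.exists(universe))
    universe <- rownames(read_expression_matrix(universe))
  rows <- lapply(modules_paths, function(p) {
    mods <- read_modules(p)
    found <- unique(unlist(lapply(mods, function(m) m$genes)))
    if (is.null(found)) found <- character(0L)
    tab <- build_contingency(found, census, universe)
    pval <- if (tab$r == 0L) 1 else fisher_exact(tab, alternative)
    msrs <- vapply(mods, function(m) as.numeric(m$msr), numeric(1L))
    data.frame(run = p, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               p_value = pval,
               msr = if (length(msrs)) min(msrs) else NA_real_,
               significant = pval < 0.05)
  })
  report <- do.call(rbind, rows)
  summary <- summarize_runs(report$p_value, report$msr)
  if (!is.null(out_path)) {
    utils::write.table(report, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cat("# summary\tp: ", summary$p_formatted, "\tMSR: ",
        summary$msr_formatted, "\n", sep = "", file = out_path,
        append = TRUE)
  }
  attr(report, "summary") <- summary
  report
}

#' Generate and write a synthetic planted-module fixture
#'
#' Writes the expression matrix TSV, the ground-truth JSON and the census
#' text file — exactly the formats the pipeline consumes.
#'
#' @param spec a [planted_module_spec()] (or path to a YAML file with its
#'   fields).
#' @param out_dir output directory.
#' @param extra_decoys decoy genes added to the census.
#' @return named character vector of paths, invisibly.
#' @export
run_simulate <- function(spec, out_dir, extra_decoys = 0L) {
  if (is.character(spec)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a spec file requires the yaml package")
    spec <- do.call(planted_module_spec, yaml::read_yaml(spec))
  }
  sim <- simulate_planted_matrix(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  matrix_path <- file.path(out_dir, "matrix.tsv")
  write_expression_matrix(sim$values, matrix_path)
  truth_path <- file.path(out_dir, "truth.json")
  truth <- sim$truth
  truth$states <- NULL  # keep the JSON small; states are reproducible from spec
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  census_path <- file.path(out_dir, "census.txt")
  writeLines(c("# synthetic driver-gene census (planted genes + decoys)",
               make_census(sim$truth, extra_decoys = extra_decoys)),
             census_path)
  invisible(c(matrix = matrix_path, truth = truth_path, census = census_path))
}

#' Budget-matched comparison of CGEMGA against the CGEM baseline
#'
#' On `instances` independently simulated planted-module matrices, runs
#' CGEMGA, counts its fitness evaluations, and gives the CGEM multistart
#' the same number of random seeds. Reports each method's best-module MSR
#' per instance — the synthetic analogue of a stability comparison across
#' independent runs.
#'
#' @param instances number of simulated instances.
#' @param spec a [planted_module_spec()] used for every instance (its
#'   `rng_seed` is overridden per instance).
#' @param ga a [ga_params()] list.
#' @param base_seed integer; instance i uses seed `base_seed + i` for both
#'   the generator and the searches.
#' @param num_states,method discretization settings.
#' @return data.frame with one row per instance: `cgemga_msr`,
#'   `cgem_msr`, `evaluations`, and the Jaccard recovery of each method's
#'   best module.
#' @export
benchmark_methods <- function(instances = 10L,
                              spec = planted_module_spec(noise_sd = 0.25),
                              ga = ga_params(), base_seed = 0L,
                              num_states = NULL, method = "equal_width") {
  if (is.null(num_states)) num_states <- spec$num_states
  rows <- lapply(seq_len(instances), function(i) {
    spec$rng_seed <- base_seed + i
    sim <- simulate_planted_matrix(spec)
    disc <- discretize(sim$values, num_states = num_states, method = method)
    ga$rng_seed <- base_seed + i
    res_ga <- run_cgemga(disc, sim$values, ga)
    ga_mod <- if (length(res_ga$modules)) res_ga$modules[[1L]] else NULL
    ga_rec <- recovery_score(ga_mod, sim$truth)
    sp <- search_params(num_seeds = res_ga$evaluations,
                        discriminating_size = ga$discriminating_size,
                        alpha = ga$alpha, rng_seed = base_seed + i)
    cgem_mod <- find_largest_module(disc, sim$values, sp)
    cgem_rec <- recovery_score(cgem_mod, sim$truth)
    data.frame(instance = i,
               cgemga_msr = if (is.null(ga_mod)) NA_real_ else ga_mod$msr,
               cgem_msr = if (is.null(cgem_mod)) NA_real_ else cgem_mod$msr,
               evaluations = res_ga$evaluations,
               cgemga_gene_jaccard = ga_rec[["gene_jaccard"]],
               cgemga_sample_jaccard = ga_rec[["sample_jaccard"]],
               cgem_gene_jaccard = cgem_rec[["gene_jaccard"]],
               cgem_sample_jaccard = cgem_rec[["sample_jaccard"]])
  })
  do.call(rbind, rows)
}
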