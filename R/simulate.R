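#' Specification of a planted-module synthetic expression matrix
#'
#' The generator emulates the structure the conserved-module model assumes:
#' a background of per-gene uniform expression states, plus one planted
#' block of genes that hold a single fixed state across a subset of
#' samples. States live on a log-expression-like scale with centers
#' `state_separation` apart (default 2, i.e. a four-fold change between
#' adjacent states on a log2 scale). Background cells are uniform within
#' their state's interval. Planted continuous values are additive —
#' state center + a per-gene offset + a per-sample offset (each uniform on
#' `+/- effect_range`) + Gaussian noise — so the planted block has MSR 0
#' at `noise_sd = 0` and the MSR fitness optimum coincides with the
#' planted truth.
#'
#' @param num_genes,num_samples matrix dimensions.
#' @param module_genes,module_samples planted block dimensions.
#' @param num_states number of states q (>= 2).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   planted block's continuous values.
#' @param background `"uniform_states"`: per-cell states drawn uniformly;
#'   `"shuffled"`: per gene, a balanced state vector (each state equally
#'   often, up to rounding) in shuffled sample order.
#' @param state_separation distance between adjacent state centers.
#' @param effect_range half-width of the per-gene / per-sample additive
#'   offsets inside the planted block.
#' @param rng_seed optional integer seed.
#' @return validated list of class `planted_module_spec`.
#' @export
planted_module_spec <- function(num_genes = 200L, num_samples = 40L,
                                module_genes = 20L, module_samples = 12L,
                                num_states = 3L, noise_sd = 0,
                                background = c("uniform_states", "shuffled"),
                                state_separation = 2, effect_range = 0.1,
                                rng_seed = NULL) {
  background <- match.arg(background)
  spec <- list(num_genes = as.integer(num_genes),
               num_samples = as.integer(num_samples),
               module_genes = as.integer(module_genes),
               module_samples = as.integer(module_samples),
               num_states = as.integer(num_states),
               noise_sd = noise_sd, background = background,
               state_separation = state_separation,
               effect_range = effect_range, rng_seed = rng_seed)
  if (spec$module_genes > spec$num_genes ||
      spec$module_samples > spec$num_samples)
    stop("planted block larger than the matrix")
  if (spec$num_states < 2L) stop("num_states must be >= 2")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(spec, class = "planted_module_spec")
}

#' Generate a synthetic expression matrix with a planted conserved module
#'
#' @param spec a [planted_module_spec()].
#' @return list with `values` (the expression matrix, genes x samples) and
#'   `truth`, the ground truth: `modules` (list with one element holding
#'   `gene_index`, `sample_index`, `gene_ids`, `sample_ids`, `states` —
#'   the planted per-gene state), the full generating `states` matrix, and
#'   the `spec`. Deterministic under `spec$rng_seed`.
#' @export
simulate_planted_matrix <- function(spec) {
  stopifnot(inherits(spec, "planted_module_spec"))
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
  q <- spec$num_states
  delta <- spec$state_separation
  n <- spec$num_genes
  m <- spec$num_samples
  states <- switch(spec$background,
    uniform_states = matrix(sample.int(q, n * m, replace = TRUE) - 1L, n, m),
    shuffled = t(vapply(seq_len(n), function(g) {
      sample(rep_len(seq_len(q) - 1L, m))
    }, integer(m))))
  values <- states * delta + matrix(stats::runif(n * m, 0, delta), n, m)
  pg <- sort(sample.int(n, spec$module_genes))
  ps <- sort(sample.int(m, spec$module_samples))
  gene_state <- sample.int(q, spec$module_genes, replace = TRUE) - 1L
  row_off <- stats::runif(spec$module_genes, -spec$effect_range, spec$effect_range)
  col_off <- stats::runif(spec$module_samples, -spec$effect_range, spec$effect_range)
  block <- outer(gene_state * delta + delta / 2 + row_off, col_off, `+`)
  if (spec$noise_sd > 0)
    block <- block + matrix(stats::rnorm(length(block), 0, spec$noise_sd),
                            nrow(block), ncol(block))
  values[pg, ps] <- block
  states[pg, ps] <- gene_state  # recycles down columns: one state per gene
  gene_ids <- sprintf("g%04d", seq_len(n))
  sample_ids <- sprintf("s%03d", seq_len(m))
  values <- expression_matrix(values, gene_ids, sample_ids)
  dimnames(states) <- dimnames(values)
  truth <- list(modules = list(list(gene_index = pg, sample_index = ps,
                                    gene_ids = gene_ids[pg],
                                    sample_ids = sample_ids[ps],
                                    states = gene_state)),
                states = states, spec = spec)
  list(values = values, truth = truth)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Jaccard recovery of a found module against the planted truth
#'
#' Separately for genes and samples, |found intersect planted| / |found
#' union planted|. When the truth holds several planted modules the found
#' module is scored against the best-matching one (largest summed
#' Jaccard).
#'
#' @param found a `conserved_module` (or any list with `genes` and
#'   `samples` index vectors).
#' @param truth the `truth` component returned by
#'   [simulate_planted_matrix()].
#' @return named numeric vector `c(gene_jaccard, sample_jaccard)`.
#' @export
recovery_score <- function(found, truth) {
  if (is.null(found))
    return(c(gene_jaccard = 0, sample_jaccard = 0))
  scores <- lapply(truth$modules, function(tm) {
    c(gene_jaccard = jaccard(found$genes, tm$gene_index),
      sample_jaccard = jaccard(found$samples, tm$sample_index))
  })
  best <- which.max(vapply(scores, sum, numeric(1L)))
  scores[[best]]
}

#' Build a synthetic driver-gene census around the planted truth
#'
#' The census contains every planted gene plus `extra_decoys` random
#' non-planted genes from the universe — a stand-in for a curated cancer
#' gene census, matched to the synthetic matrix so end-to-end enrichment
#' can be tested.
#'
#' @param truth the `truth` from [simulate_planted_matrix()].
#' @param extra_decoys number of non-planted decoy genes to add.
#' @param universe character vector of gene ids to draw decoys from;
#'   defaults to the ids of the generated matrix.
#' @return character vector of census gene ids (planted first).
#' @export
make_census <- function(truth, extra_decoys = 0L, universe = NULL) {
  planted <- unique(unlist(lapply(truth$modules, function(tm) tm$gene_ids)))
  if (is.null(universe))
    universe <- rownames(truth$states)
  pool <- setdiff(universe, planted)
  if (extra_decoys > length(pool))
    stop("not enough non-planted genes for ", extra_decoys, " decoys")
  decoys <- if (extra_decoys > 0L) pool[sample.int(length(pool), extra_decoys)]
  else character(0L)
  c(planted, decoys)
}
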