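#' Parameters for the multistart CGEM search
#'
#' @param num_seeds number of random restarts n_s.
#' @param discriminating_size size s_d of the discriminating sample subset D
#'   (the seed sample is a member of D, so s_d - 1 further samples are
#'   drawn). Clamped to the number of available samples.
#' @param alpha minimum fraction of the (original) sample count that a
#'   module's matched samples must cover; modules below are discarded.
#' @param rng_seed optional integer; when given, the search seeds the RNG
#'   itself and is fully reproducible.
#' @return validated parameter list of class `search_params`.
#' @export
search_params <- function(num_seeds = 10L, discriminating_size = 7L,
                          alpha = 0.05, rng_seed = NULL) {
  num_seeds <- as.integer(num_seeds)
  discriminating_size <- as.integer(discriminating_size)
  if (is.na(num_seeds) || num_seeds < 1L) stop("num_seeds must be >= 1")
  if (is.na(discriminating_size) || discriminating_size < 1L)
    stop("discriminating_size must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  structure(list(num_seeds = num_seeds,
                 discriminating_size = discriminating_size,
                 alpha = alpha, rng_seed = rng_seed),
            class = "search_params")
}

#' Build the conserved module induced by a seed
#'
#' Given a seed sample c and a discriminating sample set D (c is always
#' included in D), the module's gene-state set G contains every gene whose
#' state agrees with its state in c across all of D; the matched sample set
#' C contains every (active) sample that agrees with c on all gene states
#' in G. If G is empty the agreement is vacuous and C is all active
#' samples; such modules are never selected by the searches.
#'
#' @param disc a `discretized_matrix`.
#' @param seed_sample sample index c.
#' @param disc_set integer sample indices D (c is added if absent).
#' @param values optional expression matrix on which the module's MSR is
#'   computed; `NA` otherwise.
#' @param active optional subset of sample indices still in play (used by
#'   the iterative extraction); defaults to all samples.
#' @return object of class `conserved_module`: gene indices and their
#'   conserved states, matched sample indices, identifiers, `msr`,
#'   `n_genes`, `n_samples`, `size` = n_genes * n_samples, and the seed.
#' @export
build_module <- function(disc, seed_sample, disc_set, values = NULL,
                         active = NULL) {
  stopifnot(inherits(disc, "discretized_matrix"))
  st <- disc$states
  m_tot <- ncol(st)
  if (is.null(active)) active <- seq_len(m_tot)
  seed_sample <- as.integer(seed_sample)
  if (length(seed_sample) != 1L || is.na(seed_sample) ||
      !(seed_sample %in% active))
    stop("seed sample out of range (or not among active samples)")
  D <- sort(unique(c(seed_sample, as.integer(disc_set))))
  if (anyNA(D) || any(!(D %in% active)))
    stop("discriminating set out of range (or not among active samples)")
  ref <- st[, seed_sample]
  agree <- st[, D, drop = FALSE] == ref
  G <- which(rowSums(agree) == length(D))
  if (length(G) == 0L) {
    C <- active
  } else {
    agr <- st[G, active, drop = FALSE] == ref[G]
    C <- active[colSums(matrix(agr, nrow = length(G))) == length(G)]
  }
  m <- if (!is.null(values) && length(G) > 0L) msr(values, G, C) else NA_real_
  structure(list(
    genes = unname(G), states = unname(ref[G]), samples = C,
    gene_ids = rownames(st)[G], sample_ids = colnames(st)[C],
    msr = m, n_genes = length(G), n_samples = length(C),
    size = length(G) * length(C),
    seed = list(seed_sample = seed_sample, disc_set = D)),
    class = "conserved_module")
}

#' @export
print.conserved_module <- function(x, ...) {
  cat("conserved_module: |G| = ", x$n_genes, ", |C| = ", x$n_samples,
      ", MSR = ", format(x$msr, digits = 4), "\n", sep = "")
  invisible(x)
}

# tie-break chain for module comparison in the CGEM search:
# larger |G|, then larger |C|, then lower msr, then first found
module_beats <- function(a, b) {
  if (a$n_genes != b$n_genes) return(a$n_genes > b$n_genes)
  if (a$n_samples != b$n_samples) return(a$n_samples > b$n_samples)
  am <- if (is.na(a$msr)) Inf else a$msr
  bm <- if (is.na(b$msr)) Inf else b$msr
  am < bm
}

# draw one random seed: c uniform over active, D = c plus s_d - 1 further
# distinct active samples
draw_seed <- function(active, s_d) {
  c0 <- active[sample.int(length(active), 1L)]
  rest <- setdiff(active, c0)
  D <- c(c0, rest[sample.int(length(rest), min(s_d - 1L, length(rest)))])
  list(seed_sample = c0, disc_set = D)
}

#' Multistart search for the largest conserved module
#'
#' Draws `num_seeds` random seeds (seed sample uniform; D uniform among
#' size-s_d subsets containing it), builds each seed's module, discards
#' modules whose matched samples cover fewer than `alpha` of the original
#' samples (and modules with empty G), and returns the survivor with the
#' most conserved genes, ties broken by larger |C|, then lower MSR, then
#' discovery order. Returns `NULL` when every module is discarded.
#'
#' @inheritParams build_module
#' @param values expression matrix (for MSR scoring).
#' @param params a [search_params()] list.
#' @param alpha_m sample count the alpha filter is measured against;
#'   defaults to the full matrix width (kept fixed during iterative
#'   extraction).
#' @param seeds optional explicit list of seeds (each a list with
#'   `seed_sample`, `disc_set`) overriding random drawing — used for
#'   exhaustive enumeration.
#' @return the best `conserved_module`, or `NULL`.
#' @export
find_largest_module <- function(disc, values, params = search_params(),
                                active = NULL, alpha_m = NULL, seeds = NULL) {
  stopifnot(inherits(disc, "discretized_matrix"))
  m_tot <- ncol(disc$states)
  if (is.null(active)) active <- seq_len(m_tot)
  if (is.null(alpha_m)) alpha_m <- m_tot
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  s_d <- min(params$discriminating_size, length(active))
  if (is.null(seeds))
    seeds <- replicate(params$num_seeds, draw_seed(active, s_d),
                       simplify = FALSE)
  best <- NULL
  for (sd_ in seeds) {
    mod <- build_module(disc, sd_$seed_sample, sd_$disc_set, values, active)
    if (mod$n_genes == 0L) next
    if (mod$n_samples < params$alpha * alpha_m) next
    if (is.null(best) || module_beats(mod, best)) best <- mod
  }
  best
}

#' Enumerate every possible seed over a sample set
#'
#' All (c, D) pairs with |D| = s_d and c in D — the exhaustive seed space
#' used to cross-check the multistart search on small matrices.
#'
#' @param active sample indices to enumerate over.
#' @param s_d discriminating-set size.
#' @return list of seeds (each `seed_sample`, `disc_set`).
#' @export
enumerate_seeds <- function(active, s_d) {
  s_d <- min(s_d, length(active))
  subsets <- utils::combn(active, s_d, simplify = FALSE)
  out <- list()
  for (D in subsets)
    for (c0 in D)
      out[[length(out) + 1L]] <- list(seed_sample = c0, disc_set = D)
  out
}

#' Iteratively extract conserved biclusters (baseline CGEM)
#'
#' Repeats the multistart largest-module search, each time removing the
#' matched samples of the module just found, until fewer than alpha * M of
#' the original M samples remain, no module survives the filter, or
#' `max_modules` have been collected. The `best` element indexes the module
#' with the largest |G| x |C| area across iterations — the submatrix with
#' the largest row-column size.
#'
#' @inheritParams find_largest_module
#' @param max_modules maximum number of modules to extract.
#' @return object of class `cgem_result`: `modules` (list, extraction
#'   order), `best` (index into modules, or NA when empty).
#' @export
extract_biclusters <- function(disc, values, params = search_params(),
                               max_modules = 10L) {
  stopifnot(max_modules >= 1L)
  m_tot <- ncol(disc$states)
  if (!is.null(params$rng_seed)) {
    set.seed(params$rng_seed)
    params$rng_seed <- NULL  # inner calls must consume the stream, not reset it
  }
  active <- seq_len(m_tot)
  modules <- list()
  while (length(modules) < max_modules &&
         length(active) >= params$alpha * m_tot && length(active) >= 1L) {
    mod <- find_largest_module(disc, values, params, active = active,
                               alpha_m = m_tot)
    if (is.null(mod)) break
    modules[[length(modules) + 1L]] <- mod
    active <- setdiff(active, mod$samples)
  }
  best <- if (length(modules) == 0L) NA_integer_
  else which.max(vapply(modules, function(m) m$size, numeric(1L)))
  structure(list(modules = modules, best = best), class = "cgem_result")
}

#' @export
print.cgem_result <- function(x, ...) {
  cat("cgem_result: ", length(x$modules), " module(s)\n", sep = "")
  for (i in seq_along(x$modules)) {
    m <- x$modules[[i]]
    cat(sprintf("  [%d]%s |G| = %d, |C| = %d, MSR = %s\n", i,
                if (identical(i, as.integer(x$best))) "*" else " ",
                m$n_genes, m$n_samples, format(m$msr, digits = 4)))
  }
  invisible(x)
}
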