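# Independent oracles used to cross-check the implementation. These are
# deliberately naive (explicit loops, direct factorials, exhaustive
# enumeration) and share no code with the package internals.

# Mean Squared Residue by explicit double loop over the submatrix
msr_oracle <- function(x, genes, samples) {
  sub <- x[genes, samples, drop = FALSE]
  n <- nrow(sub)
  m <- ncol(sub)
  row_means <- numeric(n)
  col_means <- numeric(m)
  for (i in seq_len(n)) row_means[i] <- sum(sub[i, ]) / m
  for (j in seq_len(m)) col_means[j] <- sum(sub[, j]) / n
  grand <- sum(sub) / (n * m)
  acc <- 0
  for (i in seq_len(n))
    for (j in seq_len(m))
      acc <- acc + (sub[i, j] - row_means[i] - col_means[j] + grand)^2
  acc / (n * m)
}

# conserved module from a seed by explicit loops over a state matrix
module_oracle <- function(states, c0, D) {
  D <- sort(unique(c(c0, D)))
  G <- integer(0)
  for (g in seq_len(nrow(states))) {
    ok <- TRUE
    for (d in D) if (states[g, d] != states[g, c0]) { ok <- FALSE; break }
    if (ok) G <- c(G, g)
  }
  C <- integer(0)
  if (length(G) == 0) {
    C <- seq_len(ncol(states))
  } else {
    for (s in seq_len(ncol(states))) {
      ok <- TRUE
      for (g in G) if (states[g, s] != states[g, c0]) { ok <- FALSE; break }
      if (ok) C <- c(C, s)
    }
  }
  list(G = G, C = C)
}

# exhaustive largest-xmotif search over every (c, D) pair, applying the
# alpha filter and the |G| -> |C| -> msr -> first-found tie chain
largest_module_oracle <- function(states, values, s_d, alpha) {
  M <- ncol(states)
  best <- NULL
  subsets <- utils::combn(M, min(s_d, M), simplify = FALSE)
  for (D in subsets) {
    for (c0 in D) {
      mod <- module_oracle(states, c0, D)
      if (length(mod$G) == 0) next
      if (length(mod$C) < alpha * M) next
      h <- msr_oracle(values, mod$G, mod$C)
      cand <- list(G = mod$G, C = mod$C, msr = h)
      if (is.null(best)) { best <- cand; next }
      if (length(cand$G) > length(best$G) ||
          (length(cand$G) == length(best$G) &&
           length(cand$C) > length(best$C)) ||
          (length(cand$G) == length(best$G) &&
           length(cand$C) == length(best$C) && cand$msr < best$msr))
        best <- cand
    }
  }
  best
}

# Fisher's exact test by direct enumeration with plain factorials (valid
# for N <= 170; used at N <= 30)
fisher_oracle <- function(a, b, c, d, alternative = "greater") {
  r <- a + b; s <- c + d; m <- a + c; n <- b + d; N <- a + b + c + d
  pt <- function(aa) {
    bb <- r - aa; cc <- m - aa; dd <- n - bb
    factorial(m) * factorial(n) * factorial(r) * factorial(s) /
      (factorial(aa) * factorial(bb) * factorial(cc) * factorial(dd) *
         factorial(N))
  }
  a_all <- max(0, r - n):min(r, m)
  probs <- vapply(a_all, pt, numeric(1))
  if (alternative == "greater") sum(probs[a_all >= a])
  else min(1, sum(probs[probs <= pt(a) * (1 + 1e-7)]))
}

# wrap a bare state matrix as a discretized_matrix (for search tests that
# construct states directly)
as_disc <- function(states, num_states = max(states) + 1L) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(rownames(states)))
    rownames(states) <- paste0("g", seq_len(nrow(states)))
  if (is.null(colnames(states)))
    colnames(states) <- paste0("s", seq_len(ncol(states)))
  structure(list(states = states, boundaries = NULL,
                 num_states = as.integer(num_states), method = "manual"),
            class = "discretized_matrix")
}

# random expression matrix helper
random_matrix <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  expression_matrix(matrix(rnorm(n * m), n, m),
                    paste0("g", seq_len(n)), paste0("s", seq_len(m)))
}

write_tmp_matrix <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
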