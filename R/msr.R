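#' Row, column and grand means of a submatrix
#'
#' For a bicluster with gene index set I and sample index set J of a matrix
#' a, returns the row means a_iJ, the column means a_Ij and the grand mean
#' a_IJ over the continuous expression values.
#'
#' @param x expression matrix.
#' @param genes row indices (integer, logical or character) — the set I.
#' @param samples column indices — the set J.
#' @return list with `row_means`, `col_means`, `grand_mean`.
#' @export
submatrix_means <- function(x, genes, samples) {
  sub <- resolve_submatrix(x, genes, samples)
  list(row_means = rowMeans(sub), col_means = colMeans(sub),
       grand_mean = mean(sub))
}

#' Mean Squared Residue of a submatrix
#'
#' The MSR of a bicluster (I, J) is
#' \deqn{H(I,J) = \frac{1}{|I||J|}\sum_{i \in I, j \in J}
#'   (a_{ij} - a_{iJ} - a_{Ij} + a_{IJ})^2,}
#' the mean squared deviation of the submatrix from an additive
#' row-plus-column model. It is 0 exactly when the submatrix can be written
#' a_ij = r_i + c_j (in particular for constant submatrices and for any
#' single-row or single-column submatrix), and grows with incoherence.
#' Computed on the original continuous values, never on discretized states.
#'
#' @inheritParams submatrix_means
#' @return a single nonnegative number.
#' @export
msr <- function(x, genes, samples) {
  sub <- resolve_submatrix(x, genes, samples)
  rm_ <- rowMeans(sub)
  cm_ <- colMeans(sub)
  resid <- sweep(sweep(sub, 1L, rm_), 2L, cm_) + mean(sub)
  mean(resid^2)
}

# resolve and validate a (genes, samples) selection; duplicate-free, in bounds
resolve_submatrix <- function(x, genes, samples) {
  if (length(genes) == 0L || length(samples) == 0L)
    stop("empty gene or sample index set")
  sub <- x[genes, samples, drop = FALSE]
  if (nrow(sub) == 0L || ncol(sub) == 0L)
    stop("empty gene or sample index set")
  if (anyNA(sub)) stop("submatrix selection out of bounds")
  if (!is.logical(genes) && anyDuplicated(genes))
    stop("duplicate gene indices in bicluster")
  if (!is.logical(samples) && anyDuplicated(samples))
    stop("duplicate sample indices in bicluster")
  sub
}
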