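#' Discretize an expression matrix into per-gene expression states
#'
#' Each gene is independently partitioned into `num_states` intervals and
#' every cell is assigned the integer state (0-based) of the interval its
#' value falls into. `equal_frequency` places the cut points at the per-gene
#' quantiles k/q (k = 1..q-1, type-7 interpolation); `equal_width` splits
#' the per-gene range evenly. Intervals are left-closed: a value exactly at
#' a cut point belongs to the upper interval. Duplicate or degenerate cut
#' points (ties, constant genes) are collapsed, so low-diversity genes may
#' occupy fewer than `num_states` effective states; a constant gene is all
#' state 0.
#'
#' @param x validated expression matrix (genes x samples).
#' @param num_states number of expression states q per gene (default 3:
#'   low / baseline / high).
#' @param method `"equal_width"` (even split of the per-gene range, the
#'   default) or `"equal_frequency"` (quantile cuts). Equal width is the
#'   default because a conserved module concentrates many samples in one
#'   state of its genes; quantile cuts then fall inside that state and
#'   split it, destroying the very conservation the search looks for.
#' @return an object of class `discretized_matrix`: a list with `states`
#'   (integer matrix in 0..q-1, same dimnames as `x`), `boundaries` (per
#'   gene, the ascending cut points actually used), `num_states`, `method`.
#' @export
discretize <- function(x, num_states = 3L,
                       method = c("equal_width", "equal_frequency")) {
  method <- match.arg(method)
  validate_expression_matrix(x)
  q <- as.integer(num_states)
  if (is.na(q) || q < 1L) stop("num_states must be a positive integer")
  if (method == "equal_frequency" && q > ncol(x))
    stop("num_states (", q, ") exceeds sample count (", ncol(x),
         ") for equal_frequency discretization")
  states <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  boundaries <- vector("list", nrow(x))
  names(boundaries) <- rownames(x)
  probs <- seq_len(q - 1L) / q
  for (g in seq_len(nrow(x))) {
    v <- x[g, ]
    cuts <- if (q == 1L) numeric(0L)
    else if (method == "equal_frequency")
      unname(stats::quantile(v, probs = probs, type = 7, names = FALSE))
    else min(v) + (max(v) - min(v)) * probs
    # collapse ties and cuts that separate nothing (constant genes end at 0 cuts)
    cuts <- unique(cuts)
    cuts <- cuts[cuts > min(v) & cuts <= max(v)]
    boundaries[[g]] <- cuts
    states[g, ] <- findInterval(v, cuts)
  }
  structure(list(states = states, boundaries = boundaries,
                 num_states = q, method = method),
            class = "discretized_matrix")
}

#' @export
print.discretized_matrix <- function(x, ...) {
  cat("discretized_matrix: ", nrow(x$states), " genes x ", ncol(x$states),
      " samples, q = ", x$num_states, " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Write a discretized state matrix as TSV for inspection
#'
#' @param disc a `discretized_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(disc, path) {
  stopifnot(inherits(disc, "discretized_matrix"))
  st <- disc$states
  header <- paste(c("id", colnames(st)), collapse = "\t")
  rows <- vapply(seq_len(nrow(st)), function(i) {
    paste(c(rownames(st)[i], st[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}
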