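#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns, carrying unique gene identifiers as rownames and
#' unique sample identifiers as colnames. Values are assumed to be
#' pre-processed (e.g. log-scale) expression; no transformation is applied
#' anywhere in this package.
#'
#' @param values numeric matrix (genes x samples) or something coercible.
#' @param gene_ids character vector of row identifiers; defaults to existing
#'   rownames.
#' @param sample_ids character vector of column identifiers; defaults to
#'   existing colnames.
#' @return a numeric matrix with dimnames set, validated.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the invariants every downstream function relies on: at least one
#' gene and one sample, no missing or non-finite values, and duplicate-free
#' identifiers.
#'
#' @param x numeric matrix with dimnames.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("empty matrix: need at least one gene and one sample")
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene (row) and sample (column) identifiers")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) stop("duplicate gene id: ", dup[1L])
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup)) stop("duplicate sample id: ", dup[1L])
  invisible(x)
}

#' Read a genes x samples expression matrix from delimited text
#'
#' The first row is a header: an id column followed by one column per
#' sample. Every subsequent row is one gene. The delimiter is inferred from
#' the file extension (`.csv` gives comma, anything else tab) unless given
#' explicitly. Parsing is strict: ragged rows, duplicate identifiers and
#' non-numeric cells are errors, never silently coerced.
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter single-character field separator; `NULL` (default) to
#'   infer from the extension.
#' @return validated expression matrix (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path, delimiter = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("expression matrix file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- trimws(fields[[1L]])
  if (length(header) < 2L)
    stop("empty matrix: header has no sample columns in ", path)
  if (length(lines) < 2L) stop("empty matrix: no data rows in ", path)
  sample_ids <- header[-1L]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample id: ", dup[1L])
  body <- fields[-1L]
  bad <- which(lengths(body) != length(header))
  if (length(bad))
    stop("ragged row: line ", bad[1L] + 1L, " has ", lengths(body)[bad[1L]],
         " fields, expected ", length(header))
  gene_ids <- trimws(vapply(body, `[[`, character(1L), 1L))
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id: ", dup[1L])
  cells <- do.call(rbind, lapply(body, function(f) f[-1L]))
  vals <- suppressWarnings(as.numeric(cells))
  if (anyNA(vals)) {
    idx <- which(is.na(vals))[1L]
    g <- (idx - 1L) %% nrow(cells) + 1L
    s <- (idx - 1L) %/% nrow(cells) + 1L
    stop("non-numeric cell at gene '", gene_ids[g], "', sample '",
         sample_ids[s], "': '", cells[g, s], "'")
  }
  expression_matrix(matrix(vals, nrow = length(gene_ids)),
                    gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write an expression matrix at full precision
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the matrix bit-exactly.
#'
#' @param x validated expression matrix.
#' @param path output file path.
#' @param delimiter field separator; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, delimiter = NULL) {
  validate_expression_matrix(x)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- paste(c("id", colnames(x)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = delimiter)
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}
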