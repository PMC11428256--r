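#' Build a 2x2 contingency table with margins
#'
#' Cell a counts genes both found and in the census, b found only, c in
#' the census only, d neither. Margins m = a + c (census), n = b + d,
#' r = a + b (found), s = c + d, with total N = a + b + c + d.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @return object of class `contingency_table` with counts, margins and `N`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("contingency counts must be nonnegative integers")
  structure(list(a = a, b = b, c = c, d = d,
                 m = a + c, n = b + d, r = a + b, s = c + d,
                 N = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("contingency_table (N = ", x$N, "):\n", sep = "")
  print(matrix(c(x$a, x$c, x$b, x$d), 2L, 2L,
               dimnames = list(c("found", "not found"),
                               c("census", "not census"))))
  invisible(x)
}

#' Hypergeometric point probability of a 2x2 table
#'
#' The probability of the observed table among all tables sharing its
#' margins: p = m! n! r! s! / (a! b! c! d! N!), evaluated in log-factorial
#' space so large counts cannot overflow. An all-zero table returns 1.
#'
#' @param table a [contingency_table()].
#' @return probability in (0, 1].
#' @export
point_probability <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  exp(lfactorial(table$m) + lfactorial(table$n) + lfactorial(table$r) +
      lfactorial(table$s) - lfactorial(table$a) - lfactorial(table$b) -
      lfactorial(table$c) - lfactorial(table$d) - lfactorial(table$N))
}

# point probabilities over the full support of a given the margins
support_probabilities <- function(table) {
  a_min <- max(0L, table$r - table$n)
  a_max <- min(table$r, table$m)
  a_vals <- a_min:a_max
  lp <- lfactorial(table$m) + lfactorial(table$n) + lfactorial(table$r) +
    lfactorial(table$s) - lfactorial(table$N) -
    lfactorial(a_vals) - lfactorial(table$r - a_vals) -
    lfactorial(table$m - a_vals) - lfactorial(table$n - table$r + a_vals)
  list(a = a_vals, p = exp(lp))
}

#' Fisher's exact test on a 2x2 table
#'
#' Holding the margins fixed, sums hypergeometric point probabilities over
#' the admissible tables. `"greater"` (the default, testing enrichment of
#' found genes in the census) sums over tables with a' >= a; `"two_sided"`
#' sums over tables whose point probability does not exceed the observed
#' one (within a 1e-7 relative tolerance, matching the usual convention).
#'
#' @param table a [contingency_table()].
#' @param alternative `"greater"` or `"two_sided"`.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(table, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  sup <- support_probabilities(table)
  if (alternative == "greater") {
    sum(sup$p[sup$a >= table$a])
  } else {
    p_obs <- sup$p[sup$a == table$a]
    min(1, sum(sup$p[sup$p <= p_obs * (1 + 1e-7)]))
  }
}

#' Contingency table of found genes against a driver-gene census
#'
#' Census genes absent from the expression universe are dropped first, so
#' c counts only census genes the experiment could have found. Every found
#' gene must belong to the universe.
#'
#' @param found_genes character vector of gene ids discovered by the search
#'   (typically the union over reported modules of a run).
#' @param census character vector of driver-gene ids.
#' @param universe character vector of all gene ids in the experiment.
#' @return a [contingency_table()] with a + b + c + d = |universe|.
#' @export
build_contingency <- function(found_genes, census, universe) {
  found_genes <- unique(as.character(found_genes))
  census <- unique(as.character(census))
  universe <- unique(as.character(universe))
  missing <- setdiff(found_genes, universe)
  if (length(missing))
    stop("found gene(s) absent from the universe: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  census_u <- intersect(census, universe)
  a <- length(intersect(found_genes, census_u))
  b <- length(setdiff(found_genes, census_u))
  cc <- length(setdiff(census_u, found_genes))
  d <- length(universe) - a - b - cc
  contingency_table(a, b, cc, d)
}

#' Read a driver-gene census from plain text
#'
#' One gene symbol per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return character vector of unique gene ids.
#' @export
read_census <- function(path) {
  if (!file.exists(path)) stop("census file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Format a number in the tables' scientific notation
#'
#' e.g. `format_scientific(0.000154)` gives `"1.54 \u00d7 10^-4"`.
#'
#' @param x numeric scalar (or vector).
#' @param digits significant mantissa decimals (default 2).
#' @return character.
#' @export
format_scientific <- function(x, digits = 2) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == 0) return(sprintf(paste0("%.", digits, "f \u00d7 10^0"), 0))
    e <- floor(log10(abs(v)))
    m <- v / 10^e
    # rounding can push the mantissa to 10
    if (round(abs(m), digits) >= 10) {
      m <- m / 10
      e <- e + 1
    }
    sprintf(paste0("%.", digits, "f \u00d7 10^%d"), m, e)
  }, character(1L))
}

#' Summarize p-values and MSR scores over independent runs
#'
#' Mean and sample standard deviation (n - 1 denominator; a single run has
#' sd 0) of the per-run Fisher p-values and module MSR values, with the
#' significance threshold applied to the mean p-value.
#'
#' @param pvalues numeric vector, one Fisher p-value per run.
#' @param msrs numeric vector, one MSR per run (same length).
#' @param threshold significance threshold on p (default 0.05).
#' @return object of class `run_summary` with the raw values, means, sds,
#'   formatted `"mean +/- sd"` strings and a `significant` flag.
#' @export
summarize_runs <- function(pvalues, msrs, threshold = 0.05) {
  if (length(pvalues) == 0L || length(pvalues) != length(msrs))
    stop("pvalues and msrs must be nonempty and of equal length")
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  structure(list(
    pvalues = pvalues, msrs = msrs,
    mean_p = mean(pvalues), sd_p = sd0(pvalues),
    mean_msr = mean(msrs), sd_msr = sd0(msrs),
    p_formatted = paste(format_scientific(mean(pvalues)), "+/-",
                        format_scientific(sd0(pvalues))),
    msr_formatted = paste(format_scientific(mean(msrs)), "+/-",
                          format_scientific(sd0(msrs))),
    threshold = threshold,
    significant = mean(pvalues) < threshold),
    class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("run_summary over ", length(x$pvalues), " run(s)\n", sep = "")
  cat("  p-value: ", x$p_formatted,
      if (x$significant) "  (significant at" else "  (not significant at",
      " p < ", x$threshold, ")\n", sep = "")
  cat("  MSR:     ", x$msr_formatted, "\n", sep = "")
  invisible(x)
}
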