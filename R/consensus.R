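#' Residue frequencies of one alignment column
#'
#' Counts the 20 canonical residues in a column; gaps and X are excluded
#' from both numerator and denominator, so frequencies sum to 1 whenever
#' the column has at least one counted residue.
#'
#' @param alignment a `core_alignment`.
#' @param column column index.
#' @return list with `counts` (named integer, the 20 canonical codes),
#'   `n_non_gap` and `f` (named numeric; all NA when `n_non_gap` is 0).
#' @export
column_frequencies <- function(alignment, column) {
  letters1 <- alignment_column(alignment, column)
  counts <- stats::setNames(integer(20), AA20)
  tab <- table(letters1[letters1 %in% AA20])
  counts[names(tab)] <- as.integer(tab)
  n <- sum(counts)
  f <- if (n > 0) counts / n else stats::setNames(rep(NA_real_, 20), AA20)
  list(counts = counts, n_non_gap = n, f = f)
}

#' Frequency matrix over a set of columns
#'
#' @param alignment a `core_alignment`.
#' @param columns column indices; default the five core columns.
#' @return 20 x length(columns) matrix of frequencies (rows = residues,
#'   alphabetical), with `n_non_gap` attached as an attribute.
#' @export
frequency_matrix <- function(alignment, columns = alignment$core_columns) {
  cols <- lapply(columns, function(j) column_frequencies(alignment, j))
  m <- vapply(cols, `[[`, numeric(20), "f")
  dimnames(m) <- list(AA20, paste0("pos", seq_along(columns)))
  attr(m, "n_non_gap") <- vapply(cols, `[[`, integer(1), "n_non_gap")
  m
}

#' Call consensus residues of one column (f >= f_mean + SD)
#'
#' A residue is part of the consensus when its frequency is at least the
#' mean frequency plus one standard deviation of the frequencies. By
#' default mean and SD are taken over all 20 canonical residues,
#' zero-frequency ones included, with the population SD (divide by 20);
#' `denominator = "observed"` restricts both to residues actually seen
#' in the column. The threshold comparison is inclusive; consensus
#' residues are ordered by decreasing frequency, ties alphabetical.
#'
#' @param fcol a column as returned by [column_frequencies()].
#' @param denominator `"all20"` or `"observed"`.
#' @return list with `threshold`, `f_mean`, `sd` and `consensus` (ordered
#'   character vector; empty if the column is all-gap).
#' @export
call_consensus <- function(fcol, denominator = c("all20", "observed")) {
  denominator <- match.arg(denominator)
  if (fcol$n_non_gap == 0)
    return(list(threshold = NA_real_, f_mean = NA_real_, sd = NA_real_,
                consensus = character(0)))
  f <- fcol$f
  ref <- if (denominator == "all20") f else f[f > 0]
  f_mean <- mean(ref)
  sdev <- sqrt(mean((ref - f_mean)^2))      # population SD
  thr <- f_mean + sdev
  keep <- names(f)[f >= thr - 1e-12]        # inclusive, float-tolerant
  keep <- keep[order(-f[keep], keep)]
  list(threshold = thr, f_mean = f_mean, sd = sdev, consensus = keep)
}

#' Consensus over the core columns of an alignment
#'
#' @param alignment a `core_alignment`.
#' @param columns columns to call; default the five core columns.
#' @param denominator passed to [call_consensus()].
#' @return list of per-column consensus calls (as [call_consensus()]),
#'   named pos1..pos5.
#' @export
core_consensus <- function(alignment, columns = alignment$core_columns,
                           denominator = "all20") {
  calls <- lapply(columns, function(j)
    call_consensus(column_frequencies(alignment, j), denominator))
  stats::setNames(calls, paste0("pos", seq_along(columns)))
}

#' Bracketed consensus string
#'
#' Renders per-position consensus sets the way family consensus cores
#' are usually written: a single residue bare, several as a bracketed
#' slash-separated list in order of abundance, an uncallable (all-gap)
#' column as a middle dot.
#'
#' @param alignment a `core_alignment`.
#' @param denominator passed to [call_consensus()].
#' @return single string, e.g. `"[R/K] E [N/S] [R/K/Q] C"`.
#' @export
consensus_string <- function(alignment, denominator = "all20") {
  calls <- core_consensus(alignment, denominator = denominator)
  parts <- vapply(calls, function(cl) {
    cs <- cl$consensus
    if (!length(cs)) return("·")
    if (length(cs) == 1) cs else paste0("[", paste(cs, collapse = "/"), "]")
  }, character(1))
  paste(parts, collapse = " ")
}
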