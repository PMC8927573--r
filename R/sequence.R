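# the 20 canonical one-letter codes, alphabetical
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Topology-annotated protein sequence
#'
#' A protein sequence with four transmembrane-segment (TMS) boundary
#' annotations, 1-based inclusive, ordered TMS1-TMS4. Boundaries are
#' inputs (e.g. from a published topology table), not predicted here.
#'
#' @param id identifier (unique within a set).
#' @param sequence residue string, one-letter codes; lowercase input is
#'   uppercased with a message. Only the 20 canonical codes plus X are
#'   allowed.
#' @param tms 4x2 integer matrix (or list of four `c(start, end)` pairs)
#'   of TMS boundaries.
#' @param species free-text species tag.
#' @return object of class `sequence_record`.
#' @export
sequence_record <- function(id, sequence, tms, species = NA_character_) {
  stopifnot(length(id) == 1, nzchar(id), length(sequence) == 1)
  if (grepl("[a-z]", sequence)) {
    message("sequence ", id, ": lowercase letters uppercased")
    sequence <- toupper(sequence)
  }
  bad <- setdiff(strsplit(sequence, "")[[1]], c(AA20, "X"))
  if (length(bad))
    stop("sequence ", id, ": non-canonical letters: ",
         paste(unique(bad), collapse = ""))
  if (is.list(tms)) tms <- do.call(rbind, tms)
  tms <- matrix(as.integer(tms), ncol = 2)
  if (nrow(tms) != 4) stop("record ", id, ": need exactly 4 TMS intervals")
  if (any(tms[, 1] > tms[, 2]) || any(tms[, 1] < 1) ||
      any(tms[, 2] > nchar(sequence)))
    stop("record ", id, ": TMS interval outside 1..length(sequence)")
  if (any(tms[-1, 1] <= tms[-4, 2]))
    stop("record ", id, ": TMS intervals must be disjoint and ordered")
  structure(list(id = id, species = species, sequence = sequence, tms = tms),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("sequence_record %s (%d aa), TMS: %s\n", x$id,
              nchar(x$sequence),
              paste(apply(x$tms, 1, paste, collapse = "-"), collapse = ", ")))
  invisible(x)
}

#' Extract the small intracellular loop (TMS2-TMS3 linker)
#'
#' Returns the residues strictly between the annotated end of TMS2 and
#' start of TMS3. A degenerate topology (TMS3 starting right after TMS2)
#' yields an empty string with a warning.
#'
#' @param record a [sequence_record()].
#' @return residue string (possibly empty).
#' @export
extract_sil <- function(record) {
  stopifnot(inherits(record, "sequence_record"))
  from <- record$tms[2, 2] + 1L
  to <- record$tms[3, 1] - 1L
  if (from > to) {
    warning("record ", record$id, ": empty SIL (TMS3 adjoins TMS2)")
    return("")
  }
  substr(record$sequence, from, to)
}

#' Extract the N-terminal segment plus the first five TMS1 residues
#'
#' The intracellular N terminus (residues 1 to start(TMS1)-1) extended
#' by the first five residues of TMS1, the window in which the conserved
#' juxtamembrane basic residue lies.
#'
#' @param record a [sequence_record()].
#' @return residue string.
#' @export
extract_nterm <- function(record) {
  stopifnot(inherits(record, "sequence_record"))
  to <- min(record$tms[1, 1] + 4L, nchar(record$sequence))
  substr(record$sequence, 1L, to)
}

#' Read sequences plus a topology sidecar into sequence records
#'
#' @param fasta path to a FASTA file (wrapped or unwrapped).
#' @param topology path to a TSV with columns `id`, `tms1_start`,
#'   `tms1_end`, ..., `tms4_end` (1-based inclusive).
#' @return named list of [sequence_record()]s in FASTA order.
#' @export
read_sil_records <- function(fasta, topology) {
  seqs <- Biostrings::readAAStringSet(fasta)
  if (!length(seqs)) stop("empty FASTA: ", fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  topo <- utils::read.delim(topology, stringsAsFactors = FALSE)
  need <- c("id", paste0("tms", rep(1:4, each = 2), c("_start", "_end")))
  if (!all(need %in% names(topo)))
    stop("topology table must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(ids, topo$id)
  if (length(missing))
    stop("no topology for: ", paste(missing, collapse = ", "))
  recs <- lapply(seq_along(ids), function(i) {
    row <- topo[topo$id == ids[i], ][1, ]
    tms <- matrix(as.integer(row[paste0("tms", rep(1:4, each = 2),
                                        c("_start", "_end"))]),
                  ncol = 2, byrow = TRUE)
    sequence_record(ids[i], as.character(seqs[[i]]), tms,
                    species = if ("species" %in% names(row))
                      row$species else NA_character_)
  })
  stats::setNames(recs, ids)
}

#' Write records (or any named sequence set) as FASTA
#'
#' @param seqs named character vector of sequences, or a list of
#'   [sequence_record()]s.
#' @param path output file.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1]], "sequence_record"))
    seqs <- vapply(seqs, function(r) r$sequence, character(1))
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
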