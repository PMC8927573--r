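#' Anchoring rules for short-loop alignment
#'
#' An anchor rule is an ordered list of residue classes scanned in
#' priority order; the first class with a hit fixes the anchor residue
#' and the core position it maps to. `sil_anchor_rule()` encodes the SIL
#' convention: the most N-terminal glutamate or aspartate anchors core
#' position 2; if the loop has neither, the most N-terminal lysine or
#' arginine anchors core position 1. `nterm_anchor_rule()` anchors the
#' N-terminal segment at its most C-terminal lysine or arginine.
#'
#' @param classes named list of character vectors of one-letter codes,
#'   in priority order.
#' @param core_position integer vector, one core position per class.
#' @param scan `"N-to-C"` (first hit from the left) or `"C-to-N"`.
#' @return object of class `anchor_rule`.
#' @export
anchor_rule <- function(classes, core_position,
                        scan = c("N-to-C", "C-to-N")) {
  scan <- match.arg(scan)
  stopifnot(length(classes) >= 1, length(core_position) == length(classes),
            all(vapply(classes, length, 1L) > 0),
            all(unlist(classes) %in% AA20))
  structure(list(classes = classes, core_position = as.integer(core_position),
                 scan = scan), class = "anchor_rule")
}

#' @rdname anchor_rule
#' @export
sil_anchor_rule <- function() {
  anchor_rule(classes = list(acidic = c("E", "D"), basic = c("K", "R")),
              core_position = c(2L, 1L), scan = "N-to-C")
}

#' @rdname anchor_rule
#' @export
nterm_anchor_rule <- function() {
  anchor_rule(classes = list(basic = c("K", "R")),
              core_position = 1L, scan = "C-to-N")
}

#' Find the anchor residue of one loop
#'
#' @param loop non-empty residue string.
#' @param rule an [anchor_rule()].
#' @return list with `anchor_index` (1-based position in the loop, NA if
#'   unanchored), `matched_class` (class name or NA) and `core_position`
#'   (core position of the anchor, NA if unanchored).
#' @export
anchor_loop <- function(loop, rule = sil_anchor_rule()) {
  stopifnot(is.character(loop), length(loop) == 1, nzchar(loop))
  letters1 <- strsplit(loop, "")[[1]]
  for (k in seq_along(rule$classes)) {
    hit <- which(letters1 %in% rule$classes[[k]])
    if (length(hit)) {
      idx <- if (rule$scan == "N-to-C") hit[1] else hit[length(hit)]
      return(list(anchor_index = idx, matched_class = names(rule$classes)[k],
                  core_position = rule$core_position[k]))
    }
  }
  list(anchor_index = NA_integer_, matched_class = NA_character_,
       core_position = NA_integer_)
}

#' Anchored gap-padded alignment of short loops
#'
#' Each loop is left-padded with gaps so that all anchors line up on
#' their core columns; columns beyond a loop's end are right-padded with
#' gaps (so short loops leave core positions 4/5 empty). Loops that no
#' rule class matches are excluded — unless a manual offset supplies the
#' loop index to treat as core position 1 (the by-similarity fallback
#' for families where one member lacks every anchor class).
#'
#' @param loops named character vector of loop sequences, or a list of
#'   [sequence_record()]s (SILs are extracted with [extract_sil()]).
#' @param rule an [anchor_rule()].
#' @param manual_offsets optional named integer vector: id -> loop index
#'   of core position 1, applied to otherwise unanchored loops.
#' @return object of class `core_alignment`: list with `rows` (named
#'   character vector of equal-length gapped strings), `anchor_column`,
#'   `core_columns` (five column indices for core positions 1-5),
#'   `anchors` (per-row anchor info data.frame) and `excluded` (ids).
#' @export
align_loops <- function(loops, rule = sil_anchor_rule(),
                        manual_offsets = NULL) {
  if (is.list(loops) && length(loops) &&
      inherits(loops[[1]], "sequence_record")) {
    ids <- vapply(loops, function(r) r$id, character(1))
    loops <- stats::setNames(vapply(loops, extract_sil, character(1)), ids)
  }
  stopifnot(is.character(loops), length(loops) >= 1)
  if (is.null(names(loops)) || anyDuplicated(names(loops)))
    names(loops) <- make.unique(if (is.null(names(loops)))
      paste0("seq", seq_along(loops)) else names(loops))

  anc <- lapply(loops, function(s)
    if (nzchar(s)) anchor_loop(s, rule) else
      list(anchor_index = NA_integer_, matched_class = NA_character_,
           core_position = NA_integer_))
  for (id in names(manual_offsets)) {
    if (!id %in% names(loops)) stop("manual offset for unknown id: ", id)
    if (is.na(anc[[id]]$anchor_index)) {
      off <- as.integer(manual_offsets[[id]])
      if (off < 1 || off > nchar(loops[[id]]))
        stop("manual offset out of range for ", id)
      anc[[id]] <- list(anchor_index = off, matched_class = "manual",
                        core_position = 1L)
    }
  }
  anchored <- !vapply(anc, function(a) is.na(a$anchor_index), logical(1))
  excluded <- names(loops)[!anchored]
  if (length(excluded))
    message("excluded unanchored loop(s): ", paste(excluded, collapse = ", "))
  if (!any(anchored)) stop("no loop could be anchored")
  loops <- loops[anchored]
  anc <- anc[anchored]

  # index (within the loop) of core position 1; may be 0 when the anchor
  # sits at the very first residue and maps to core position 2
  lead <- vapply(anc, function(a) a$anchor_index - (a$core_position - 1L),
                 integer(1))
  c1 <- max(max(lead), 1L)
  pad <- c1 - lead
  width <- max(pad + nchar(loops), c1 + 4L)
  rows <- vapply(seq_along(loops), function(i) {
    s <- paste0(strrep("-", pad[i]), loops[[i]])
    paste0(s, strrep("-", width - nchar(s)))
  }, character(1))
  names(rows) <- names(loops)

  anchors <- data.frame(
    id = names(loops),
    anchor_index = vapply(anc, `[[`, 1L, "anchor_index"),
    matched_class = vapply(anc, `[[`, "", "matched_class"),
    core_position = vapply(anc, `[[`, 1L, "core_position"),
    column = pad + vapply(anc, `[[`, 1L, "anchor_index"),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(rows = rows,
                 anchor_column = c1 + (rule$core_position[1] - 1L),
                 core_columns = c1:(c1 + 4L),
                 anchors = anchors, excluded = excluded),
            class = "core_alignment")
}

#' @export
print.core_alignment <- function(x, ...) {
  cat(sprintf("core_alignment: %d rows x %d columns, core columns %d-%d\n",
              length(x$rows), nchar(x$rows[1]),
              x$core_columns[1], x$core_columns[5]))
  invisible(x)
}

#' Column letters of an alignment
#'
#' @param alignment a `core_alignment`.
#' @param column column index.
#' @return character vector of per-row letters ("-" for gaps).
#' @export
alignment_column <- function(alignment, column) {
  stopifnot(column >= 1, column <= nchar(alignment$rows[1]))
  unname(substr(alignment$rows, column, column))
}

#' Write an alignment as gapped FASTA
#'
#' @param alignment a `core_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  write_fasta(alignment$rows, path)
}
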