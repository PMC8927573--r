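#' Default per-position core residue frequencies
#'
#' Position-specific residue frequency tables for the planted 5-position
#' SIL core, calibrated to a 33-member family: position 1 mostly R/K,
#' position 2 dominated by E with a minor D component and a fraction of
#' loops carrying no acidic residue at all, position 3 N/S, position 4
#' split across R/K/Q, position 5 mostly C. With these defaults the
#' consensus machinery recovers `[R/K] E [N/S] [R/K/Q] C`.
#'
#' @return list of five named numeric vectors, each summing to 1.
#' @export
default_core_frequencies <- function() {
  list(
    pos1 = c(R = 13, K = 11, G = 3, S = 3, T = 3) / 33,
    pos2 = c(E = 23, D = 2, S = 4, Q = 4) / 33,
    pos3 = c(N = 14, S = 9, T = 5, G = 5) / 33,
    pos4 = c(R = 9, K = 8, Q = 7, L = 3, G = 3, S = 3) / 33,
    pos5 = c(C = 20, S = 5, L = 5, F = 3) / 33
  )
}

#' Specification of a synthetic SIL family
#'
#' @param n number of family members (default 33, the human family size).
#' @param core per-position frequency tables, as
#'   [default_core_frequencies()]; each must sum to 1.
#' @param loop_len_range total loop length range, inclusive (default
#'   6..21, the span observed across human SILs; the 5-residue core plus
#'   random flanks is made to fit it).
#' @param background named probability vector for flank (and non-loop
#'   linker) residues. The default spans polar/aliphatic residues and
#'   deliberately excludes E, D, K and R so that flanks never steal the
#'   anchor from the planted core.
#' @param seed integer seed; generation is fully reproducible.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(n = 33, core = default_core_frequencies(),
                        loop_len_range = c(6, 21),
                        background = c(A = .14, G = .14, S = .14, T = .12,
                                       L = .12, V = .10, F = .08, N = .06,
                                       Q = .05, P = .05),
                        seed = 1L) {
  stopifnot(n >= 1, length(core) == 5,
            all(abs(vapply(core, sum, 1) - 1) < 1e-9),
            abs(sum(background) - 1) < 1e-9,
            loop_len_range[1] >= 5, loop_len_range[2] >= loop_len_range[1])
  structure(list(n = n, core = core, loop_len_range = loop_len_range,
                 background = background, seed = as.integer(seed)),
            class = "family_spec")
}

sample_bg <- function(n, background) {
  if (n <= 0) return("")
  paste(sample(names(background), n, replace = TRUE, prob = background),
        collapse = "")
}

#' Generate a synthetic topology-annotated sequence family
#'
#' Each member is built as N-term | TMS1 | linker | TMS2 | SIL | TMS3 |
#' linker | TMS4 | C-term, with poly-L transmembrane segments and
#' background-sampled soluble segments. The SIL is a planted core (one
#' residue per position, sampled from the per-position frequency tables)
#' padded with background flanks to a random total length inside
#' `loop_len_range`. Output is seed-reproducible byte for byte.
#'
#' @param spec a [family_spec()].
#' @param fasta,topology optional output paths; when given, the family
#'   is also written as FASTA plus a TSV topology sidecar.
#' @return named list of [sequence_record()]s; the planted core strings
#'   are attached as attribute `planted_core`.
#' @export
make_sil_family <- function(spec = family_spec(), fasta = NULL,
                            topology = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  tms_len <- 18L
  recs <- vector("list", spec$n)
  planted <- character(spec$n)
  for (i in seq_len(spec$n)) {
    core <- vapply(spec$core, function(p)
      sample(names(p), 1, prob = p), character(1))
    planted[i] <- paste(core, collapse = "")
    len <- sample(spec$loop_len_range[1]:spec$loop_len_range[2], 1)
    left <- sample(0:(len - 5L), 1)
    right <- len - 5L - left
    sil <- paste0(sample_bg(left, spec$background), planted[i],
                  sample_bg(right, spec$background))
    nterm <- paste0("M", sample_bg(7, spec$background), "K",
                    sample_bg(4, spec$background))   # basic juxtamembrane
    tms <- strrep("L", tms_len)
    seqs <- paste0(nterm, tms, sample_bg(4, spec$background), tms, sil,
                   tms, sample_bg(4, spec$background), tms,
                   sample_bg(5, spec$background))
    s1 <- nchar(nterm) + 1L
    s2 <- s1 + tms_len + 4L
    s3 <- s2 + tms_len + nchar(sil)
    s4 <- s3 + tms_len + 4L
    recs[[i]] <- sequence_record(
      id = sprintf("syn%02d", i), sequence = seqs,
      tms = rbind(c(s1, s1 + tms_len - 1L), c(s2, s2 + tms_len - 1L),
                  c(s3, s3 + tms_len - 1L), c(s4, s4 + tms_len - 1L)),
      species = "synthetic")
  }
  names(recs) <- vapply(recs, function(r) r$id, character(1))
  if (!is.null(fasta)) write_fasta(recs, fasta)
  if (!is.null(topology)) {
    topo <- do.call(rbind, lapply(recs, function(r)
      data.frame(id = r$id,
                 tms1_start = r$tms[1, 1], tms1_end = r$tms[1, 2],
                 tms2_start = r$tms[2, 1], tms2_end = r$tms[2, 2],
                 tms3_start = r$tms[3, 1], tms3_end = r$tms[3, 2],
                 tms4_start = r$tms[4, 1], tms4_end = r$tms[4, 2])))
    utils::write.table(topo, topology, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  attr(recs, "planted_core") <- planted
  recs
}

#' Synthetic 33-loop family matching the human anchoring composition
#'
#' A deterministic, fully synthetic set of 33 short loops whose anchor
#' composition matches the tallies reported for the human tetraspanin
#' family: 23 loops anchored at a glutamate, 2 at an aspartate, 8 with
#' neither acidic residue (anchored at a basic position-1 residue), and
#' 13 arginines plus 11 lysines in the position-1 column. The loop
#' sequences themselves are invented (this is a stand-in for the real
#' UniProt family, not derived from it); only the composition is
#' calibrated. Flank residues avoid all anchor classes.
#'
#' @return named character vector of 33 loops.
#' @export
synthetic_human_sil_stub <- function() {
  pos1 <- c(rep("R", 8), rep("K", 8),                # E-anchored rows ...
            c("G", "S", "T", "G", "S", "T", "G"),    # ... with non-basic pos1
            c("S", "T"),                             # D-anchored rows
            rep("R", 5), rep("K", 3))                # rows lacking E/D
  pos2 <- c(rep("E", 23), rep("D", 2),
            c("S", "T", "Q", "G", "S", "T", "Q", "G"))
  pos3 <- rep(c("N", "N", "S", "N", "S", "T", "N", "G", "N", "S", "N"), 3)
  pos4 <- rep(c("R", "K", "Q", "R", "K", "Q", "R", "K", "L", "G", "R"), 3)
  pos5 <- rep(c("C", "C", "S", "C", "C", "L", "C", "F", "C", "C", "S"), 3)
  left <- rep(c("", "G", "AG", "TSA"), length.out = 33)
  right <- rep(c("GT", "", "ASG", "T", "GASTG"), length.out = 33)
  loops <- paste0(left, pos1, pos2, pos3, pos4, pos5, right)
  stats::setNames(loops, sprintf("stub%02d", seq_len(33)))
}

#' Anchoring tallies of a loop set
#'
#' Runs [anchor_loop()] over a loop set and counts, per anchor class and
#' residue, how the family anchors; also counts the residues occupying
#' the position-1 column of the resulting alignment.
#'
#' @param loops named character vector of loops.
#' @param rule an [anchor_rule()].
#' @return named list of counts: `E_anchors`, `D_anchors`,
#'   `no_acidic` (loops lacking E and D), `unanchored`, and
#'   `pos1_R`/`pos1_K` (position-1 column composition).
#' @export
anchor_tallies <- function(loops, rule = sil_anchor_rule()) {
  anc <- lapply(loops, anchor_loop, rule = rule)
  letter_at <- function(s, i) substr(s, i, i)
  anchor_letter <- mapply(function(s, a)
    if (is.na(a$anchor_index)) NA_character_
    else letter_at(s, a$anchor_index), loops, anc)
  cls <- vapply(anc, `[[`, "", "matched_class")
  aln <- align_loops(loops, rule = rule)
  p1 <- alignment_column(aln, aln$core_columns[1])
  list(E_anchors = sum(anchor_letter == "E", na.rm = TRUE),
       D_anchors = sum(anchor_letter == "D", na.rm = TRUE),
       no_acidic = sum(is.na(cls) | cls != "acidic"),
       unanchored = sum(is.na(cls)),
       pos1_R = sum(p1 == "R"), pos1_K = sum(p1 == "K"))
}
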