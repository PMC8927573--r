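# Direction of a helix axis from consecutive CA positions (rows of m).
# For runs of >= 4 residues the ~1-turn offset vectors CA[k+3]-CA[k]
# average out the radial component; shorter runs fall back to the
# end-to-end vector. Returned unit vector points C-terminally.
helix_axis <- function(ca) {
  m <- nrow(ca)
  v <- if (m >= 4) {
    colMeans(ca[4:m, , drop = FALSE] - ca[1:(m - 3), , drop = FALSE])
  } else {
    ca[m, ] - ca[1, ]
  }
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) return(c(NA_real_, NA_real_, NA_real_))
  v / nv
}

#' Detect M-shaped inter-helix turns
#'
#' Scans a chain for five-residue windows whose Ramachandran classes read
#' (ALPHA_R, ALPHA_L, BETA, ALPHA_R, ALPHA_R) — the dihedral signature of
#' the M-motif: a compact 180-degree turn initiated by a left-handed
#' residue at position 2, bridged by a beta-conformation residue at
#' position 3, with helical character at positions 1, 4 and 5. A window
#' is a hit only if it is flanked on both sides by at least `flank_min`
#' consecutive well-defined ALPHA_R residues (the helical arms). For each
#' hit the RMS deviation of the 15 backbone atoms (N, CA, C of the five
#' residues) from their best-fit plane is reported, together with the
#' angle between the flanking helix axes; when `antiparallel` is TRUE
#' windows whose arms diverge by less than `axis_min_angle` degrees are
#' rejected (a genuine U-turn has nearly antiparallel arms).
#'
#' @param chain a `backbone_chain`.
#' @param regions Ramachandran region set.
#' @param flank_min minimum ALPHA_R flank run on each side (default 3).
#' @param antiparallel apply the flanking-axis angle filter (default TRUE).
#' @param axis_min_angle minimum inter-arm angle in degrees (default 120).
#' @param ca_break chain-break CA-CA cutoff for [phi_psi()].
#' @return data.frame, one row per hit: `chain`, `start_resno`,
#'   `end_resno`, `sequence`, `classes`, `planarity_rms`, `axis_angle`,
#'   `flank_up`, `flank_down` (flank run lengths). Zero rows if none.
#' @export
find_m_motifs <- function(chain, regions = default_rama_regions(),
                          flank_min = 3, antiparallel = TRUE,
                          axis_min_angle = 120, ca_break = 4.5) {
  stopifnot(inherits(chain, "backbone_chain"))
  rama <- rama_table(chain, regions = regions, ca_break = ca_break)
  n <- nrow(rama)
  empty <- data.frame(chain = character(), start_resno = integer(),
                      end_resno = integer(), sequence = character(),
                      classes = character(), planarity_rms = numeric(),
                      axis_angle = numeric(), flank_up = integer(),
                      flank_down = integer(), stringsAsFactors = FALSE)
  if (n < 5 + 2 * flank_min) return(empty)
  target <- c("ALPHA_R", "ALPHA_L", "BETA", "ALPHA_R", "ALPHA_R")
  helical <- rama$class == "ALPHA_R" & rama$defined

  run_len <- function(i, step) {        # consecutive helical run from i
    k <- 0L
    while (i >= 1 && i <= n && helical[i]) { k <- k + 1L; i <- i + step }
    k
  }
  one <- strsplit(chain_sequence(chain), "")[[1]]

  hits <- list()
  for (ws in seq_len(n - 4)) {
    win <- ws:(ws + 4)
    if (!all(rama$defined[win]) || !identical(rama$class[win], target)) next
    up <- run_len(ws - 1, -1L)
    down <- run_len(ws + 5, +1L)
    if (up < flank_min || down < flank_min) next
    # flanks must be contiguous in space too (no chain break hiding in a gap)
    pts <- do.call(rbind, lapply(win, function(i) {
      rbind(atom_xyz(chain, i, "N"), atom_xyz(chain, i, "CA"),
            atom_xyz(chain, i, "C"))
    }))
    prms <- plane_fit_rms(pts)
    ca_up <- do.call(rbind, lapply((ws - up):(ws - 1),
                                   function(i) atom_xyz(chain, i, "CA")))
    ca_dn <- do.call(rbind, lapply((ws + 5):(ws + 4 + down),
                                   function(i) atom_xyz(chain, i, "CA")))
    dt <- sum(helix_axis(ca_up) * helix_axis(ca_dn))
    # single-residue flanks have no measurable axis; the angle filter
    # cannot apply there and the angle is reported as NA
    ang <- if (is.na(dt)) NA_real_ else acos(max(-1, min(1, dt))) * 180 / pi
    if (antiparallel && !is.na(ang) && ang < axis_min_angle) next
    hits[[length(hits) + 1L]] <- data.frame(
      chain = chain$chain_id,
      start_resno = rama$resno[ws], end_resno = rama$resno[ws + 4],
      sequence = paste(one[win], collapse = ""),
      classes = paste(rama$class[win], collapse = ","),
      planarity_rms = prms, axis_angle = ang,
      flank_up = up, flank_down = down, stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  do.call(rbind, hits)
}
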