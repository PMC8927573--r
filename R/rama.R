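#' Default Ramachandran regions
#'
#' Rectangular (phi, psi) regions used to classify backbone conformation:
#' right-handed alpha (ALPHA_R), left-handed alpha (ALPHA_L) and beta
#' strand (BETA); anything else is OTHER. Edges are half-open
#' (lower bound included, upper excluded) except where a bound touches
#' the +180 end of the angular range. The beta region wraps across the
#' psi = 180/-180 seam.
#'
#' Each region is a list of rectangles `list(phi = c(lo, hi), psi = c(lo, hi))`.
#'
#' @return named list of regions.
#' @export
default_rama_regions <- function() {
  list(
    ALPHA_R = list(list(phi = c(-160, -20), psi = c(-120, 50))),
    BETA    = list(list(phi = c(-180, -20), psi = c(50, 180)),
                   list(phi = c(-180, -20), psi = c(-180, -150))),
    ALPHA_L = list(list(phi = c(20, 160), psi = c(-60, 90)))
  )
}

in_rect <- function(v, lim) {
  # half-open [lo, hi), but inclusive when hi is the +180 end of the range
  v >= lim[1] & (v < lim[2] | (lim[2] >= 180 & v <= 180))
}

#' Classify a (phi, psi) pair into a Ramachandran region
#'
#' @param phi,psi backbone dihedrals in degrees, range (-180, 180];
#'   vectors are recycled to common length.
#' @param regions region set as from [default_rama_regions()].
#' @return character vector of classes: "ALPHA_R", "ALPHA_L", "BETA" or
#'   "OTHER"; NA input gives "OTHER".
#' @export
classify_rama <- function(phi, psi, regions = default_rama_regions()) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  out <- rep("OTHER", n)
  for (cls in names(regions)) {
    hit <- rep(FALSE, n)
    for (rect in regions[[cls]])
      hit <- hit | (in_rect(phi, rect$phi) & in_rect(psi, rect$psi))
    take <- hit & out == "OTHER"      # regions are disjoint by construction
    out[take] <- cls
  }
  out[is.na(phi) | is.na(psi)] <- "OTHER"
  out
}

#' Ramachandran classes for a whole chain
#'
#' Convenience wrapper: [phi_psi()] followed by [classify_rama()].
#'
#' @param chain a `backbone_chain`.
#' @param regions Ramachandran region set.
#' @param ca_break chain-break CA-CA cutoff passed to [phi_psi()].
#' @return the [phi_psi()] data.frame with extra columns `class` and
#'   `defined` (both dihedrals available).
#' @export
rama_table <- function(chain, regions = default_rama_regions(),
                       ca_break = 4.5) {
  pp <- phi_psi(chain, ca_break = ca_break)
  pp$class <- classify_rama(pp$phi, pp$psi, regions)
  pp$defined <- !is.na(pp$phi) & !is.na(pp$psi)
  pp
}

#' Assign helical segments from Ramachandran classes
#'
#' A helix is a maximal run of at least `min_run` consecutive residues
#' classified ALPHA_R with both dihedrals defined. Undefined dihedrals
#' (termini, chain breaks) interrupt runs.
#'
#' @param rama data.frame from [rama_table()].
#' @param min_run minimum run length (default 4).
#' @return data.frame with columns `from`, `to` (row indices into `rama`),
#'   `resno_from`, `resno_to`, `length`; zero rows if no helix.
#' @export
assign_helices <- function(rama, min_run = 4) {
  ok <- rama$class == "ALPHA_R" & rama$defined
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  data.frame(from = starts[keep], to = ends[keep],
             resno_from = rama$resno[starts[keep]],
             resno_to = rama$resno[ends[keep]],
             length = r$lengths[keep])
}
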