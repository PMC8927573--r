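#' Default turn dihedrals for a planted M-motif
#'
#' Per-position (phi, psi) for the five turn residues: alpha-R at
#' positions 1, 4, 5; left-handed at 2; beta at 3. The values sit well
#' inside the default Ramachandran rectangles so classification is
#' insensitive to moderate region re-configuration.
#'
#' @return 5x2 matrix with columns phi, psi (degrees).
#' @export
default_turn_dihedrals <- function() {
  m <- rbind(c(-57, -47), c(60, 45), c(-120, 130), c(-57, -47), c(-57, -47))
  colnames(m) <- c("phi", "psi")
  m
}

# renumber residues of a chain (vector of new author numbers, one per residue)
renumber_chain <- function(chain, new_resno) {
  stopifnot(length(new_resno) == nrow(chain$residues))
  key <- paste(chain$atoms$resno, chain$atoms$ins, sep = "|")
  old <- paste(chain$residues$resno, chain$residues$ins, sep = "|")
  chain$atoms$resno <- new_resno[match(key, old)]
  backbone_chain(chain$atoms, chain_id = chain$chain_id)
}

translate_chain <- function(chain, v) {
  chain$atoms$x <- chain$atoms$x + v[1]
  chain$atoms$y <- chain$atoms$y + v[2]
  chain$atoms$z <- chain$atoms$z + v[3]
  chain
}

#' Synthetic helix-turn-helix backbone with a planted M-motif
#'
#' Builds two alpha-helical arms (ideal helix dihedrals phi = -57,
#' psi = -47) joined by a five-residue turn with the given per-position
#' dihedrals. With the defaults the turn classifies as
#' (ALPHA_R, ALPHA_L, BETA, ALPHA_R, ALPHA_R) and the arms fold back
#' antiparallel, so [find_m_motifs()] finds exactly the planted window.
#' Optional Gaussian jitter on all dihedrals supports robustness tests
#' of the detector.
#'
#' @param n1,n2 lengths of the upstream/downstream helical arms
#'   (n1 = 0 builds a turn with no upstream arm).
#' @param turn_dihedrals 5x2 matrix (phi, psi), default
#'   [default_turn_dihedrals()].
#' @param turn_sequence five one-letter residues for the turn
#'   (default "QESQC").
#' @param jitter_sd standard deviation (degrees) of Gaussian noise added
#'   to every phi/psi; default 0.
#' @param seed optional integer seed (only relevant when jitter_sd > 0).
#' @return list with `chain` (a [backbone_chain()]), `window` (residue
#'   indices of the planted turn) and `torsions` (the torsion table used).
#' @export
make_m_hairpin <- function(n1 = 8, n2 = 8,
                           turn_dihedrals = default_turn_dihedrals(),
                           turn_sequence = "QESQC",
                           jitter_sd = 0, seed = NULL) {
  stopifnot(n1 >= 0, n2 >= 2, nrow(turn_dihedrals) == 5,
            nchar(turn_sequence) == 5)
  phi <- c(rep(-57, n1), turn_dihedrals[, 1], rep(-57, n2))
  psi <- c(rep(-47, n1), turn_dihedrals[, 2], rep(-47, n2))
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    phi <- phi + stats::rnorm(length(phi), 0, jitter_sd)
    psi <- psi + stats::rnorm(length(psi), 0, jitter_sd)
  }
  tor <- data.frame(phi = phi, psi = psi, omega = 180)
  seqs <- paste0(strrep("A", n1), turn_sequence, strrep("A", n2))
  chain <- build_backbone(tor, sequence = seqs)
  list(chain = chain, window = (n1 + 1):(n1 + 5), torsions = tor)
}

# append extra atoms (data.frame rows elety/resid/resno/ins/x/y/z) to a chain
add_atoms <- function(chain, extra) {
  backbone_chain(rbind(chain$atoms, extra), chain_id = chain$chain_id)
}

sidechain_row <- function(elety, resid, resno, p) {
  data.frame(elety = elety, resid = resid, resno = resno, ins = "",
             x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
}

#' Minimal Lys/Glu pair with a prescribed NZ-carboxylate distance
#'
#' Constructs a toy structure with one lysine and one glutamate whose
#' minimum NZ to OE1/OE2 heavy-atom distance is exactly `d` Angstrom —
#' a controlled fixture for the inclusive 4.0 Angstrom salt-bridge
#' cutoff. The two residues are far apart in sequence (1 and 10) and not
#' peptide-bonded.
#'
#' @param d target minimum distance in Angstrom (> 0).
#' @param path optional file path; when given the structure is also
#'   written as PDB.
#' @return a [backbone_chain()] with the two residues.
#' @export
make_salt_bridge_toy <- function(d, path = NULL) {
  stopifnot(d > 0)
  lys_bb <- rbind(N = c(0, 0, 0), CA = c(1.458, 0, 0),
                  C = c(2.0, 1.4, 0), O = c(1.5, 2.5, 0))
  lys_sc <- rbind(CB = c(1.458, -1.53, 0), CG = c(1.458, -2.8, 0.5),
                  CD = c(1.458, -4.1, 0.2), CE = c(1.458, -5.4, 0.6),
                  NZ = c(1.458, -6.6, 0.2))
  nz <- lys_sc["NZ", ]
  oe1 <- nz + c(d, 0, 0)                       # exact minimum by construction
  oe2 <- oe1 + c(1.4, 1.6, 0)
  cd  <- oe1 + c(0.6, -1.1, 0)
  glu <- rbind(OE1 = oe1, OE2 = oe2, CD = cd, CG = cd + c(1.3, -0.8, 0),
               CB = cd + c(2.6, -1.4, 0), CA = cd + c(3.9, -0.9, 0),
               N = cd + c(4.4, 0.4, 0), C = cd + c(5.2, -1.7, 0),
               O = cd + c(6.3, -1.2, 0))
  atoms <- rbind(
    do.call(rbind, lapply(rownames(lys_bb), function(a)
      sidechain_row(a, "LYS", 1L, lys_bb[a, ]))),
    do.call(rbind, lapply(rownames(lys_sc), function(a)
      sidechain_row(a, "LYS", 1L, lys_sc[a, ]))),
    do.call(rbind, lapply(c("N", "CA", "CB", "CG", "CD", "OE1", "OE2",
                            "C", "O"), function(a)
      sidechain_row(a, "GLU", 10L, glu[a, ]))))
  chain <- backbone_chain(atoms, chain_id = "A")
  if (!is.null(path)) write_structure(chain, path)
  chain
}

# a crude glutamate carboxylate grafted onto backbone atoms of residue i:
# CB-CG-CD extend away from the backbone, OE1/OE2 fork off CD
graft_glu_sidechain <- function(chain, i) {
  ca <- atom_xyz(chain, i, "CA"); nn <- atom_xyz(chain, i, "N")
  cc <- atom_xyz(chain, i, "C")
  u <- ca - (nn + cc) / 2
  u <- u / sqrt(sum(u^2))
  w <- cross3(u, cc - nn); w <- w / sqrt(sum(w^2))
  cb <- ca + 1.53 * u
  cg <- cb + 1.52 * u
  cd <- cg + 1.52 * u
  oe1 <- cd + 1.25 * (cos(pi / 6) * u + sin(pi / 6) * w)
  oe2 <- cd + 1.25 * (cos(pi / 6) * u - sin(pi / 6) * w)
  rn <- chain$residues$resno[i]
  extra <- rbind(sidechain_row("CB", "GLU", rn, cb),
                 sidechain_row("CG", "GLU", rn, cg),
                 sidechain_row("CD", "GLU", rn, cd),
                 sidechain_row("OE1", "GLU", rn, oe1),
                 sidechain_row("OE2", "GLU", rn, oe2))
  list(chain = add_atoms(chain, extra), oe1 = oe1, oe2 = oe2)
}

# lysine side chain from CA of residue i to an exact NZ target position
graft_lys_sidechain <- function(chain, i, nz) {
  ca <- atom_xyz(chain, i, "CA")
  rn <- chain$residues$resno[i]
  names <- c("CB", "CG", "CD", "CE", "NZ")
  extra <- do.call(rbind, lapply(seq_along(names), function(k) {
    sidechain_row(names[k], "LYS", rn, ca + (k / 5) * (nz - ca))
  }))
  add_atoms(chain, extra)
}

#' Synthetic tetraspanin-like stand-in structures
#'
#' Builds a fully synthetic backbone that emulates the published SIL
#' geometry of two tetraspanin crystal structures; it is NOT derived from
#' any PDB entry, and the reported distances are planted by construction.
#' `"CD9"` mimics CD9: a TMS2-SIL-TMS3 hairpin whose turn reads QESQC at
#' author numbers 83-87, plus a short N-terminal helix carrying K11 whose
#' NZ atom is placed 2.8 Angstrom from the E84 carboxylate (the published
#' salt-bridge distance). `"CD53"` mimics CD53: turn KENKS at 76-80 (the
#' crystallised construct carries C80S) and an N-terminal helix with K7
#' and K10 placed 5.1 and 5.2 Angstrom from the E77 carboxylate — too far
#' for a salt bridge at the 4 Angstrom criterion.
#'
#' @param protein `"CD9"` or `"CD53"`.
#' @param helix_len length of the TMS-like helical arms (default 19).
#' @return list with `chain` (a [backbone_chain()]), `sil_resno` (author
#'   numbers of the five turn residues) and `planted` (named distances in
#'   Angstrom that the construction embeds).
#' @export
make_tetraspanin_stub <- function(protein = c("CD9", "CD53"),
                                  helix_len = 19) {
  protein <- match.arg(protein)
  p <- if (protein == "CD9") {
    list(turn_seq = "QESQC", turn_start = 83L, glu = 84L,
         lys = c(11L), dist = c(2.8), nterm_start = 3L,
         nterm_seq = "AAAAAAAAKA")          # K at author position 11
  } else {
    list(turn_seq = "KENKS", turn_start = 76L, glu = 77L,
         lys = c(7L, 10L), dist = c(5.1, 5.2), nterm_start = 3L,
         nterm_seq = "AAAAKAAKAA")          # K at author positions 7 and 10
  }
  hp <- make_m_hairpin(n1 = helix_len, n2 = helix_len,
                       turn_sequence = p$turn_seq)
  chain <- renumber_chain(hp$chain,
                          seq(p$turn_start - helix_len,
                              length.out = helix_len * 2 + 5))
  glu_i <- which(chain$residues$resno == p$glu)
  g <- graft_glu_sidechain(chain, glu_i)
  chain <- g$chain
  w <- g$oe1 - g$oe2
  w <- w / sqrt(sum(w^2))                   # points away from OE2 through OE1

  # N-terminal helical segment, rigidly displaced from the hairpin
  nt_tor <- data.frame(phi = rep(-57, 10), psi = rep(-47, 10), omega = 180)
  nt <- build_backbone(nt_tor, sequence = p$nterm_seq)
  nt <- renumber_chain(nt, seq(p$nterm_start, length.out = 10))
  nz1 <- g$oe1 + p$dist[1] * w
  anchor_ca <- atom_xyz(nt, which(nt$residues$resno == p$lys[1]), "CA")
  nt <- translate_chain(nt, nz1 + 5.5 * w - anchor_ca)
  for (k in seq_along(p$lys)) {
    # second lysine (CD53) sits on a slightly rotated direction so its
    # carboxylate distance differs from the first
    wk <- if (k == 1) w else {
      axis <- cross3(w, c(0, 0, 1)); axis <- axis / sqrt(sum(axis^2))
      rot_about(w, axis, 20)
    }
    nzk <- g$oe1 + p$dist[k] * wk
    nt <- graft_lys_sidechain(nt, which(nt$residues$resno == p$lys[k]), nzk)
  }
  chain <- backbone_chain(rbind(nt$atoms, chain$atoms), chain_id = "A")
  list(chain = chain,
       sil_resno = seq(p$turn_start, length.out = 5),
       planted = stats::setNames(p$dist, paste0("K", p$lys, "-E", p$glu)))
}

# Rodrigues rotation of vector v about unit axis by `deg` degrees
rot_about <- function(v, axis, deg) {
  th <- deg * pi / 180
  v * cos(th) + cross3(axis, v) * sin(th) + axis * sum(axis * v) * (1 - cos(th))
}
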