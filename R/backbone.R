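#' Backbone chain container
#'
#' An ordered set of residues from one chain with their heavy-atom
#' coordinates. The atom table keeps every heavy atom that survived the
#' altloc/model policy (side chains included, for contact screening); the
#' residue table records author numbering (residue number + insertion
#' code) and whether the four backbone atoms N, CA, C, O are all present.
#'
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (3-letter residue name), `resno` (author residue number), `ins`
#'   (insertion code, "" if none), `x`, `y`, `z` (Angstrom).
#' @param chain_id single chain identifier.
#' @return object of class `backbone_chain`.
#' @export
backbone_chain <- function(atoms, chain_id = "A") {
  stopifnot(is.data.frame(atoms),
            all(c("elety", "resid", "resno", "ins", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("backbone_chain: non-finite coordinates")
  key <- paste(atoms$resno, atoms$ins, sep = "|")
  ord <- unique(key)                       # source order preserved
  res <- data.frame(
    resno = atoms$resno[match(ord, key)],
    ins   = atoms$ins[match(ord, key)],
    resid = atoms$resid[match(ord, key)],
    stringsAsFactors = FALSE
  )
  res$complete <- vapply(ord, function(k) {
    all(c("N", "CA", "C", "O") %in% atoms$elety[key == k])
  }, logical(1))
  structure(list(chain_id = chain_id, atoms = atoms, residues = res),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("backbone_chain %s: %d residues, %d atoms (%d incomplete)\n",
              x$chain_id, nrow(x$residues), nrow(x$atoms),
              sum(!x$residues$complete)))
  invisible(x)
}

#' @export
length.backbone_chain <- function(x) nrow(x$residues)

#' Coordinates of one named atom of a residue
#'
#' @param x a `backbone_chain`.
#' @param i residue index (row of `x$residues`).
#' @param name atom name (e.g. "CA", "NZ").
#' @return numeric length-3 xyz in Angstrom, or NULL if absent.
#' @export
atom_xyz <- function(x, i, name) {
  a <- x$atoms
  sel <- a$resno == x$residues$resno[i] & a$ins == x$residues$ins[i] &
    a$elety == name
  if (!any(sel)) return(NULL)
  as.numeric(a[which(sel)[1], c("x", "y", "z")])
}

#' One-letter residue sequence of a chain
#'
#' @param chain a `backbone_chain`.
#' @return character scalar; unknown residue names become "X".
#' @export
chain_sequence <- function(chain) {
  one <- suppressWarnings(bio3d::aa321(chain$residues$resid))
  one[is.na(one) | one == ""] <- "X"
  paste(one, collapse = "")
}

#' Backbone phi/psi dihedrals
#'
#' Computes phi(i) from C(i-1)-N(i)-CA(i)-C(i) and psi(i) from
#' N(i)-CA(i)-C(i)-N(i+1). An angle is NA for chain termini, for residues
#' with missing backbone atoms, and across chain breaks (consecutive
#' CA-CA distance above `ca_break` Angstrom, default 4.5).
#'
#' @param chain a `backbone_chain`.
#' @param ca_break CA-CA distance (Angstrom) beyond which consecutive
#'   residues are treated as disconnected.
#' @return data.frame with columns resno, ins, resid, phi, psi (degrees).
#' @export
phi_psi <- function(chain, ca_break = 4.5) {
  stopifnot(inherits(chain, "backbone_chain"))
  n <- nrow(chain$residues)
  N  <- lapply(seq_len(n), function(i) atom_xyz(chain, i, "N"))
  CA <- lapply(seq_len(n), function(i) atom_xyz(chain, i, "CA"))
  C  <- lapply(seq_len(n), function(i) atom_xyz(chain, i, "C"))
  linked <- function(i, j) {          # are residues i and j bonded neighbours?
    !is.null(CA[[i]]) && !is.null(CA[[j]]) &&
      sqrt(sum((CA[[i]] - CA[[j]])^2)) <= ca_break
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.null(N[[i]]) || is.null(CA[[i]]) || is.null(C[[i]])) next
    if (i > 1 && !is.null(C[[i - 1]]) && linked(i - 1, i))
      phi[i] <- dihedral(C[[i - 1]], N[[i]], CA[[i]], C[[i]])
    if (i < n && !is.null(N[[i + 1]]) && linked(i, i + 1))
      psi[i] <- dihedral(N[[i]], CA[[i]], C[[i]], N[[i + 1]])
  }
  data.frame(resno = chain$residues$resno, ins = chain$residues$ins,
             resid = chain$residues$resid, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}
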