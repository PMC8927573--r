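# Side-chain atom sets used for charge-charge screening. Histidine is
# not treated as basic by default (only Lys/Arg carry a reliable positive
# charge at physiological pH); hydrogens are ignored throughout.
basic_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
acidic_atoms <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))
# polar side-chain O/N donors/acceptors for the polar-contact mode
polar_sidechain_atoms <- list(
  ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"), SER = "OG", THR = "OG1",
  TYR = "OH", HIS = c("ND1", "NE2"), TRP = "NE1",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

res_atoms <- function(chain, i, names) {
  a <- chain$atoms
  sel <- a$resno == chain$residues$resno[i] & a$ins == chain$residues$ins[i] &
    a$elety %in% names
  a[sel, c("elety", "x", "y", "z")]
}

min_atom_dist <- function(A, B) {
  # minimum pairwise distance between two small atom tables
  best <- list(d = Inf, a = NA_character_, b = NA_character_)
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt(sum((as.numeric(A[i, c("x", "y", "z")]) -
                   as.numeric(B[j, c("x", "y", "z")]))^2))
    if (d < best$d) best <- list(d = d, a = A$elety[i], b = B$elety[j])
  }
  best
}

# parse a pair label like "K11" into list(aa = "K", resno = 11)
parse_res_label <- function(lab) {
  m <- regmatches(lab, regexec("^([A-Za-z])(-?[0-9]+)$", lab))[[1]]
  if (length(m) != 3) stop("cannot parse residue label: ", lab)
  list(aa = toupper(m[2]), resno = as.integer(m[3]))
}

find_residue <- function(chain, lab) {
  p <- parse_res_label(lab)
  one <- suppressWarnings(bio3d::aa321(chain$residues$resid))
  i <- which(chain$residues$resno == p$resno & one == p$aa)
  if (!length(i))
    stop(sprintf("residue %s not found in chain %s", lab, chain$chain_id))
  i[1]
}

#' Screen residue pairs for salt bridges or polar contacts
#'
#' For each candidate residue pair, reports the minimum heavy-atom
#' distance over the configured atom sets. In `salt_bridge` mode the
#' donors are the Lys/Arg side-chain nitrogens and the acceptors the
#' Glu/Asp carboxylate oxygens, with an inclusive cutoff of 4.0 Angstrom
#' (the distance at or below which an ion pair is counted as a salt
#' bridge). In `polar` mode side-chain O/N atoms are screened against
#' backbone N/O atoms with a default cutoff of 3.5 Angstrom.
#'
#' @param chain a `backbone_chain` (the atom table must include the
#'   relevant side-chain atoms; residues missing them are skipped with a
#'   warning).
#' @param pairs optional character vector of explicit pairs
#'   `"K11:E84"`-style (one-letter code + author residue number,
#'   donor:acceptor). When NULL, all donor x acceptor residue pairs in
#'   the chain are screened.
#' @param mode `"salt_bridge"` or `"polar"`.
#' @param cutoff distance cutoff in Angstrom; defaults to 4.0 for
#'   salt bridges, 3.5 for polar contacts. The flag column is inclusive:
#'   `distance <= cutoff`.
#' @return data.frame, one row per screened pair: donor/acceptor residue
#'   name + number, closest atom names, `distance` (Angstrom) and
#'   `is_salt_bridge` (or `is_contact` in polar mode).
#' @export
contact_scan <- function(chain, pairs = NULL,
                         mode = c("salt_bridge", "polar"), cutoff = NULL) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "salt_bridge") 4.0 else 3.5
  stopifnot(cutoff > 0)
  res <- chain$residues

  atoms_for <- function(i, role) {
    rn <- res$resid[i]
    names <- if (mode == "salt_bridge") {
      if (role == "donor") basic_atoms[[rn]] else acidic_atoms[[rn]]
    } else {
      if (role == "donor") polar_sidechain_atoms[[rn]] else c("N", "O")
    }
    if (is.null(names)) return(NULL)
    res_atoms(chain, i, names)
  }

  if (is.null(pairs)) {
    donors <- which(res$resid %in% names(if (mode == "salt_bridge")
      basic_atoms else polar_sidechain_atoms))
    acceptors <- if (mode == "salt_bridge")
      which(res$resid %in% names(acidic_atoms)) else seq_len(nrow(res))
    cand <- expand.grid(d = donors, a = acceptors)
    cand <- cand[cand$d != cand$a, , drop = FALSE]
  } else {
    idx <- lapply(strsplit(pairs, ":", fixed = TRUE), function(p) {
      if (length(p) != 2) stop("pair must be donor:acceptor, got: ",
                               paste(p, collapse = ":"))
      c(find_residue(chain, p[1]), find_residue(chain, p[2]))
    })
    cand <- data.frame(d = vapply(idx, `[`, 1L, 1),
                       a = vapply(idx, `[`, 1L, 2))
  }

  out <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$d[k]; j <- cand$a[k]
    A <- atoms_for(i, "donor"); B <- atoms_for(j, "acceptor")
    if (is.null(A) || is.null(B)) {
      warning(sprintf("residue %s%d or %s%d has no screened atom set; skipped",
                      res$resid[i], res$resno[i], res$resid[j], res$resno[j]))
      next
    }
    if (!nrow(A) || !nrow(B)) {
      warning(sprintf("missing side-chain atoms for %s%d/%s%d; pair skipped",
                      res$resid[i], res$resno[i], res$resid[j], res$resno[j]))
      next
    }
    m <- min_atom_dist(A, B)
    out[[length(out) + 1L]] <- data.frame(
      donor_resid = res$resid[i], donor_resno = res$resno[i],
      donor_ins = res$ins[i], donor_atom = m$a,
      acceptor_resid = res$resid[j], acceptor_resno = res$resno[j],
      acceptor_ins = res$ins[j], acceptor_atom = m$b,
      distance = m$d, flag = m$d <= cutoff, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    out <- data.frame(donor_resid = character(), donor_resno = integer(),
                      donor_ins = character(), donor_atom = character(),
                      acceptor_resid = character(), acceptor_resno = integer(),
                      acceptor_ins = character(), acceptor_atom = character(),
                      distance = numeric(), flag = logical(),
                      stringsAsFactors = FALSE)
  } else out <- do.call(rbind, out)
  names(out)[names(out) == "flag"] <-
    if (mode == "salt_bridge") "is_salt_bridge" else "is_contact"
  out
}
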