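#' Read a protein chain from a PDB or mmCIF file
#'
#' Format is sniffed from the extension (.cif/.mmcif vs anything else)
#' and falls back on content (a `_atom_site` loop marks mmCIF). Only the
#' first model of multi-model files is used. Alternate locations are
#' resolved per atom: highest occupancy wins, ties go to the
#' alphabetically first altloc id. Hydrogens and HETATM records are
#' dropped; author residue numbering and insertion codes are preserved.
#'
#' @param path file path.
#' @param chain author chain identifier; if NA and the file holds exactly
#'   one chain, that chain is used.
#' @return a [backbone_chain()].
#' @export
read_structure <- function(path, chain = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  is_cif <- ext %in% c("cif", "mmcif")
  if (!is_cif && !ext %in% c("pdb", "ent")) {
    head_lines <- readLines(path, n = 200, warn = FALSE)
    is_cif <- any(grepl("^_atom_site\\.", head_lines))
  }
  pdb <- if (is_cif) bio3d::read.cif(path, multi = FALSE, verbose = FALSE)
         else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                              verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)

  chains <- unique(at$chain)
  if (is.na(chain)) {
    if (length(chains) > 1)
      stop("file has several chains (", paste(chains, collapse = ", "),
           "); pick one")
    chain <- chains[1]
  }
  if (!chain %in% chains)
    stop("chain ", chain, " not present; available: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  at <- at[!grepl("^H", at$elety), , drop = FALSE]

  # altloc policy: highest occupancy, then first alphabetically
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  if (any(at$alt != "")) {
    at$o[is.na(at$o)] <- 1
    at$.src <- seq_len(nrow(at))
    akey <- paste(at$resno, at$insert, at$elety, sep = "|")
    at <- at[order(akey, -at$o, at$alt), , drop = FALSE]
    at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "|")), ,
             drop = FALSE]
    at <- at[order(at$.src), , drop = FALSE]
  }
  atoms <- data.frame(elety = at$elety, resid = at$resid,
                      resno = at$resno, ins = at$insert,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  backbone_chain(atoms, chain_id = chain)
}

#' Write a backbone chain as a one-model PDB file
#'
#' @param chain a `backbone_chain`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(chain, path) {
  a <- chain$atoms
  n <- nrow(a)
  ins <- a$ins
  ins[!nzchar(ins)] <- NA
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, insert = ins,
                   eleno = seq_len(n), elety = a$elety,
                   chain = rep(chain$chain_id, n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}
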