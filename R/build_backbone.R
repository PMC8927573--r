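#' Standard peptide backbone geometry
#'
#' Bond lengths and angles used by [build_backbone()]: N-CA 1.458, CA-C
#' 1.525, C-N 1.329, C-O 1.231 Angstrom; angles N-CA-C 111.2, CA-C-N
#' 116.2, C-N-CA 121.7, CA-C-O 120.8 degrees; omega defaults to 180
#' (trans peptide bond).
#'
#' @return named list of geometry constants.
#' @export
peptide_geometry <- function() {
  list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
       a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
       a_ca_c_o = 120.8, omega = 180)
}

# NeRF placement: position of atom D given the three preceding atoms
# A-B-C, the C-D bond length r, the B-C-D angle theta and the A-B-C-D
# torsion tau (degrees).
nerf_place <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180
  ta <- tau * pi / 180
  d2 <- r * c(-cos(th), sin(th) * cos(ta), sin(th) * sin(ta))
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("nerf_place: collinear reference atoms")
  n <- n / nn
  m <- cross3(n, bc)
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a backbone chain from phi/psi/omega torsions
#'
#' Torsion-to-Cartesian construction: atoms N, CA, C, O are placed
#' sequentially from internal coordinates (natural-extension-reference-frame
#' style) using the bond lengths and angles of `geometry`. The first
#' residue is placed in a canonical frame (N at the origin, CA on +x,
#' C in the xy-plane), so `phi[1]` is never consumed; `psi[i]` sets the
#' position of N(i+1) and of O(i) (O is placed anti to the following N),
#' and `omega[i]` the CA(i) position across the peptide bond.
#'
#' @param torsions data.frame with columns `phi`, `psi` and optionally
#'   `omega` (degrees), one row per residue; >= 2 rows.
#' @param sequence optional one-letter residue string (length = rows);
#'   defaults to poly-alanine.
#' @param geometry list from [peptide_geometry()].
#' @param chain_id chain identifier for the result.
#' @return a [backbone_chain()] with residues numbered 1..n.
#' @export
build_backbone <- function(torsions, sequence = NULL,
                           geometry = peptide_geometry(), chain_id = "A") {
  torsions <- as.data.frame(torsions)
  n <- nrow(torsions)
  if (n < 2) stop("build_backbone: need at least 2 residues")
  if (is.null(torsions$omega)) torsions$omega <- geometry$omega
  g <- geometry
  if (any(unlist(g[c("b_n_ca", "b_ca_c", "b_c_n", "b_c_o")]) <= 0))
    stop("build_backbone: non-positive bond length")
  angs <- unlist(g[c("a_n_ca_c", "a_ca_c_n", "a_c_n_ca", "a_ca_c_o")])
  if (any(angs <= 0 | angs >= 180))
    stop("build_backbone: bond angles must lie strictly inside (0, 180)")
  if (anyNA(torsions$phi[-1]) || anyNA(torsions$psi[-n]) ||
      anyNA(torsions$omega[-1]))
    stop("build_backbone: NA torsion where one is required")
  if (is.na(torsions$psi[n])) torsions$psi[n] <- 180  # only places O(n)
  if (is.null(sequence)) sequence <- strrep("A", n)
  res3 <- bio3d::aa123(strsplit(sequence, "")[[1]])
  if (length(res3) != n) stop("build_backbone: sequence length != torsion rows")

  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ]  <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  a0 <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(a0), sin(a0), 0)
  for (i in 2:n) {
    N[i, ]  <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          g$b_c_n, g$a_ca_c_n, torsions$psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, torsions$omega[i])
    C[i, ]  <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                          g$b_ca_c, g$a_n_ca_c, torsions$phi[i])
  }
  for (i in 1:n)
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, torsions$psi[i] + 180)

  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(elety = c("N", "CA", "C", "O"),
               resid = res3[i], resno = i, ins = "",
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
               stringsAsFactors = FALSE)
  }))
  backbone_chain(atoms, chain_id = chain_id)
}
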