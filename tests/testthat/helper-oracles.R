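# Independent oracles and small fixture helpers. Each oracle takes a
# deliberately different computational route from the implementation it
# checks.

# --- dihedral oracle: project the outer bonds onto the plane normal to
# the central bond and take the signed angle between the projections.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  bh <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * bh) * bh
  v <- (p4 - p3) - sum((p4 - p3) * bh) * bh
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sum(cr * bh), sum(u * v)) * 180 / pi
}

ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# --- plane RMS oracle: direct numeric minimisation over the unit normal
# parameterised by spherical angles, multi-start.
oracle_plane_rms <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  f <- function(par) {
    n <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
    sqrt(mean((ctr %*% n)^2))
  }
  starts <- list(c(0.1, 0.1), c(pi / 2, 0), c(pi / 2, pi / 2), c(1, 2),
                 c(2, 4), c(2.5, 1))
  min(vapply(starts, function(s)
    stats::optim(s, f, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$value,
    numeric(1)))
}

# --- brute-force column frequency tally
oracle_colfreq <- function(letters1) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  counts <- integer(20)
  names(counts) <- aa
  for (ch in letters1) if (ch %in% aa) counts[ch] <- counts[ch] + 1L
  n <- sum(counts)
  list(counts = counts, n_non_gap = n,
       f = if (n > 0) counts / n else rep(NA_real_, 20))
}

# --- brute-force re-evaluation of the f >= f_mean + SD rule; the >= is
# inclusive at algebraic ties (f exactly equal to the threshold), so the
# comparison carries a float tolerance against last-bit rounding
oracle_consensus <- function(f) {
  m <- sum(f) / 20
  sdev <- sqrt(sum((f - m)^2) / 20)
  thr <- m + sdev
  keep <- names(f)[f >= thr - 1e-12]
  keep[order(-f[keep], keep)]
}

# --- independent backbone kinematics: atom placement by explicit
# axis-angle rotation matrices (Rodrigues), cis reference + torsion spin.
rotmat <- function(axis, deg) {
  th <- deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

oracle_place <- function(A, B, C, r, theta, tau) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  n0 <- c((A - B)[2] * bc[3] - (A - B)[3] * bc[2],
          (A - B)[3] * bc[1] - (A - B)[1] * bc[3],
          (A - B)[1] * bc[2] - (A - B)[2] * bc[1])
  n0 <- n0 / sqrt(sum(n0^2))
  u <- (A - B) - sum((A - B) * bc) * bc       # cis reference direction
  cand1 <- as.numeric(rotmat(n0, theta) %*% (-bc))
  cand2 <- as.numeric(rotmat(n0, -theta) %*% (-bc))
  d0 <- if (sum(cand1 * u) > sum(cand2 * u)) cand1 else cand2
  C + r * as.numeric(rotmat(bc, tau) %*% d0)
}

oracle_build_backbone <- function(torsions, g = peptide_geometry()) {
  n <- nrow(torsions)
  if (is.null(torsions$omega)) torsions$omega <- 180
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  a0 <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(a0), sin(a0), 0)
  for (i in 2:n) {
    N[i, ] <- oracle_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, torsions$psi[i - 1])
    CA[i, ] <- oracle_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, torsions$omega[i])
    C[i, ] <- oracle_place(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, torsions$phi[i])
  }
  list(N = N, CA = CA, C = C)
}

# --- misc fixture helpers
random_rigid <- function() {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, sd = 10))
}

apply_rigid <- function(p, tr) as.numeric(tr$R %*% p + tr$t)

transform_chain <- function(chain, tr) {
  xyz <- t(apply(as.matrix(chain$atoms[, c("x", "y", "z")]), 1,
                 apply_rigid, tr = tr))
  chain$atoms$x <- xyz[, 1]; chain$atoms$y <- xyz[, 2]
  chain$atoms$z <- xyz[, 3]
  chain
}

# a core_alignment holding one column of interest: each row is a single
# letter (or "-"/"X"), so column 1 is the column under test
single_column_alignment <- function(letters1) {
  structure(list(rows = stats::setNames(letters1,
                                        paste0("r", seq_along(letters1))),
                 anchor_column = 1L, core_columns = 1:5,
                 anchors = NULL, excluded = character(0)),
            class = "core_alignment")
}

# random residue column: dirichlet-ish composition, optional gaps/X
random_column <- function(nrow = sample(5:40, 1), gap_frac = 0.1) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  w <- rexp(20)^2
  pool <- sample(aa, nrow, replace = TRUE, prob = w / sum(w))
  gaps <- runif(nrow) < gap_frac
  pool[gaps] <- sample(c("-", "X"), sum(gaps), replace = TRUE)
  pool
}
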