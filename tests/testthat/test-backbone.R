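test_that("build_backbone/phi_psi round-trips ideal helix torsions", {
  ch <- build_backbone(data.frame(phi = rep(-57, 12), psi = rep(-47, 12)))
  pp <- phi_psi(ch)
  expect_true(all(abs(pp$phi[2:12] + 57) < 1e-6))
  expect_true(all(abs(pp$psi[1:11] + 47) < 1e-6))
  expect_true(is.na(pp$phi[1]) && is.na(pp$psi[12]))
})

test_that("every bond length in built backbones equals its geometry constant", {
  g <- peptide_geometry()
  ch <- build_backbone(data.frame(phi = runif(8, -180, 180),
                                  psi = runif(8, -180, 180)))
  for (i in 1:8) {
    n <- atom_xyz(ch, i, "N"); ca <- atom_xyz(ch, i, "CA")
    cc <- atom_xyz(ch, i, "C"); o <- atom_xyz(ch, i, "O")
    expect_equal(sqrt(sum((ca - n)^2)), g$b_n_ca, tolerance = 1e-9)
    expect_equal(sqrt(sum((cc - ca)^2)), g$b_ca_c, tolerance = 1e-9)
    expect_equal(sqrt(sum((o - cc)^2)), g$b_c_o, tolerance = 1e-9)
    if (i < 8) {
      n2 <- atom_xyz(ch, i + 1, "N")
      expect_equal(sqrt(sum((n2 - cc)^2)), g$b_c_n, tolerance = 1e-9)
    }
  }
})

test_that("built coordinates match the independent rotation-matrix oracle", {
  set.seed(23)
  for (k in 1:20) {
    n <- sample(3:12, 1)
    tor <- data.frame(phi = runif(n, -175, 175), psi = runif(n, -175, 175),
                      omega = 180 + rnorm(n, 0, 5))
    ch <- build_backbone(tor)
    orc <- oracle_build_backbone(tor)
    for (i in seq_len(n)) {
      expect_lt(max(abs(atom_xyz(ch, i, "N") - orc$N[i, ])), 1e-6)
      expect_lt(max(abs(atom_xyz(ch, i, "CA") - orc$CA[i, ])), 1e-6)
      expect_lt(max(abs(atom_xyz(ch, i, "C") - orc$C[i, ])), 1e-6)
    }
  }
})

test_that("random torsion lists round-trip through build + measure", {
  set.seed(29)
  worst <- 0
  for (k in 1:100) {
    n <- sample(4:20, 1)
    # keep torsions away from the collinearity singularities at 0/180
    tor <- data.frame(phi = runif(n, -170, 170), psi = runif(n, -170, 170))
    pp <- phi_psi(build_backbone(tor), ca_break = Inf)
    worst <- max(worst,
                 max(ang_diff(pp$phi[2:n], tor$phi[2:n])),
                 max(ang_diff(pp$psi[1:(n - 1)], tor$psi[1:(n - 1)])))
  }
  expect_lt(worst, 1e-6)
})

test_that("phi_psi honours the boundary and chain-break contracts", {
  ch2 <- build_backbone(data.frame(phi = c(-60, -60), psi = c(-40, -40)))
  pp2 <- phi_psi(ch2)
  expect_true(is.na(pp2$phi[1]) && !is.na(pp2$psi[1]))
  expect_true(!is.na(pp2$phi[2]) && is.na(pp2$psi[2]))

  # displacing the second half of a chain breaks dihedrals across the gap
  ch <- build_backbone(data.frame(phi = rep(-57, 8), psi = rep(-47, 8)))
  shift <- ch$atoms$resno > 4
  ch$atoms$x[shift] <- ch$atoms$x[shift] + 50
  ch <- backbone_chain(ch$atoms)
  pp <- phi_psi(ch)
  expect_true(is.na(pp$phi[5]) && is.na(pp$psi[4]))
  expect_false(is.na(pp$phi[3]) || is.na(pp$phi[7]))

  # missing backbone atoms flag the residue and void its dihedrals
  ca_only <- ch$atoms[ch$atoms$elety == "CA", ]
  flat <- backbone_chain(ca_only)
  expect_true(all(!flat$residues$complete))
  ppf <- phi_psi(flat)
  expect_true(all(is.na(ppf$phi)) && all(is.na(ppf$psi)))
})

test_that("build_backbone rejects non-physical inputs", {
  expect_error(build_backbone(data.frame(phi = 0, psi = 0)), "at least 2")
  g <- peptide_geometry(); g$a_n_ca_c <- 180
  expect_error(build_backbone(data.frame(phi = c(0, 0), psi = c(0, 0)),
                              geometry = g), "strictly inside")
  g2 <- peptide_geometry(); g2$b_c_n <- -1
  expect_error(build_backbone(data.frame(phi = c(0, 0), psi = c(0, 0)),
                              geometry = g2), "bond length")
})
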