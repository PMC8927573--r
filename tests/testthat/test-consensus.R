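test_that("column frequencies exclude gaps and X from the denominator", {
  col <- column_frequencies(single_column_alignment(c("E", "E")), 1)
  expect_equal(unname(col$f["E"]), 1)
  expect_equal(sum(col$f), 1)

  col2 <- column_frequencies(single_column_alignment(c("E", "D", "-", "E")), 1)
  expect_equal(unname(col2$f["E"]), 2 / 3)
  expect_equal(unname(col2$f["D"]), 1 / 3)
  expect_equal(col2$n_non_gap, 3)

  colx <- column_frequencies(single_column_alignment(c("E", "X", "E")), 1)
  expect_equal(colx$n_non_gap, 2)

  gap <- column_frequencies(single_column_alignment(c("-", "-")), 1)
  expect_equal(gap$n_non_gap, 0)
  expect_true(all(is.na(gap$f)))
})

test_that("the f >= f_mean + SD rule reproduces the forced edge cases", {
  # single residue type: threshold = 0.05 + sqrt((0.95^2 + 19*0.05^2)/20)
  cc <- call_consensus(column_frequencies(
    single_column_alignment(rep("W", 7)), 1))
  expect_equal(cc$f_mean, 0.05)
  expect_equal(cc$sd, sqrt((0.95^2 + 19 * 0.05^2) / 20), tolerance = 1e-12)
  expect_equal(cc$threshold, 0.2679, tolerance = 1e-3)
  expect_equal(cc$consensus, "W")

  # perfectly uniform column: SD = 0, inclusive >= admits all 20
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  cu <- call_consensus(column_frequencies(single_column_alignment(aa), 1))
  expect_equal(cu$sd, 0)
  expect_equal(sort(cu$consensus), aa)

  # all-gap column: no call
  expect_equal(call_consensus(column_frequencies(
    single_column_alignment(c("-", "-")), 1))$consensus, character(0))
})

test_that("frequencies and consensus agree with brute-force oracles on random columns", {
  set.seed(43)
  for (k in 1:1000) {
    letters1 <- random_column()
    aln <- single_column_alignment(letters1)
    col <- column_frequencies(aln, 1)
    orc <- oracle_colfreq(letters1)
    expect_identical(unname(col$counts), unname(orc$counts))
    expect_equal(col$n_non_gap, orc$n_non_gap)
    if (col$n_non_gap > 0) {
      expect_equal(sum(col$f), 1, tolerance = 1e-12)
      expect_equal(call_consensus(col)$consensus, oracle_consensus(col$f))
    }
  }
})

test_that("consensus ordering is by descending frequency, ties alphabetical", {
  cc <- call_consensus(column_frequencies(
    single_column_alignment(c("K", "K", "R", "R", "E", "E", "E")), 1))
  expect_equal(cc$consensus, c("E", "K", "R"))
})

test_that("consensus_string renders bare, bracketed and undefined positions", {
  ident <- align_loops(stats::setNames(rep("KENKC", 6), paste0("r", 1:6)))
  expect_equal(consensus_string(ident), "K E N K C")

  stub <- align_loops(synthetic_human_sil_stub())
  expect_equal(consensus_string(stub), "[R/K] E [N/S] [R/K/Q] C")

  # a single short loop leaves core positions 4-5 as all-gap columns
  short <- align_loops(c(a = "RES"))
  expect_equal(consensus_string(short), "R E S · ·")
})

test_that("adding a copy of a row never evicts its unique-max residues", {
  set.seed(47)
  for (k in 1:50) {
    letters1 <- random_column(nrow = sample(6:25, 1), gap_frac = 0)
    col <- column_frequencies(single_column_alignment(letters1), 1)
    top <- names(col$f)[col$f == max(col$f)]
    if (length(top) != 1) next
    base <- call_consensus(col)$consensus
    grown <- call_consensus(column_frequencies(
      single_column_alignment(c(letters1, top)), 1))$consensus
    if (top %in% base) expect_true(top %in% grown)
  }
})
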