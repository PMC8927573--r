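make_record <- function(seqs, tms, id = "rec1") {
  sequence_record(id, seqs, tms)
}

test_that("extract_sil slices strictly between TMS2 and TMS3", {
  # 1-letter-per-position toy: loop is the residues after TMS2, before TMS3
  r <- make_record("ACDEFGHIKL",
                   rbind(c(1, 1), c(2, 3), c(8, 9), c(10, 10)))
  expect_equal(extract_sil(r), "EFGH"[1])
  expect_equal(extract_sil(r), substr("ACDEFGHIKL", 4, 7))
})

test_that("a Tspan17-like topology brackets the RENTF core inside the loop", {
  # topology places residues 87-91 = RENTF inside the TMS2-TMS3 linker
  seqs <- paste0(strrep("A", 20), strrep("L", 21),   # nterm + TMS1 (21-41)
                 strrep("G", 8), strrep("L", 21),    # SEL + TMS2 (50-70)
                 "GSTGSTGSTGSTGSTG",                 # SIL 71-86
                 "RENTF",                            # 87-91
                 "GST", strrep("L", 21),             # TMS3 (95-115)
                 strrep("G", 6), strrep("L", 21))    # TMS4 (122-142)
  r <- make_record(seqs, rbind(c(21, 41), c(50, 70), c(95, 115), c(122, 142)),
                   id = "Tspan17syn")
  sil <- extract_sil(r)
  expect_true(grepl("RENTF", sil))
  expect_equal(substr(r$sequence, 87, 91), "RENTF")
  expect_equal(nchar(sil), 94 - 71 + 1)
})

test_that("degenerate and invalid topologies are handled", {
  r <- make_record("ACDEFGHIKL", rbind(c(1, 1), c(2, 3), c(4, 5), c(9, 10)))
  expect_warning(sil <- extract_sil(r), "empty SIL")
  expect_equal(sil, "")
  expect_error(make_record("ACDEFGHIKL",
                           rbind(c(1, 3), c(2, 5), c(6, 7), c(9, 10))),
               "disjoint")
  expect_error(make_record("ACDEFGHIKL",
                           rbind(c(1, 2), c(3, 4), c(5, 6), c(9, 12))),
               "outside")
  expect_error(make_record("ACDBFGHIKL",
                           rbind(c(1, 2), c(3, 4), c(5, 6), c(9, 10))),
               "non-canonical")
})

test_that("extract_nterm appends the first five TMS1 residues", {
  r <- make_record("MGKACLLLLLWYFNQRSTVY",
                   rbind(c(6, 12), c(14, 15), c(17, 18), c(19, 20)))
  expect_equal(extract_nterm(r), "MGKACLLLLL")   # 1..5 plus 5 TMS1 residues
})

test_that("FASTA + topology round trip preserves sequences and catches errors", {
  fam <- make_sil_family(family_spec(n = 5, seed = 3))
  fa <- tempfile(fileext = ".fasta"); tp <- tempfile(fileext = ".tsv")
  make_sil_family(family_spec(n = 5, seed = 3), fasta = fa, topology = tp)
  back <- read_sil_records(fa, tp)
  expect_equal(names(back), names(fam))
  expect_equal(vapply(back, function(r) r$sequence, ""),
               vapply(fam, function(r) r$sequence, ""))
  expect_equal(vapply(back, extract_sil, ""), vapply(fam, extract_sil, ""))

  # duplicate id is a hard error naming the id
  writeLines(c(">dup", "ACDE", ">dup", "ACDF"), fa2 <- tempfile())
  expect_error(read_sil_records(fa2, tp), "dup")
  # record absent from the topology table is rejected
  writeLines(c(">syn01", "ACDE", ">orphan", "ACDF"), fa3 <- tempfile())
  expect_error(read_sil_records(fa3, tp), "orphan")
  # empty FASTA is an error
  writeLines(character(0), fa4 <- tempfile())
  expect_error(read_sil_records(fa4, tp), "empty")
})

test_that("lowercase input is uppercased with a message", {
  expect_message(r <- make_record("acdefghikl",
                                  rbind(c(1, 2), c(3, 4), c(6, 7), c(9, 10))),
                 "uppercased")
  expect_equal(r$sequence, "ACDEFGHIKL")
})
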