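#!/usr/bin/env Rscript
# Anchor-align the SIL families from step 01, export the gapped
# alignment, the per-position residue-frequency matrix and the
# consensus calls under the f >= f_mean + SD rule.

suppressMessages(library(silmotif))
dir.create("results", showWarnings = FALSE)

recs <- read_sil_records("results/sil_family.fasta",
                         "results/sil_family_topology.tsv")
aln <- align_loops(recs)
write_alignment(aln, "results/sil_family_alignment.fasta")

fm <- frequency_matrix(aln)
utils::write.table(round(fm, 4), "results/sil_family_frequencies.tsv",
                   sep = "\t", quote = FALSE, col.names = NA)
cat("sampled family consensus:", consensus_string(aln), "\n")

stub <- readLines("results/human_stub_loops.fasta")
loops <- stats::setNames(stub[c(FALSE, TRUE)],
                         sub("^>", "", stub[c(TRUE, FALSE)]))
aln2 <- align_loops(loops)
tal <- anchor_tallies(loops)
cat(sprintf("stand-in anchors: %d E, %d D, %d without E/D; position 1: %d R + %d K\n",
            tal$E_anchors, tal$D_anchors, tal$no_acidic, tal$pos1_R,
            tal$pos1_K))
cat("stand-in consensus:", consensus_string(aln2), "\n")

calls <- core_consensus(aln2)
jsonlite::write_json(
  lapply(calls, function(cl) list(threshold = cl$threshold,
                                  consensus = cl$consensus)),
  "results/human_stub_consensus.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
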