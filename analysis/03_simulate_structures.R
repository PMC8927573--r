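#!/usr/bin/env Rscript
# Build the synthetic structures: a helix-turn-helix backbone with the
# planted M-turn, the CD9-like and CD53-like stand-ins (salt-bridge
# geometry planted at the published distances), and salt-bridge toys
# spanning the 4 Angstrom cutoff. All are written as PDB for the later
# steps and for external inspection.

suppressMessages(library(silmotif))
dir.create("results", showWarnings = FALSE)

hp <- make_m_hairpin(n1 = 12, n2 = 12)
write_structure(hp$chain, "results/synthetic_hairpin.pdb")
cat(sprintf("hairpin: %d residues, planted turn at %d-%d\n",
            length(hp$chain), min(hp$window), max(hp$window)))

for (p in c("CD9", "CD53")) {
  st <- make_tetraspanin_stub(p)
  write_structure(st$chain, sprintf("results/%s_stub_synthetic.pdb",
                                    tolower(p)))
  cat(sprintf("%s-like stand-in: SIL %d-%d, planted %s\n", p,
              min(st$sil_resno), max(st$sil_resno),
              paste(names(st$planted), st$planted, sep = "=",
                    collapse = ", ")))
}

for (d in c(2.8, 4.0, 4.5))
  make_salt_bridge_toy(d, sprintf("results/salt_bridge_toy_%.1fA.pdb", d))
cat("salt-bridge toys written at 2.8, 4.0 and 4.5 Angstrom\n")
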