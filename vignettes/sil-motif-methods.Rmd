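---
title: "Methods: anchored SIL consensus and M-motif detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored SIL consensus and M-motif detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silmotif)
```

## Scope and model

`silmotif` analyses the small intracellular loop (SIL) of tetraspanin-like
membrane proteins on two levels. On the sequence level it treats the SIL as
the linker strictly between the annotated end of TMS2 and start of TMS3 —
transmembrane boundaries are *inputs* (a TSV sidecar), never predicted —
and asks which residues are conserved once the loops are anchored on their
charged core. On the structure level it treats the SIL as a candidate
five-residue inter-helix turn and asks whether the backbone dihedrals show
the M-motif signature: right-handed α conformation at positions 1, 4, 5,
left-handed α at position 2, and β-strand at position 3, flanked by the
helical arms that continue into the TMS helices.

## Anchored alignment

Short loops of 6–21 residues cannot be aligned meaningfully by generic
multiple-alignment heuristics, so the package uses the family's own
anchoring convention, encoded as an ordered rule
(`sil_anchor_rule()`): scan N→C for the first acidic residue (E or D, no
preference between them — the rule is "most N-terminal acidic") and map it
to core position 2; if the loop has no acidic residue, the first basic
residue (K or R) maps to core position 1; loops matching neither class are
excluded with a message unless a *manual offset* supplies the index to use
as core position 1 (the by-similarity fallback a curator would apply to the
single family member lacking all anchor classes). Rows are left-padded with
gaps so anchors share columns, and right-padded so the five core columns
always exist; a loop that ends early simply leaves core positions 4/5 as
gaps. Core position 1 is defined as the column immediately before an acidic
anchor even when the anchor is the loop's first residue (the position-1
cell is then a gap).

## Consensus rule

Per column, the frequency *f* of each of the 20 canonical residues is the
count divided by the number of non-gap, non-X letters; gaps and X are
excluded from numerator and denominator, so defined columns sum to 1. A
residue is consensus when *f ≥ f̄ + SD*, inclusively. Both f̄ and SD are
computed over **all 20** residue frequencies, zeros included, with the
population SD (divide by 20). This reference set is a design choice (the
rule itself does not fix it): with all 20 included, a single-residue column
yields a threshold of `0.05 + sqrt((0.95^2 + 19*0.05^2)/20) ≈ 0.268` and
exactly one consensus letter, and realistic mixed columns yield two to
three letters — matching how family core consensus strings are written.
`call_consensus(denominator = "observed")` restricts the reference set to
residues actually seen, for sensitivity analysis. Consensus sets are
ordered by decreasing frequency with alphabetical tie-breaks, and rendered
as `[R/K] E [N/S] [R/K/Q] C`-style strings (`·` marks an uncallable,
all-gap column). A perfectly uniform column has SD = 0 and, because the
threshold is inclusive, all 20 residues qualify — the documented edge case
of the rule.

## Dihedrals, Ramachandran classes, M-motif

φ(i) is the C(i−1)–N(i)–CA(i)–C(i) torsion, ψ(i) the
N(i)–CA(i)–C(i)–N(i+1) torsion, both in the IUPAC sign convention in
(−180°, 180°]. Dihedrals are undefined (NA) at chain termini, for residues
with missing backbone atoms, and across chain breaks, operationalised as a
consecutive Cα–Cα distance above 4.5 Å — safely above the ≈3.8 Å of a
trans peptide and below any genuine gap. Undefined residues interrupt
helix runs and motif windows.

Ramachandran classes are rectangles in (φ, ψ) space with half-open edges
(lower bound in, upper bound out, except the +180° seam which is closed):

| class   | φ            | ψ                         |
|---------|--------------|---------------------------|
| ALPHA_R | [−160, −20)  | [−120, 50)                |
| BETA    | [−180, −20)  | [50, 180] ∪ [−180, −150)  |
| ALPHA_L | [20, 160)    | [−60, 90)                 |

Everything else is OTHER; the rectangles are disjoint so classification is
total and unique. The boundaries are configurable
(`default_rama_regions()`); the defaults are generous textbook regions
chosen so that the canonical examples (−57, −47) → αR, (60, 45) → αL,
(−120, 130) → β classify correctly with wide margins.

A helix (`assign_helices()`) is a maximal run of ≥ `min_run = 4`
consecutive well-defined ALPHA_R residues. An M-motif
(`find_m_motifs()`) is a five-residue window classified exactly
(ALPHA_R, ALPHA_L, BETA, ALPHA_R, ALPHA_R) with at least `flank_min = 3`
consecutive ALPHA_R residues immediately on both sides — an approximation
of "helical arms continuing into the TMSs" that does not demand full
TMS-length helices. An optional antiparallel filter (on by default)
requires the flanking helix axes to diverge by ≥ `axis_min_angle = 120°`;
axes are estimated from the flank Cα trace as the mean of one-turn offset
vectors (Cα(k+3) − Cα(k)), which cancels the radial component, falling
back to the end-to-end vector for runs of 2–3 residues and to NA (filter
inapplicable) for single-residue flanks.

Each hit reports the co-planarity of the turn as the RMS orthogonal
distance of the 15 backbone atoms (N, CA, C of the five residues) from
their least-squares plane (smallest-singular-vector fit through the
centroid). Planarity is *reported, not filtered*: no published threshold
exists. On the package's ideal-geometry turns the value is ≈0.51 Å, so a
`max_planarity` of ~0.7–1.0 Å would be a reasonable starting point for
users who want a filter; the config default leaves it off.

## Contacts

`contact_scan()` reports, per candidate residue pair, the minimum
heavy-atom distance over configured atom sets. Salt-bridge mode uses
Lys NZ and Arg NE/NH1/NH2 against Glu OE1/OE2 and Asp OD1/OD2 with an
*inclusive* 4.0 Å cutoff; histidine is excluded from the basic set by
default (its protonation is ambiguous at physiological pH) and hydrogens
are ignored. Which atoms define a published distance is rarely stated, so
the minimum-over-sets convention is used throughout; it is the least
arbitrary and reproduces printed distances whenever those were measured
between the closest charged atoms. Polar mode screens side-chain O/N
(Asn OD1/ND2, Gln OE1/NE2, Ser OG, Thr OG1, Tyr OH, His ND1/NE2, Trp NE1,
plus the charged sets) against backbone N/O at 3.5 Å. Pairs may be given
explicitly as `"K11:E84"` (one-letter code + author residue number);
author numbering with insertion codes is preserved everywhere so reports
match the literature's residue labels. Residues missing their screened
atoms are skipped with a warning, never silently.

`wheel_separation()` is a deliberately minimal ideal-helical-wheel
stand-in: (|j − i| × 100°) mod 360, replacing interactive helical-wheel
servers for the orientation argument about the juxtamembrane lysine. It
assumes ideal 3.6-residues/turn periodicity and knows nothing about real
side-chain conformations.

## Synthetic generators: what they emulate, and what they do not

`build_backbone()` places N, CA, C, O sequentially from internal
coordinates (natural-extension-reference-frame construction) with standard
peptide geometry: bonds N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, C–O
1.231 Å; angles N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°, CA–C–O
120.8°; ω = 180° unless overridden. Any self-consistent constant set
would serve equally, because all uses are round trips against the
package's own dihedral measurement; these values are the standard
textbook ones. The carbonyl O is placed anti to the next amide N
(torsion ψ + 180°).

`make_m_hairpin()` joins two ideal helical arms (φ = −57°, ψ = −47°) by a
turn whose default per-position dihedrals — (−57, −47), (60, 45),
(−120, 130), (−57, −47), (−57, −47) — sit deep inside the default
Ramachandran rectangles, so the planted window classifies as the M
signature regardless of moderate region re-configuration. Optional
Gaussian dihedral jitter (default σ = 0°) supports detector-robustness
experiments.

`make_sil_family()` emulates a 20–40 member family of short loops: each
member embeds a five-position core sampled from per-position frequency
tables into background flanks, inside a full synthetic topology
(N-term | TMS1 | linker | TMS2 | SIL | TMS3 | linker | TMS4 | C-term)
with poly-L TMSs of 18 residues and total loop lengths drawn from 6–21 —
the span observed across the human family. The default core tables are
calibrated to the human composition (position 1: 13 R + 11 K of 33;
position 2: 23 E + 2 D, 8 with neither; position 3 N/S-rich; position 4
R/K/Q; position 5 C-rich). The background distribution excludes E, D, K
and R so flanks can never steal the anchor from the planted core — real
flanks do occasionally contain charged residues, which is exactly the
ambiguity the generator deliberately avoids; passing tests therefore
certify the alignment/consensus machinery, not robustness to
anchor-stealing flanks.

Two deterministic stand-ins are *labelled synthetic* and must not be
mistaken for crystal-structure data: `make_tetraspanin_stub()` builds
CD9-like and CD53-like backbones whose turn sequences (QESQC at 83–87;
KENKS at 76–80, the crystallised C→S exchange) and Lys–Glu carboxylate
distances (2.8 Å; 5.1 and 5.2 Å) are planted by construction at the
published values, with simplified straight-chain side-chain geometry; and
`synthetic_human_sil_stub()` is a 33-loop set whose anchor composition
(23 E, 2 D, 8 without acid, 13 R + 11 K at position 1) matches the human
family's printed tallies while the sequences themselves are invented.
Tests and the acceptance script run the measurement machinery on these
stand-ins; agreement shows the pipeline measures what was planted, not
that the real structures were re-derived. With real PDB/mmCIF files the
same calls (`read_structure()` → `find_m_motifs()` / `contact_scan()`)
apply unchanged.

## Numerical choices and degenerate inputs

* Torsions are mapped to (−180°, 180°]; −180° is normalised to +180°.
* Collinear triples make a torsion undefined and raise an error at the
  primitive level; `phi_psi()` never feeds them (peptide geometry forbids
  them) and instead returns NA by the termini/break rules.
* `plane_fit_rms()` requires ≥3 non-collinear points; collinear input is
  an error, not 0.
* Altlocs: highest occupancy wins, ties alphabetically; multi-model files
  contribute model 1 only; hydrogens and HETATM records are dropped.
* Consensus threshold comparison uses a 1e−12 float tolerance on the
  inclusive ≥ so algebraic ties (e.g. the uniform column) are stable.
* Reports round distances/angles to 0.1 Å / 0.1° (TSV) for diffability;
  JSON keeps full precision.

## Problem sizes

The test suite and acceptance script use 100 random torsion lists
(4–25 residues), 200 planted hairpins plus 200 pure helices for detector
recall/precision, 1000 random columns against brute-force consensus
oracles, 1000 random point sets against a numeric plane-fit minimiser,
and families of n = 33 (with n = 330 for the consensus-convergence
check). These sizes give stable statistics for every property while the
whole suite stays fast on a single CPU.

## Known limitations

* TMS boundaries are trusted as given; disagreements between topology
  sources shift the extracted SIL and hence anchors and tallies.
* The interface is the package's functions plus the numbered scripts in
  `analysis/`; there is no shell subcommand wrapper.
* No membrane embedding, rotamer analysis or secondary-structure
  prediction; "orientation towards TMS1/TMS4" is reduced to reported
  contact distances and ideal-wheel separations.
* The M-motif definition is purely dihedral + flank based; turns with
  distorted arms (breaks, kinks within `flank_min` residues) are missed
  by design.
* Synthetic side chains in the stand-ins are geometric stubs; only their
  planted inter-group distances are meaningful.
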