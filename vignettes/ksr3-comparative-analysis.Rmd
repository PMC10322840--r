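---
title: "Comparative analysis of KSR3 pseudokinases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of KSR3 pseudokinases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksrtools)
```

## The scientific problem

KSR (Kinase Suppressor of Ras) proteins are catalytically impaired members
of the RAF kinase family that act as scaffolds and allosteric activators of
RAF. The KSR3 branch of this family is defined by a distinctive
architecture: a C1/CRD zinc-finger domain and a kinase domain, but no
CC-SAM domain (the KSR1/2 hallmark) and no RAS-binding domain (the RAF
hallmark); within the kinase domain the ATP-binding P-loop is degenerate
(Glu-X-Gly-X-X-Gly instead of Gly-X-Gly-X-X-Gly), the VAIK lysine motif is
replaced by variants such as VLIQ, and the HRD catalytic loop and DFG motif
are absent outright. Despite — indeed because of — this catalytic
decay, KSR3 proteins are constitutive, RAS-independent activators of RAF:
their family-specific residues in the β3 strand, αC helix, dimerization
interface (DIF) and activation segment (AS) mirror the positions where
activating mutations of human B-RAF arise.

`ksrtools` turns that comparative argument into a reusable pipeline with
four stages:

1. **Motif fingerprinting** (`annotate_kinase()`): locate the kinase domain
   and grade each short motif as canonical / degenerate / absent; detect
   accessory domains (CRD, RBD, CC-SAM), the NtA acidic motif, both 14-3-3
   sites, and ERK-feedback phosphosites.
2. **Family classification** (`classify_family()`), corroborated by a
   neighbor-joining tree with bootstrap supports (`bootstrap_tree()`).
3. **Divergence profiling** (`divergence_profile()`, `region_summary()`):
   per-position fraction of a pseudokinase set differing from a reference
   kinase, summarized over named structural regions.
4. **Mutation transposition** (`donor_specific_residues()`,
   `transpose_mutations()`): residues shared by the KSR3 donors but absent
   from the acceptor become candidate activating substitutions, deletions
   and segment swaps of the acceptor, in standard L485R-style notation with
   an embedded known-oncogenic lookup.

## Synthetic references instead of downloaded sequences

The package deliberately ships no third-party sequence data and performs no
network access. All reference objects are **synthetic stand-ins**
constructed in code (`braf_reference()`, `ksr3_reference()`,
`ksr1_reference()`):

* The B-RAF-like stand-in is 766 residues long and its kinase-domain
  segment (positions 446–723) reproduces the canonical human B-RAF
  numbering of every landmark the analysis uses: NtA SSDD 446–449, P-loop
  G464…G469 with F468, VAVK ending at K483, L485, V487, QLQA 494–497,
  F498, K499, L505, RKTR 506–509, catalytic D576, D587/L588, DFG 594–596,
  L597, T599, V600. Flanking regions are synthetic filler carrying an RBD
  exemplar, a C1/CRD cysteine pattern, two ERK-feedback sites and a
  C-terminal 14-3-3 site at realistic locations.
* The KSR3-like stand-ins are derived from that kinase segment by an
  explicit edit script (the degenerate P-loop, VLIQ, loss of HRD and DFG,
  DIND in place of QLQA, SKIR in place of RKTR, K/V at the D587/L588
  equivalents, an acidic activation segment, a 3-residue-shorter β3–αC
  region). Three homolog types differ only in linker lengths, chosen so
  that each carries its published landmark coordinates: the sea-urchin
  type (NtA S306/E307, dimer arginine R364, C-terminal serine 586), the
  hemichordate type (D293/E294, R350, S572) and the cnidarian type (R390,
  S618).
* The KSR1/2-like stand-in adds a CC-SAM exemplar, a proline-rich region
  with two P-x-T-P feedback sites, and an HKD catalytic loop; its
  dimerization arginine falls at 608.

Because the KSR templates are *edits of* the B-RAF kinase segment, the
residue-level homology between them is known by construction. This gives
every alignment, liftover, divergence and transposition test an exact
ground truth: for example, a global Gotoh alignment of the sea-urchin-type
KSR3 against the B-RAF stand-in must map 343→485, 354→499, 361→506 and
364→509, which is precisely the correspondence the transposition analysis
relies on.

One template choice deserves explanation: the RAF-family template carries
16 additional RAF-diagnostic substitutions in the kinase C-lobe tail
(positions 625–723, outside every named region and landmark). In a design
where KSR1 and KSR3 are edits of the RAF template, RAF itself is the
ancestral state and has no shared derived characters, so no tree method
could recover it as a clade; the C-lobe substitutions give each of the
three families its own diagnostic character set without altering any
landmark coordinate or region-level divergence statistic.

## The synthetic-data generator

`make_archetype()` realizes a family template under a simple noise model:
independent per-site substitution to a uniformly chosen different residue,
applied **only outside the embedded motif positions** — an embedded state
(canonical, degenerate, or absent) is part of the ground truth, so the
positions that define it (including the windows where HRD and DFG must
remain absent) are never mutated. Indels are restricted to inter-domain
linkers, so the kinase-core alignment that the tree and divergence
benchmarks use is indel-free by construction. Defaults are `noise = 0`
for single archetypes and `noise = 0.02` (2% per site) for family sets,
with label-recovery benchmarks also run at 5%; these are the working
points of all packaged analyses.

`make_family_set()` returns, besides the sequences and the truth table, a
**ground-truth kinase-core alignment**: 279 columns covering B-RAF 446–723
plus one insertion column, with each template's known gaps. The package
does not construct multiple alignments (that is an external-tool task);
precomputed alignments are ingested with `read_msa()` (aligned FASTA or
Clustal), and the generator's exact alignment serves for benchmarking.

What the generator does *not* emulate: phylogenetically realistic
substitution processes (no rate heterogeneity, no exchangeability matrix),
domain-level rearrangements, alternative isoforms, or alignment error.
Passing tests therefore demonstrate the correctness of the pipeline's
logic and coordinate bookkeeping, not robustness to real-data alignment
noise — on real sequences the quality of the input MSA is the binding
constraint.

## Alignment and coordinate liftover

`pairwise_align()` implements the affine-gap Gotoh three-state recurrence
in C++ with BLOSUM62 defaults (gap open 11, gap extend 1; a gap of length
L costs `open + extend × L`, the same convention as
`Biostrings::pairwiseAlignment`, which the test suite uses as an
independent cross-check alongside an exhaustive-enumeration oracle).
Traceback tie-breaking is fixed (diagonal, then gap-in-b, then gap-in-a)
so outputs are byte-reproducible. Positions are 1-based everywhere
user-facing; `map_position()` returns the residue of the partner sequence
sharing the column, or `NA` where the column is gapped — the "no
homologous residue" case that turns into deletion candidates during
transposition.

## Motif grading and windows

Motif scans are window-constrained: the kinase domain is anchored by local
alignment against a packaged kinase-domain exemplar (corroborated by exact
catalytic-motif matches in priority order HRD > DFG > VAIK > P-loop), each
motif's expected position is lifted through that anchor, and the scan
searches expected ± 10 residues (`window_pad`, configurable). Grading is
three-valued: an exact class-pattern match is canonical; otherwise the
best positional match retaining **at least half of the pattern's anchor
residues** is degenerate (this threshold is this package's
operationalization of the distinction between a "highly divergent" motif
such as VLIQ — 2 of 4 anchors — and a simply absent one such as the KSR3
HRD, where no window position retains 2 of 3); otherwise absent. Ties go
to the leftmost window position. When no anchoring evidence exists at all
(e.g. a random sequence), the whole sequence is returned as a
low-confidence domain and only exact motif matches are reported —
degenerate grading without a coordinate prediction would be noise.

Two numbering caveats are built in rather than papered over. The
N-terminal inhibitory 14-3-3 serine pair is located by pattern
(S-x-x-S in the CRD–kinase linker), not by liftover, because the
literature numbers the equivalent site (S259) in C-RAF coordinates that do
not transfer between homologs. And `landmark_table()` places the αC QLQA
motif at 494–497 with F498: the mutagenesis-primer-derived local sequence
(…T491 P492 Q493 Q494 L495 Q496 A497 F498 K499…) is the only numbering
consistent with the K499/R506/R509 anchors, although parts of the
literature write "F497". `validate_landmarks()` exists precisely to catch
this class of drift: it checks every landmark's residue letter and, when a
sequence fails, probes whether one constant offset repairs it.

## Classification rules

`classify_family()` is a pure function of the fingerprint, in rule order:
RBD ⇒ RAF; else CC-SAM ⇒ KSR1/2; else CRD ∧ ¬DFG ∧ ¬HRD ⇒ KSR3; else
UNKNOWN. A fingerprint with both RBD and CC-SAM is contradictory and
returns UNKNOWN at low confidence rather than a guess. Accessory domains
are detected by local alignment against packaged exemplars with a score
threshold of 100 — calibrated to sit far above the empirical maximum of
100 shuffled-exemplar null scores (≈ 30–40) and far below exemplar
self-scores (≈ 350), so presence calls tolerate several percent
substitution noise.

## Trees and supports

`distance_matrix()` computes p-distances (fraction of differing
residue–residue columns; optional Poisson correction −ln(1−p));
`nj_tree()` wraps `ape::nj` with negative branch lengths clamped to zero;
`bootstrap_tree()` resamples columns with replacement, rebuilds the NJ
tree per replicate and places majority-rule supports on the full-data
tree. The consensus threshold is 50% majority rule. The packaged
benchmarks use 200 replicates (the API default is 1000); with 10
sequences per family at 2% noise all three family clades reach support
100, so 200 replicates already decide the question and the default is
available for real data. NJ here is the packaged approximation for tree
corroboration of the classifier — full maximum-likelihood inference is an
external-tool task and out of scope; accordingly the test surface is
family monophyly on generated data, not any particular published topology.

## Divergence statistic

`divergence_profile()` reports, for every alignment column where the
reference has a residue, the fraction of the comparison set differing from
the reference. A gap in a set sequence counts as divergent by default
(`gap_divergent = FALSE` switches to a residues-only denominator);
columns where the reference itself is gapped are skipped, i.e. insertions
relative to the reference do not enter the profile. On the synthetic
benchmark (19 KSR3-like sequences at 2% noise against the RAF reference)
the region ranking is P-loop (mean 0.67) > activation segment > αC helix,
with the catalytic-loop and β7–β8 regions far lower — the concentration
pattern the comparative argument predicts.

Region definitions are anchored to motif evidence: PLOOP is the P-loop
match; BETA3 the VAIK match ±3; ALPHAC a window around the dimerization
motif (start −12 to end +5); DIF the dimer arginine ±5; CATLOOP the HRD
window ±4; AS runs from the DFG position (observed or anchor-predicted)
to DFG+30. BETA7_BETA8 is the segment **between** the catalytic-loop
window and the activation segment: in the kinase fold β7–β8 lie
C-terminal of the catalytic loop, and the K443↔D587 / V444↔L588
correspondences require exactly that placement.

## Transposition

`donor_specific_residues()` flags columns where ≥ 80% of donors
(configurable) share a residue that differs from the acceptor;
`transpose_mutations()` turns them into candidates within the regions of
interest (β3, β3–αC loop, αC, DIF, β7–β8, AS by default — the regions
where such swaps are mechanistically interpretable): substitutions,
single-residue deletions where the acceptor aligns to a donor-consensus
gap (the ΔV487 class), and segment swaps for contiguous runs of ≥ 3
donor-specific residues (the QLQA→DIND class; the run's individual
substitutions are folded into the swap rather than double-reported). The
known-oncogenic flag comes from an embedded, variant-aware static list of
cancer-reported B-RAF positions (464, 468, 469, 485, 499, 506, 588, 594,
597, 600) — L485F is flagged, L485R and R506E are explicitly not (never
described, each requiring two base substitutions) — and is `NA` for any
acceptor other than the packaged B-RAF reference. No external database is
ever queried.

## Numerical and degenerate-input choices

* Alignment traceback ties: diagonal > gap-in-b > gap-in-a; leftmost
  maximum for local alignments; leftmost window position for motif ties.
* `percent_identity()` errors (rather than returning 0/0) when an
  alignment has no residue–residue column, and `distance_matrix()` errors
  naming the pair that shares no residue columns; the Poisson correction
  refuses p = 1.
* Empty FASTA files read as empty collections; an empty comparison or
  donor set is an error, not an empty result, because a silent empty
  profile would be indistinguishable from a genuinely non-divergent one.
* Negative NJ branch lengths are clamped to 0 after topology estimation.
* All randomness flows through explicit integer seeds; child streams are
  derived with a fixed multiplicative scheme so that one seed reproduces
  an entire analysis.

## Problem sizes used in packaged analyses

The packaged benchmarks run at sizes chosen to exercise every code path
with comfortable statistical margins: label recovery on 90 sequences at
zero noise and 300 at 5% noise; bootstrap supports on 30 sequences × 279
columns × 200 replicates; the alignment enumeration check on all 57,970
unordered pairs of length ≤ 4 over a 4-letter alphabet in the test suite
(3,570 pairs of length ≤ 3 in the acceptance script); exhaustive topology
scoring up to 6 taxa (105 topologies). The divergence demonstration uses
a set of 19 KSR3-like sequences, a realistic cross-phylum homolog-set
size for this family.

## Known limitations

* The synthetic templates share far higher kinase-domain identity (~85%)
  than real cross-phylum homologs (~30–40%); real-data use depends on a
  good external MSA and may need wider motif windows
  (`window_pad`) and a lower `min_anchor_score`.
* The classifier is architecture-based; a KSR3 gene with a secondarily
  degraded CRD, or a truncated transcript missing the N-terminus, will
  return UNKNOWN rather than KSR3 (by design — UNKNOWN is preferred over
  guessing).
* The divergence statistic treats columns independently; it makes no
  attempt to model covariation or alignment uncertainty.
* `known_oncogenic_lookup()` reflects a fixed embedded list, not a live
  database; it answers "was this position/variant in the packaged
  catalogue", nothing more.
* Functional effect sizes (fold-activation of ERK signalling by a given
  mutant) are experimental quantities and are not modelled anywhere in
  this package.
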