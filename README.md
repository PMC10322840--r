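# ksrtools

Comparative sequence analysis of RAF kinases and the KSR (Kinase Suppressor
of Ras) scaffold family, centred on the KSR3 branch of catalytically
inactive, constitutively RAF-activating pseudokinases.

## The problem and who this is for

RAF-family activity is gated by a set of short, highly conserved kinase
motifs — the glycine-rich P-loop (G-x-G-x-x-G), the VAIK lysine, the HRD
catalytic loop, the DFG motif at the start of the activation segment — plus
accessory domains that define the family branches: the RAS-binding domain
(RBD, RAF only), the CC-SAM domain (KSR1/2 only), and the C1/CRD
zinc-finger shared across the family. KSR3 pseudokinases keep the CRD but
have lost CC-SAM, HRD and DFG and carry degenerate P-loop and VAIK variants
— and their family-specific residues in the β3 strand, αC helix,
dimerization interface and activation segment sit exactly where activating
mutations of human B-RAF occur (the V600E region, L485, K499, the RKTR
motif R506–R509, D587/L588).

`ksrtools` is for sequence-analysis work that runs that comparison as a
pipeline:

* **motif fingerprinting** — `annotate_kinase()` grades every motif
  canonical / degenerate / absent, locates the NtA acidic motif, both
  14-3-3 sites, CRD/RBD/CC-SAM, and counts ERK-feedback P-x-[S/T]-P sites;
* **family classification** — `classify_family()` (RBD ⇒ RAF; CC-SAM ⇒
  KSR1/2; CRD without DFG/HRD ⇒ KSR3), corroborated by neighbor-joining
  trees with bootstrap supports (`bootstrap_tree()`);
* **divergence profiling** — `divergence_profile()` + `region_summary()`
  measure where a pseudokinase set diverges from a reference kinase,
  per position and per named region;
* **mutation transposition** — `donor_specific_residues()` +
  `transpose_mutations()` lift KSR3-specific residues onto the acceptor
  kinase through an affine-gap Gotoh alignment (`pairwise_align()`,
  `map_position()`), emitting candidates such as `L485R`, `K499L`,
  `R506S`, `delV487` and the `QLQA>DIND` segment swap, each checked
  against an embedded list of cancer-reported B-RAF positions;
* **synthetic benchmarking** — `make_family_set()` generates labelled
  RAF/KSR1-2/KSR3-like sequences with per-site noise, linker indels and a
  ground-truth kinase-core alignment, so every stage is testable offline.

All packaged reference sequences are *synthetic stand-ins* built in code;
the B-RAF-like reference reproduces canonical human B-RAF numbering for
every landmark in its kinase-domain segment (446–723), and the KSR stand-ins
carry their published landmark coordinates (e.g. sea-urchin-type KSR3
C37/C40, S84/S87, NtA S306/E307, dimer arginine R364, C-terminal serine
586). See the methods vignette (`vignettes/ksr3-comparative-analysis.Rmd`)
for the full design.

## Worked example

```r
library(ksrtools)

braf <- braf_reference()
ksr3 <- ksr3_reference("Pl")
annotate_kinase(ksr3)
#> <kinase_annotation Pl_KSR3_synth> domain 306-510 (high)
#>   PLOOP        degenerate 322-327 ETGKRG
#>   VAIK         degenerate 338-341 VLIQ
#>   HRD          absent
#>   DFG          absent
#>   DIMER_RKTR   degenerate 361-364 SKIR
#>   NTA          canonical  306-307 SE
#>   CTERM_1433   canonical  583-588 HSLSEP
#>   C1_CRD       canonical  25-56 HNQNAYAQWNMQCYYCLAWWWANLMWNWCANC
#>   NTERM_1433   canonical  84-87 SAMS
#>   fingerprint: has_cc_sam=FALSE has_rbd=FALSE has_crd=TRUE ... dfg_present=FALSE ...
```

The fingerprint reads: a C1/CRD but no CC-SAM or RBD, a Glu-x-Gly-x-x-Gly
P-loop, VLIQ in place of VAIK, no catalytic loop, no DFG — the KSR3
architecture (`classify_family()` returns `KSR3`).

Residue liftover onto B-RAF reproduces the homologous-position argument:

```r
aln <- pairwise_align(ksr3, braf)
map_position(aln, 343)   # KSR3 R343 -> B-RAF 485 (the L485R site)
#> [1] 485
map_position(aln, 361)   # KSR3 S361 -> B-RAF 506 (the R506E/R506S site)
#> [1] 506
```

and transposing the residues a synthetic KSR3 donor set carries onto the
B-RAF reference recovers the activating-mutant panel:

```r
fs <- make_family_set(6, noise = 0.02, seed = 1)
raf_row <- make_archetype(archetype_spec("RAF", seed = 1), id = "BRAF_synth")
rows <- c(BRAF_synth = raf_row$truth$msa_row,
          fs$msa$seqs[grepl("^KSR3", names(fs$msa$seqs))])
msa <- msa_from_strings(rows)
hits <- donor_specific_residues(msa, setdiff(names(rows), "BRAF_synth"), "BRAF_synth")
hits$acceptor_pos <- hits$acceptor_pos + 445L   # kinase-core row starts at B-RAF 446
cand <- transpose_mutations(hits, braf, annotate_kinase(braf))
head(cand[cand$kind == "substitution", c("label", "region", "hgvs", "known_oncogenic")], 5)
#>    label region        hgvs known_oncogenic
#> 2  L485R  BETA3 p.Leu485Arg           FALSE
#> 7  K499L ALPHAC p.Lys499Leu            TRUE
#> 8  G503A ALPHAC p.Gly503Ala           FALSE
#> 9  V504M ALPHAC p.Val504Met           FALSE
#> 10 R506S ALPHAC p.Arg506Ser            TRUE
```

`K499L` and `R506S` are flagged because K499 and R506 are cancer-reported
B-RAF positions; `L485R` is deliberately *not* flagged — substitutions at
L485 are known, but the arginine variant (which needs two base changes) has
never been described. The candidate table also contains the `delV487`
deletion and the `QLQA494-497>DIND` segment swap.

A command-line wrapper over the same functions lives at
`inst/scripts/ksrtools-cli.R` (subcommands `annotate`, `classify`, `tree`,
`diverge`, `transpose`, `simulate`, `validate-landmarks`, `pipeline`).

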