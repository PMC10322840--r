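# Synthetic reference sequences.
#
# The package has no bundled copies of the real RAF/KSR proteins; instead it
# constructs synthetic stand-ins whose landmark residues sit at the
# coordinates used throughout the human B-RAF and KSR3 literature (B-RAF
# G464/K483/L485/R506/RKTR 506-509/D576/DFG 594-596/V600, sea urchin KSR3
# C37/C40, S84/S87, NtA S306/E307, SKIR 361-364, K443/V444, D452/D455, S586,
# and their hemichordate/cnidarian counterparts).  The B-RAF-like stand-in's
# kinase segment (446-723) follows the canonical numbering of every one of
# those landmarks; regions outside the kinase domain are synthetic filler
# carrying exemplar accessory domains at realistic locations.  The KSR
# stand-ins are derived from the B-RAF kinase segment by an explicit edit
# script, so residue-level homology between the templates is known by
# construction and is used as ground truth for alignment, liftover and
# divergence tests.

# letters that cannot form any motif this package scans for
FILLER_ALPHABET <- strsplit("ALMNQWY", "")[[1]]

filler <- function(n, seed) {
  if (n == 0) return(character(0))
  with_seed(seed, sample(FILLER_ALPHABET, n, replace = TRUE))
}

# fixed exemplar domains (synthetic).  Generated once from a fixed stream,
# with rejection of the motif patterns the annotator scans for, so exemplar
# occurrences never confound motif counting.
.make_exemplar <- function(n, seed) {
  aa <- chars(AA_ALPHABET)
  forbidden <- c("P.[ST]P", "GS?.GS?..G", "G.G..G", "HRD", "DFG",
                 "V[A-Z][IV]K", ".S.SEP")
  for (k in 0:200) {
    s <- collapse0(with_seed(child_seed(seed, k), sample(aa, n, replace = TRUE)))
    if (!any(vapply(forbidden, function(p) grepl(p, s), logical(1)))) return(s)
  }
  stop("exemplar generation failed") # nocov
}

#' Packaged exemplar domain sequences (synthetic)
#'
#' Synthetic exemplars standing in for the RAS-binding domain (RBD, a
#' RAF-only domain) and the coiled-coil sterile-alpha-motif domain (CC-SAM,
#' a KSR1/2-only domain).  They are fixed, deterministic sequences used both
#' by the synthetic-sequence generator (which embeds them in the RAF and
#' KSR1-like templates) and by [detect_domain_by_exemplar()].
#'
#' @return A named list of protein [seq_record()]s with elements `RBD` and
#'   `CC_SAM`.
#' @export
domain_exemplars <- function() {
  list(
    RBD = seq_record("RBD_exemplar", .make_exemplar(75, 90001),
                     description = "synthetic RAS-binding-domain exemplar"),
    CC_SAM = seq_record("CC_SAM_exemplar", .make_exemplar(70, 90002),
                        description = "synthetic CC-SAM exemplar")
  )
}

# ---------------------------------------------------------------------------
# B-RAF-like reference

# kinase segment, canonical human B-RAF numbering 446-723 (278 residues)
.BRAF_KINASE_446_723 <- paste0(
  "SSDDWEIPDGQITVGQRIGSGSFG",                           # 446-469
  "TVYKGKWHGDVAVKMLNVTAPTPQQLQAFKNEVGVLRKTR",           # 470-509
  "HVNILLFMGYSTKPQLAIVTQWCEGSSLYHHLHIIETKFE",           # 510-549
  "MIKLIDIARQTAQGMDYLHAKSIIHRDLKSNNIFLHEDLTVKIGDFGLAT", # 550-599
  "VKSRWSGSHQFEQLSGSILWMAPEVIRMQDKNPYSFQSDVYAFGIVLYELMTGQLPYSNI", # 600-659
  "NNRDQIIFMVGRGYLSPDLSKVRSNCPKAMKRLMAECLKKKRDERPLFPQILASIELLARSLPK" # 660-723
)

# RAF-family diagnostic substitutions, applied to the B-RAF-like reference
# only, in the C-lobe tail (625-723): outside every named region and every
# landmark, so they give the RAF family its own shared derived characters
# (needed for the family to be recoverable as a clade) without touching the
# coordinates or the region-level divergence structure.
.RAF_SUBS <- c(
  "626" = "K", "633" = "F", "638" = "E", "645" = "I", "650" = "V",
  "658" = "D", "662" = "Q", "666" = "L", "671" = "T", "679" = "A",
  "684" = "S", "689" = "R", "697" = "I", "703" = "D", "710" = "V",
  "716" = "D"
)

# canonical B-RAF coordinates of the anchors used throughout the package
BRAF_COORDS <- list(
  nta = c(446L, 449L), ploop = c(464L, 469L), vaik = c(480L, 483L),
  rktr = c(506L, 509L), hrd = c(574L, 576L), dfg = c(594L, 596L),
  kinase = c(446L, 723L)
)

# place a string at positions [at, at+nchar-1] of a character vector
.emplace <- function(v, at, s) {
  cs <- chars(s)
  v[at:(at + length(cs) - 1L)] <- cs
  v
}

#' Synthetic B-RAF-like reference sequence
#'
#' A 766-residue protein stand-in for human B-RAF.  Its kinase-domain
#' segment (positions 446-723) reproduces canonical human B-RAF numbering
#' for every landmark this package works with: NtA SSDD 446-449, P-loop
#' G464-G469 (F468), VAVK with K483, L485, V487, QLQA 494-497, F498, K499,
#' L505, RKTR 506-509, HRD with catalytic D576, D587/L588, DFG 594-596,
#' L597, T599, V600.  The flanks are synthetic: an RBD exemplar at 155-229,
#' a C1/CRD cysteine pattern at 234-280, ERK-feedback P-x-S/T-P sites at
#' 401 and 748 (outside the kinase domain), and a C-terminal 14-3-3 site
#' RSASEP at 726-731 (key serine 729).
#'
#' @return A protein [seq_record()] with id `"BRAF_synth"`.
#' @export
braf_reference <- function() {
  v <- filler(766, 80001)
  ex <- domain_exemplars()
  v <- .emplace(v, 155L, ex$RBD$residues)                 # RBD 155-229
  # C1/CRD zinc-finger cysteine spacing H-x11-C-x2-C-x12-C-x2-C
  v <- .emplace(v, 240L, "H"); v <- .emplace(v, 252L, "C")
  v <- .emplace(v, 255L, "C"); v <- .emplace(v, 268L, "C")
  v <- .emplace(v, 271L, "C")
  v <- .emplace(v, 401L, "PQSP")                          # ERK feedback site
  v <- .emplace(v, 446L, .BRAF_KINASE_446_723)            # kinase segment
  v[as.integer(names(.RAF_SUBS))] <- unname(.RAF_SUBS)    # RAF-family characters
  v <- .emplace(v, 726L, "RSASEP")                        # C-terminal 14-3-3
  v <- .emplace(v, 748L, "PGTP")                          # ERK feedback site
  rec <- seq_record("BRAF_synth", collapse0(v),
                    description = "synthetic B-RAF-like reference (canonical kinase-domain numbering)")
  .check_landmarks(rec, c(G464 = "G", G466 = "G", F468 = "F", G469 = "G",
                          K483 = "K", L485 = "L", V487 = "V", Q494 = "Q",
                          L495 = "L", Q496 = "Q", A497 = "A", F498 = "F",
                          K499 = "K", L505 = "L", R506 = "R", R509 = "R",
                          D576 = "D", D587 = "D", L588 = "L", D594 = "D",
                          G596 = "G", L597 = "L", T599 = "T", V600 = "V"))
  rec
}

.check_landmarks <- function(rec, lm) {
  pos <- as.integer(sub("^[A-Z]", "", names(lm)))
  got <- residue_at(rec, pos)
  bad <- got != unname(lm)
  if (any(bad)) {
    stop("reference construction error in ", rec$id, ": ",         # nocov
         paste(names(lm)[bad], "=", got[bad], collapse = ", "))    # nocov
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# KSR3 edit script relative to the B-RAF kinase segment
#
# Substitutions encode the family-specific residues the comparative analysis
# detects (degenerate E-x-G-x-x-G P-loop, VLIQ in place of VAVK, R at the
# L485-equivalent, DIND in place of QLQA, L at the K499-equivalent, SKIR in
# place of RKTR, loss of HRD and DFG, acidic activation segment, K/V at the
# D587/L588 equivalents).  Deletions encode the 3-residue-shorter beta3-alphaC
# region (and a 2-residue-shorter NtA-to-P-loop stretch); the single
# insertion after B-RAF 545 reproduces the +1 offset implied by the
# K443/D587 correspondence.

.KSR3_SUBS_PL <- c(
  "447" = "E", "455" = "H", "460" = "Q",
  "464" = "E", "465" = "T", "467" = "K", "468" = "R",     # E-x-G-x-x-G P-loop
  "481" = "L", "482" = "I", "483" = "Q",                  # VLIQ
  "485" = "R",                                            # R at L485-equiv
  "494" = "D", "495" = "I", "496" = "N", "497" = "D",     # DIND
  "499" = "L",                                            # L at K499-equiv
  "503" = "A", "504" = "M",
  "506" = "S", "508" = "I",                               # SKIR dimer motif
  "511" = "E", "514" = "A",
  "574" = "S", "575" = "G", "576" = "Q",                  # HRD lost
  "587" = "K", "588" = "V",                               # K/V beta7-beta8
  "593" = "T", "594" = "S", "595" = "V", "596" = "D",     # DFG lost,
  "597" = "T", "598" = "S", "599" = "D", "601" = "T",     # acidic AS
  "602" = "N", "603" = "Q", "605" = "A", "608" = "N",     # divergent AS tail
  "610" = "Y", "612" = "M", "614" = "A", "617" = "L",
  "619" = "F", "624" = "I"
)
.KSR3_DELS_PL <- c(458L, 459L, 487L, 488L, 489L)
.KSR3_INS_AFTER <- 545L
.KSR3_INS_RES <- "N"

# KSR1/2 kinase edit script: HRD -> HKD plus scattered family-identifying
# substitutions away from motif anchors
.KSR1_SUBS <- c(
  "575" = "K",                                            # HKD catalytic loop
  "452" = "V", "462" = "K", "471" = "I", "477" = "N", "486" = "D",
  "521" = "S", "528" = "I", "537" = "M", "544" = "L", "552" = "R",
  "561" = "S", "583" = "Y", "604" = "F", "613" = "I", "628" = "E",
  "641" = "S", "655" = "A", "663" = "E", "678" = "I", "692" = "M",
  "706" = "V"
)

# apply a substitution set (names = B-RAF coordinates) to the kinase chars
.apply_subs <- function(kin, subs) {
  idx <- as.integer(names(subs)) - 445L
  kin[idx] <- unname(subs)
  kin
}

# map a B-RAF kinase coordinate into a derived template's own numbering
.map_braf_coord <- function(braf_pos, start, dels, ins_after = NULL) {
  if (braf_pos %in% dels) return(NA_integer_)
  p <- start + (braf_pos - 446L) - sum(dels < braf_pos)
  if (!is.null(ins_after) && braf_pos > ins_after) p <- p + 1L
  p
}

# species parameterization of the KSR3-like stand-ins: NtA coordinates,
# NtA residue pair, C-terminal 14-3-3 motif, and small length offsets that
# reproduce the printed coordinates of each homolog
.KSR3_SPECIES <- list(
  Pl = list(nta_start = 306L, nta = c("S", "E"), extra_del = integer(0),
            cterm_motif = "HSLSEP", tail_pad = 0L,
            desc = "synthetic sea-urchin-type KSR3 stand-in"),
  Sk = list(nta_start = 293L, nta = c("D", "E"), extra_del = 455L,
            cterm_motif = "HSQSEP", tail_pad = 0L,
            desc = "synthetic hemichordate-type KSR3 stand-in"),
  Nv = list(nta_start = 332L, nta = c("S", "E"), extra_del = integer(0),
            cterm_motif = "GSHSEP", tail_pad = 6L,
            desc = "synthetic cnidarian-type KSR3 stand-in")
)

#' Synthetic KSR3-like reference sequence
#'
#' Builds the KSR3 pseudokinase stand-in for one of three species types.
#' All three share the same architecture - C1/CRD with cysteines 37/40, an
#' N-terminal 14-3-3 serine pair (84/87), an NtA acidic pair immediately
#' N-terminal of the kinase domain, a kinase domain with degenerate P-loop
#' (E-x-G-x-x-G), VLIQ in place of VAIK, no HRD, no DFG, an S/D-rich acidic
#' activation segment, the SKIR dimerization motif, and a C-terminal
#' x-S-x-S-E-P 14-3-3 site - but differ in linker lengths so that each
#' homolog's landmark residues fall at its published coordinates:
#' `"Pl"` (sea urchin type): NtA S306/E307, dimer arginine R364, key C-term
#' serine 586 (HSLSEP); `"Sk"` (hemichordate type): NtA D293/E294, R350,
#' S572 (HSQSEP); `"Nv"` (cnidarian type): R390, S618 (GSHSEP).
#'
#' @param species `"Pl"`, `"Sk"` or `"Nv"`.
#' @return A protein [seq_record()].
#' @export
ksr3_reference <- function(species = c("Pl", "Sk", "Nv")) {
  species <- match.arg(species)
  sp <- .KSR3_SPECIES[[species]]
  dels <- sort(c(.KSR3_DELS_PL, sp$extra_del))

  kin <- chars(.BRAF_KINASE_446_723)
  kin <- .apply_subs(kin, .KSR3_SUBS_PL)
  kin[1:2] <- sp$nta
  kin <- kin[-(dels - 445L)]
  ins_at <- .KSR3_INS_AFTER - 445L - sum(dels < .KSR3_INS_AFTER)
  kin <- append(kin, .KSR3_INS_RES, after = ins_at)

  head <- filler(sp$nta_start - 1L, 80100L + match(species, names(.KSR3_SPECIES)))
  head <- .emplace(head, 25L, "H")
  head <- .emplace(head, 37L, "C"); head <- .emplace(head, 40L, "C")
  head <- .emplace(head, 53L, "C"); head <- .emplace(head, 56L, "C")
  head <- .emplace(head, 84L, "S"); head <- .emplace(head, 87L, "S")

  tail_fill <- filler(3L + sp$tail_pad, 80200L + match(species, names(.KSR3_SPECIES)))
  v <- c(head, kin, tail_fill, chars(sp$cterm_motif), chars("DNLNGTLFR"))
  rec <- seq_record(paste0(species, "_KSR3_synth"), collapse0(v),
                    description = sp$desc)

  # construction-time landmark validation
  dimer <- .map_braf_coord(509L, sp$nta_start, dels, .KSR3_INS_AFTER)
  stopifnot(residue_at(rec, dimer) == "R")
  if (species == "Pl") {
    .check_landmarks(rec, c(C37 = "C", C40 = "C", S84 = "S", S87 = "S",
                            S306 = "S", E307 = "E", R343 = "R", L354 = "L",
                            S361 = "S", K362 = "K", I363 = "I", R364 = "R",
                            K443 = "K", V444 = "V", T449 = "T", D452 = "D",
                            T453 = "T", S454 = "S", D455 = "D", T457 = "T",
                            S586 = "S"))
  }
  if (species == "Sk") {
    .check_landmarks(rec, c(D293 = "D", E294 = "E", R350 = "R", S572 = "S"))
  }
  if (species == "Nv") {
    .check_landmarks(rec, c(R390 = "R", S618 = "S"))
  }
  rec
}

#' Synthetic KSR1/2-like reference sequence
#'
#' An 845-residue stand-in for a KSR1/2-family scaffold: CC-SAM exemplar at
#' 45-114, proline-rich stretch with two ERK-feedback P-x-T-P sites, C1/CRD
#' at 180-211, N-terminal 14-3-3 serine pair 240/243, and a kinase domain
#' (545-822) that is a lightly substituted copy of the B-RAF kinase segment
#' with the catalytic-loop HRD replaced by the partially conserved HKD.
#' The dimerization arginine (final R of RKTR) falls at position 608.
#'
#' @return A protein [seq_record()] with id `"Pl_KSR1_synth"`.
#' @export
ksr1_reference <- function() {
  v <- filler(845, 80002)
  ex <- domain_exemplars()
  v <- .emplace(v, 45L, ex$CC_SAM$residues)               # CC-SAM 45-114
  v <- .emplace(v, 122L, "APPTPPAAPPTPP")                 # P-rich, 2 feedback sites
  v <- .emplace(v, 180L, "H"); v <- .emplace(v, 192L, "C")
  v <- .emplace(v, 195L, "C"); v <- .emplace(v, 208L, "C")
  v <- .emplace(v, 211L, "C")
  v <- .emplace(v, 240L, "S"); v <- .emplace(v, 243L, "S")
  kin <- .apply_subs(chars(.BRAF_KINASE_446_723), .KSR1_SUBS)
  v <- .emplace(v, 545L, collapse0(kin))                  # kinase 545-822
  v <- .emplace(v, 828L, "HSGSEP")                        # C-terminal 14-3-3
  rec <- seq_record("Pl_KSR1_synth", collapse0(v),
                    description = "synthetic KSR1/2-like reference (CC-SAM, HKD catalytic loop)")
  .check_landmarks(rec, c(H673 = "H", K674 = "K", D675 = "D", K582 = "K",
                          R608 = "R", S831 = "S"))
  rec
}
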