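# Landmark bookkeeping: the named residues of the B-RAF/KSR3 comparative
# analysis, with validation against loaded sequences to guard against
# numbering drift.

#' Packaged landmark table
#'
#' The named residues used throughout the analysis, one row per landmark:
#' human-B-RAF-numbered sites (P-loop glycines G464/G466/G469 and F468, the
#' VAIK lysine K483, beta3 L485 and V487, the alphaC QLQA span 494-497 with
#' F498 and K499, L505, the RKTR dimerization motif 506-509, catalytic D576,
#' beta7-beta8 D587/L588, activation-segment D594/L597/T599/V600, the NtA
#' SSDD span 446-449) and the KSR3/KSR1 homolog sites (sea-urchin-type KSR3
#' C37/C40, S84/S87, NtA S306/E307, R343, L354, SKIR 361-364, K443/V444,
#' D452/D455, S586, the VTA insertion point 345; KSR1 R608; hemichordate
#' KSR3 D293/E294, R350, S572; cnidarian KSR3 R390, S618).
#'
#' @param offset Constant numbering offset added to every position of a
#'   sequence (named vector, e.g. `c(Pl_KSR3_synth = 0)`); used when a
#'   source's translation start differs from the published numbering.
#' @return data.frame with columns `sequence`, `landmark`, `position`,
#'   `residue`, `note`.
#' @export
landmark_table <- function(offset = NULL) {
  row <- function(sequence, landmark, position, residue, note = "") {
    data.frame(sequence = sequence, landmark = landmark, position = position,
               residue = residue, note = note, stringsAsFactors = FALSE)
  }
  braf <- function(l, p, r, note = "") row("BRAF_synth", l, p, r, note)
  pl <- function(l, p, r, note = "") row("Pl_KSR3_synth", l, p, r, note)
  tab <- rbind(
    braf("G464", 464, "G", "P-loop"), braf("G466", 466, "G", "P-loop"),
    braf("F468", 468, "F", "P-loop"), braf("G469", 469, "G", "P-loop"),
    braf("K483", 483, "K", "VAIK lysine"),
    braf("L485", 485, "L", "beta3"), braf("V487", 487, "V", "beta3-alphaC"),
    braf("Q494", 494, "Q", "QLQA span"), braf("L495", 495, "L", "QLQA span"),
    braf("Q496", 496, "Q", "QLQA span"), braf("A497", 497, "A", "QLQA span"),
    braf("F498", 498, "F", "alphaC hydrophobic network"),
    braf("K499", 499, "K", "alphaC"), braf("L505", 505, "L", "R-spine"),
    braf("R506", 506, "R", "RKTR/DIF"), braf("K507", 507, "K", "RKTR"),
    braf("T508", 508, "T", "RKTR"),
    braf("R509", 509, "R", "RKTR dimerization arginine"),
    braf("D576", 576, "D", "HRD catalytic aspartate"),
    braf("D587", 587, "D", "beta7-beta8"), braf("L588", 588, "L", "beta7-beta8"),
    braf("D594", 594, "D", "DFG"), braf("L597", 597, "L", "activation segment"),
    braf("T599", 599, "T", "activation segment"),
    braf("V600", 600, "V", "activation segment"),
    braf("S446", 446, "S", "NtA SSDD"), braf("S447", 447, "S", "NtA SSDD"),
    braf("D448", 448, "D", "NtA SSDD"), braf("D449", 449, "D", "NtA SSDD"),
    pl("C37", 37, "C", "C1/CRD"), pl("C40", 40, "C", "C1/CRD"),
    pl("S84", 84, "S", "N-terminal 14-3-3 pair"),
    pl("S87", 87, "S", "N-terminal 14-3-3 pair"),
    pl("S306", 306, "S", "NtA"), pl("E307", 307, "E", "NtA"),
    pl("R343", 343, "R", "beta3, homolog of B-RAF L485"),
    pl("VTA_insertion_point", 345, "P",
       "site of the 3-residue beta3-alphaC restoration insertion"),
    pl("L354", 354, "L", "alphaC, homolog of B-RAF K499"),
    pl("S361", 361, "S", "SKIR dimer motif, homolog of B-RAF R506"),
    pl("K362", 362, "K", "SKIR"), pl("I363", 363, "I", "SKIR"),
    pl("R364", 364, "R", "dimerization arginine, homolog of B-RAF R509"),
    pl("K443", 443, "K", "beta7-beta8, homolog of B-RAF D587"),
    pl("V444", 444, "V", "beta7-beta8, homolog of B-RAF L588"),
    pl("D452", 452, "D", "acidic activation segment"),
    pl("D455", 455, "D", "acidic activation segment"),
    pl("S586", 586, "S", "C-terminal 14-3-3 serine (HSLSEP)"),
    row("Pl_KSR1_synth", "R608", 608, "R", "dimerization arginine"),
    row("Sk_KSR3_synth", "D293", 293, "D", "NtA"),
    row("Sk_KSR3_synth", "E294", 294, "E", "NtA"),
    row("Sk_KSR3_synth", "R350", 350, "R", "dimerization arginine"),
    row("Sk_KSR3_synth", "S572", 572, "S", "C-terminal 14-3-3 serine (HSQSEP)"),
    row("Nv_KSR3_synth", "R390", 390, "R", "dimerization arginine"),
    row("Nv_KSR3_synth", "S618", 618, "S", "C-terminal 14-3-3 serine (GSHSEP)")
  )
  if (!is.null(offset)) {
    for (id in names(offset)) {
      tab$position[tab$sequence == id] <- tab$position[tab$sequence == id] + offset[[id]]
    }
  }
  tab
}

#' Validate a landmark table against loaded sequences
#'
#' Checks, per landmark, that the residue letter at the stated position of
#' the named sequence matches.  When every landmark of one sequence fails
#' but a single constant shift fixes all of them, that shift is suggested
#' (guards against off-by-constant numbering drift between a published
#' coordinate system and a translated ORF).
#'
#' @param table A [landmark_table()]-shaped data.frame.
#' @param records Named list of [seq_record()]s covering the table's
#'   sequence ids (ids not present are skipped).
#' @param max_shift Largest constant offset probed for the suggestion.
#' @return data.frame with columns of `table` plus `observed`, `pass`, and
#'   an attribute `suggested_offsets` (named numeric vector, one entry per
#'   sequence where a uniform shift repairs all failures).
#' @export
validate_landmarks <- function(table, records, max_shift = 10L) {
  if (inherits(records, "seq_record")) records <- list(records)
  ids <- vapply(records, function(r) r$id, character(1))
  names(records) <- ids
  keep <- table$sequence %in% ids
  tab <- table[keep, , drop = FALSE]
  tab$observed <- NA_character_
  tab$pass <- NA
  for (i in seq_len(nrow(tab))) {
    rec <- records[[tab$sequence[i]]]
    p <- tab$position[i]
    if (p >= 1 && p <= seq_length(rec)) {
      tab$observed[i] <- residue_at(rec, p)
      tab$pass[i] <- tab$observed[i] == tab$residue[i]
    } else {
      tab$pass[i] <- FALSE
    }
  }
  suggestions <- numeric(0)
  for (id in unique(tab$sequence)) {
    rows <- tab[tab$sequence == id, ]
    if (any(!rows$pass)) {
      rec <- records[[id]]
      for (s in setdiff(seq(-max_shift, max_shift), 0)) {
        p2 <- rows$position + s
        if (any(p2 < 1 | p2 > seq_length(rec))) next
        if (all(residue_at(rec, p2) == rows$residue)) {
          suggestions[id] <- s
          break
        }
      }
    }
  }
  attr(tab, "suggested_offsets") <- suggestions
  rownames(tab) <- NULL
  tab
}
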