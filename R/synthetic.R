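# Labelled synthetic RAF / KSR1-2 / KSR3 sequence generation with ground
# truth.  Templates are the synthetic references of references.R; noise is
# independent per-site substitution to a uniformly chosen different residue,
# applied only outside embedded motif positions (the embedded states -
# canonical, degenerate or absent - are part of the ground truth and are
# never mutated away); indels are restricted to inter-domain linkers.

# master column space for the ground-truth kinase-core alignment:
# B-RAF kinase coordinates 446..723 plus one insertion column after 545
.MSA_BRAF_COORDS <- local({
  v <- 446:723
  append(v, NA_integer_, after = match(545L, v))  # NA marks the insertion col
})

# per-family structural metadata (template coordinates)
.template_meta <- function(family, species = "Pl") {
  if (family == "RAF") {
    rec <- braf_reference()
    map <- function(bc) bc
    ins_pos <- NA_integer_
    protected <- c(446:449, 464:469, 480:483, 506:509, 574:576, 594:596,
                   240, 252, 255, 268, 271, 726:731, 401:404, 748:751)
    linkers <- list(c(285L, 395L))
    status <- c(PLOOP = "canonical", VAIK = "canonical", HRD = "canonical",
                DFG = "canonical", DIMER_RKTR = "canonical",
                NTA = "canonical", CTERM_1433 = "canonical",
                NTERM_1433 = "absent", C1_CRD = "canonical")
    fingerprint <- list(has_cc_sam = FALSE, has_rbd = TRUE, has_crd = TRUE,
                        ploop_canonical = TRUE, vaik_canonical = TRUE,
                        hrd_present = TRUE, dfg_present = TRUE,
                        has_nta_acidic = TRUE, has_cterm_1433 = TRUE,
                        erk_feedback_count = 2L)
    keys <- c(ploop_start = 464L, vaik_lysine = 483L, hrd_aspartate = 576L,
              dfg_start = 594L, dimer_arginine = 509L, nta_start = 447L,
              cterm_serine = 729L)
  } else if (family == "KSR1_2") {
    rec <- ksr1_reference()
    map <- function(bc) bc + 99L
    ins_pos <- NA_integer_
    protected <- c(545:548, 563:568, 579:582, 605:608, 673:675, 693:695,
                   180, 192, 195, 208, 211, 240, 243, 122:134, 828:833)
    linkers <- list(c(250L, 535L))
    status <- c(PLOOP = "canonical", VAIK = "canonical", HRD = "degenerate",
                DFG = "canonical", DIMER_RKTR = "canonical",
                NTA = "canonical", CTERM_1433 = "canonical",
                NTERM_1433 = "canonical", C1_CRD = "canonical")
    fingerprint <- list(has_cc_sam = TRUE, has_rbd = FALSE, has_crd = TRUE,
                        ploop_canonical = TRUE, vaik_canonical = TRUE,
                        hrd_present = TRUE, dfg_present = TRUE,
                        has_nta_acidic = TRUE, has_cterm_1433 = TRUE,
                        erk_feedback_count = 2L)
    keys <- c(ploop_start = 563L, vaik_lysine = 582L, hrd_aspartate = 675L,
              dfg_start = 693L, dimer_arginine = 608L, nta_start = 546L,
              cterm_serine = 831L)
  } else if (family == "KSR3") {
    rec <- ksr3_reference(species)
    sp <- .KSR3_SPECIES[[species]]
    dels <- sort(c(.KSR3_DELS_PL, sp$extra_del))
    map <- function(bc) .map_braf_coord(bc, sp$nta_start, dels, .KSR3_INS_AFTER)
    ins_pos <- map(545L) + 1L
    cterm_start <- map(723L) + 3L + sp$tail_pad + 1L
    protected <- c(
      25, 37, 40, 53, 56, 84, 87,
      sp$nta_start, sp$nta_start + 1L,
      map(464L):map(469L),              # degenerate P-loop
      map(480L):map(483L),              # VLIQ
      map(506L):map(509L),              # SKIR
      map(564L):map(586L),              # catalytic-loop window (HRD stays absent)
      map(590L):map(612L),              # DFG window (DFG stays absent)
      cterm_start:(cterm_start + 5L)    # x-S-x-S-E-P
    )
    linkers <- list(c(90L, sp$nta_start - 12L))
    status <- c(PLOOP = "degenerate", VAIK = "degenerate", HRD = "absent",
                DFG = "absent", DIMER_RKTR = "degenerate",
                NTA = "canonical", CTERM_1433 = "canonical",
                NTERM_1433 = "canonical", C1_CRD = "canonical")
    fingerprint <- list(has_cc_sam = FALSE, has_rbd = FALSE, has_crd = TRUE,
                        ploop_canonical = FALSE, vaik_canonical = FALSE,
                        hrd_present = FALSE, dfg_present = FALSE,
                        has_nta_acidic = TRUE, has_cterm_1433 = TRUE,
                        erk_feedback_count = 0L)
    keys <- c(ploop_start = map(464L), vaik_lysine = map(483L),
              hrd_aspartate = NA_integer_, dfg_start = NA_integer_,
              dimer_arginine = map(509L), nta_start = sp$nta_start,
              cterm_serine = cterm_start + 3L)
  } else stop("unknown family: ", family)
  list(record = rec, map = map, ins_pos = ins_pos, protected = protected,
       linkers = linkers, status = status, fingerprint = fingerprint,
       keys = keys,
       domain = c(unname(keys["nta_start"]), min(seq_length(rec), map(624L) + 30L)))
}

#' Parameter set for one synthetic archetype
#'
#' @param family `"RAF"`, `"KSR1_2"` or `"KSR3"`.
#' @param species For KSR3, the homolog type (`"Pl"`, `"Sk"`, `"Nv"`).
#' @param noise Per-site substitution probability outside embedded motif
#'   positions, in `[0, 0.5]`.
#' @param indel_rate Per-site insertion/deletion probability inside linker
#'   regions, in `[0, 0.2]`.
#' @param seed Integer seed; generation is deterministic given the
#'   parameter set.
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(family = c("RAF", "KSR1_2", "KSR3"),
                           species = "Pl", noise = 0, indel_rate = 0,
                           seed = 1L) {
  family <- match.arg(family)
  if (!(noise >= 0 && noise <= 0.5)) stop("noise must be in [0, 0.5]")
  if (!(indel_rate >= 0 && indel_rate <= 0.2)) stop("indel_rate must be in [0, 0.2]")
  if (family != "KSR3" && !identical(species, "Pl")) {
    stop("species variants are only defined for KSR3")
  }
  structure(list(family = family, species = species, noise = noise,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "archetype_spec")
}

#' Generate one labelled synthetic sequence with ground truth
#'
#' Realizes an [archetype_spec()]: the family template with substitution
#' noise outside the embedded motif positions and (optionally) indels
#' inside linkers.  At zero noise and zero indel rate the output equals the
#' template exactly.  The ground truth records the family label, every
#' embedded motif's status, the key-residue positions (indel-adjusted), the
#' kinase-domain span and the row of the ground-truth kinase-core
#' alignment.
#'
#' @param spec An [archetype_spec()].
#' @param id Sequence id (default derived from family and seed).
#' @return List with elements `record` ([seq_record()]) and `truth`.
#' @export
make_archetype <- function(spec, id = NULL) {
  stopifnot(inherits(spec, "archetype_spec"))
  meta <- .template_meta(spec$family, spec$species)
  tv <- chars(meta$record$residues)
  L <- length(tv)
  orig <- seq_len(L)
  aa <- chars(AA_ALPHABET)

  with_seed(spec$seed, {
    if (spec$noise > 0) {
      eligible <- setdiff(seq_len(L), meta$protected)
      hit <- eligible[stats::runif(length(eligible)) < spec$noise]
      for (p in hit) tv[p] <- sample(setdiff(aa, tv[p]), 1L)
    }
    if (spec$indel_rate > 0) {
      linker_pos <- unlist(lapply(meta$linkers, function(r) r[1]:r[2]))
      linker_pos <- setdiff(linker_pos, meta$protected)
      ops <- linker_pos[stats::runif(length(linker_pos)) < spec$indel_rate]
      for (p in sort(ops, decreasing = TRUE)) {
        if (stats::runif(1) < 0.5) {         # deletion
          tv <- tv[-p]; orig <- orig[-p]
        } else {                             # insertion after p
          tv <- append(tv, sample(aa, 1L), after = p)
          orig <- append(orig, NA_integer_, after = p)
        }
      }
    }
  })

  if (is.null(id)) {
    id <- sprintf("%s_%s_s%d", sub("_2$", "", spec$family),
                  spec$species, spec$seed)
  }
  record <- seq_record(id, collapse0(tv), description = sprintf(
    "synthetic %s archetype (noise %.3g, indels %.3g, seed %d)",
    spec$family, spec$noise, spec$indel_rate, spec$seed))

  pos_of <- function(p) {
    if (is.na(p)) return(NA_integer_)
    match(p, orig)
  }
  keys <- vapply(meta$keys, pos_of, integer(1))
  domain <- c(pos_of(meta$domain[1]), pos_of(meta$domain[2]))
  if (is.na(domain[2])) domain[2] <- length(tv)

  # ground-truth kinase-core alignment row over the master columns
  msa_row <- vapply(.MSA_BRAF_COORDS, function(bc) {
    p <- if (is.na(bc)) meta$ins_pos else meta$map(bc)
    if (is.na(p)) return("-")
    q <- pos_of(p)
    if (is.na(q)) "-" else tv[q]
  }, character(1))

  truth <- list(
    family = spec$family, species = spec$species, spec = spec,
    motif_status = meta$status, fingerprint = meta$fingerprint,
    key_positions = keys, domain = domain,
    msa_row = collapse0(msa_row)
  )
  # self-validation: embedded key residues must survive generation
  stopifnot(identical(
    unname(residue_at(record, unname(keys[!is.na(keys)]))),
    unname(residue_at(meta$record, unname(meta$keys[!is.na(keys)])))
  ))
  list(record = record, truth = truth)
}

#' Generate a labelled three-family sequence set
#'
#' `n_per_family` sequences from each of the RAF, KSR1/2 and KSR3
#' templates, all at the same noise level, plus the ground-truth table and
#' the ground-truth kinase-core alignment used for tree and divergence
#' benchmarks.  By template construction the within-family mutational
#' distance (noise) is much smaller than the between-family template
#' distance.
#'
#' @param n_per_family Sequences per family (>= 1).
#' @param noise Per-site substitution rate outside motif positions.
#' @param seed Integer seed.
#' @param indel_rate Linker indel rate (affects full-length sequences, not
#'   the kinase-core alignment).
#' @return List with `records` (named list of [seq_record()]),
#'   `truth` (data.frame id/family/species/seed), `truths` (full per-id
#'   ground truth) and `msa` (ground-truth kinase-core
#'   `multiple_alignment`).
#' @export
make_family_set <- function(n_per_family, noise = 0.02, seed = 1L,
                            indel_rate = 0) {
  stopifnot(n_per_family >= 1)
  fams <- c("RAF", "KSR1_2", "KSR3")
  records <- list(); truths <- list()
  rows <- character(0)
  tab <- list()
  k <- 0L
  for (fam in fams) {
    for (i in seq_len(n_per_family)) {
      k <- k + 1L
      s <- child_seed(seed, k)
      id <- sprintf("%s_%02d", sub("_2$", "", fam), i)
      a <- make_archetype(archetype_spec(fam, noise = noise,
                                         indel_rate = indel_rate, seed = s),
                          id = id)
      records[[id]] <- a$record
      truths[[id]] <- a$truth
      rows[id] <- a$truth$msa_row
      tab[[k]] <- data.frame(id = id, family = fam, species = a$truth$species,
                             seed = s, stringsAsFactors = FALSE)
    }
  }
  list(records = records, truth = do.call(rbind, tab), truths = truths,
       msa = msa_from_strings(rows))
}

#' Apply a candidate mutation to a sequence
#'
#' Applies a substitution, single-residue deletion or segment swap to a
#' record, guarding against numbering drift by checking the wild-type
#' residue(s) first.  The id is suffixed with the mutation label.
#'
#' @param record A [seq_record()].
#' @param mutation One row of a [transpose_mutations()] result (or a list
#'   with fields `kind`, `acceptor_pos`, `acceptor_residue`,
#'   `donor_residue`, `label`).
#' @return The mutated [seq_record()].
#' @export
inject_mutation <- function(record, mutation) {
  if (is.data.frame(mutation)) {
    stopifnot(nrow(mutation) == 1)
    mutation <- as.list(mutation)
  }
  pos <- mutation$acceptor_pos
  wt <- mutation$acceptor_residue
  v <- chars(record$residues)
  span <- pos:(pos + nchar(wt) - 1L)
  if (max(span) > length(v) || collapse0(v[span]) != wt) {
    stop("wild-type mismatch at ", pos, ": expected '", wt, "', found '",
         collapse0(v[span[span <= length(v)]]), "'")
  }
  if (mutation$kind == "substitution") {
    v[pos] <- mutation$donor_residue
  } else if (mutation$kind == "deletion") {
    v <- v[-span]
  } else if (mutation$kind == "segment_swap") {
    v <- append(v[-span], chars(mutation$donor_residue), after = pos - 1L)
  } else stop("unknown mutation kind: ", mutation$kind)
  seq_record(paste0(record$id, "_", mutation$label), collapse0(v),
             alphabet = record$alphabet,
             description = trimws(paste(record$description, mutation$label)))
}
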