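# Kinase-domain motif scanning and architecture fingerprinting.
#
# Short catalytic motifs are graded in three states: "canonical" (the class
# pattern matches exactly inside the search window), "degenerate" (the
# window-constrained best positional match retains at least half of the
# pattern's anchor residues), or "absent".  Search windows are positioned
# relative to the kinase-domain anchoring rather than at absolute
# coordinates, so the scan is stable under N-terminal extensions.

#' Motif catalog
#'
#' Definitions of the short kinase-domain motifs the annotator grades.  Each
#' entry gives the class pattern (`x` = any residue, `[..]` = residue class),
#' a canonical exemplar string, the anchor coordinate of the motif start in
#' the packaged kinase-domain exemplar (canonical B-RAF numbering), and the
#' 1-based offset of the motif's key residue (e.g. the VAIK lysine, the HRD
#' catalytic aspartate).
#'
#' @return Named list of `motif_def` lists with fields `id`, `pattern`,
#'   `exemplar`, `anchor`, `key_offset`.
#' @export
motif_defs <- function() {
  def <- function(id, pattern, exemplar, anchor, key_offset) {
    list(id = id, pattern = pattern, exemplar = exemplar,
         anchor = anchor, key_offset = key_offset)
  }
  list(
    PLOOP = def("PLOOP", "G-x-G-x-x-G", "GSGSFG", 464L, 1L),
    VAIK = def("VAIK", "V-A-[IV]-K", "VAVK", 480L, 4L),
    HRD = def("HRD", "H-R-D", "HRD", 574L, 3L),
    DFG = def("DFG", "D-F-G", "DFG", 594L, 1L),
    DIMER_RKTR = def("DIMER_RKTR", "R-K-T-R", "RKTR", 506L, 4L)
  )
}

#' Packaged kinase-domain exemplar
#'
#' The kinase-domain segment (canonical numbering 446-723) of the synthetic
#' B-RAF-like reference, used to anchor motif search windows by local
#' alignment.
#' @return A protein [seq_record()].
#' @export
kinase_domain_exemplar <- function() {
  seq_record("kinase_exemplar", .BRAF_KINASE_446_723,
             description = "kinase-domain anchor exemplar (B-RAF numbering 446-723)")
}

# parse "G-x-G-x-x-G" into a list of residue classes (NULL = any)
.parse_pattern <- function(pattern) {
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  lapply(toks, function(t) {
    if (t == "x") return(NULL)
    chars(gsub("\\[|\\]", "", t))
  })
}

.pattern_regex <- function(pattern) {
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  collapse0(vapply(toks, function(t) {
    if (t == "x") "." else if (grepl("^\\[", t)) t else t
  }, character(1)))
}

# count positional anchor matches of a parsed pattern at offset `at`
.anchor_score <- function(seqchars, at, classes) {
  n <- length(classes)
  if (at < 1L || at + n - 1L > length(seqchars)) return(-1L)
  sum(vapply(seq_len(n), function(k) {
    cls <- classes[[k]]
    !is.null(cls) && seqchars[at + k - 1L] %in% cls
  }, logical(1)))
}

# local alignment of a sequence against the kinase exemplar; returns the
# alignment (seq as `a`, exemplar as `b`) or NULL if below `min_score`
.anchor_alignment <- function(seq, min_score = 200) {
  ex <- kinase_domain_exemplar()
  aln <- pairwise_align(seq, ex, alignment_params(mode = "local"))
  if (aln$score < min_score) return(NULL)
  aln
}

# map a canonical B-RAF coordinate into `seq` coordinates through the
# anchor alignment; falls back to nearest aligned column plus offset
.lift_braf <- function(aln, braf_pos) {
  cm <- aln$col_map
  ok <- !is.na(cm$pos_a) & !is.na(cm$pos_b)
  ex_pos <- cm$pos_b[ok] + 445L
  seq_pos <- cm$pos_a[ok]
  hit <- which(ex_pos == braf_pos)
  if (length(hit) == 1L) return(seq_pos[hit])
  k <- which.min(abs(ex_pos - braf_pos))
  seq_pos[k] + (braf_pos - ex_pos[k])
}

#' Locate the kinase domain of a protein sequence
#'
#' Anchors the kinase domain by local alignment against the packaged
#' kinase-domain exemplar, corroborated by exact catalytic-motif matches in
#' priority order HRD > DFG > VAIK > P-loop.  The returned span runs from
#' just N-terminal of the P-loop search region to about 30 residues past the
#' end of the activation segment.  When no anchoring evidence is found the
#' whole sequence is returned with a low-confidence flag.
#'
#' @param seq A protein [seq_record()].
#' @param min_score Minimum local-alignment score against the exemplar for
#'   alignment-based anchoring (default 200; random sequences score well
#'   below this, homologous kinase domains far above).
#' @return List with `span` (c(start, end)), `confidence` (`"high"`/`"low"`),
#'   `anchor` (name of the highest-priority anchoring evidence) and
#'   `anchor_aln` (the local alignment, or NULL).
#' @export
locate_kinase_domain <- function(seq, min_score = 200) {
  stopifnot(inherits(seq, "seq_record"), seq$alphabet == "protein")
  n <- seq_length(seq)
  aln <- .anchor_alignment(seq, min_score)
  if (!is.null(aln)) {
    start <- max(1L, .lift_braf(aln, 449L) - 3L)
    end <- min(n, .lift_braf(aln, 624L) + 30L)
    # name the highest-priority exact motif corroborating the alignment
    anchor <- "alignment"
    sc <- chars(seq$residues)
    for (id in c("HRD", "DFG", "VAIK", "PLOOP")) {
      d <- motif_defs()[[id]]
      exp_pos <- .lift_braf(aln, d$anchor)
      rex <- .pattern_regex(d$pattern)
      m <- regexpr(rex, substr(seq$residues,
                               max(1L, exp_pos - 12L),
                               min(n, exp_pos + 12L + nchar(d$exemplar))))
      if (m > 0) { anchor <- id; break }
    }
    return(list(span = c(start, end), confidence = "high",
                anchor = anchor, anchor_aln = aln))
  }
  # exact-motif anchoring with B-RAF-geometry spacing consistency
  hits <- lapply(motif_defs()[c("HRD", "DFG", "VAIK", "PLOOP")], function(d) {
    m <- gregexpr(.pattern_regex(d$pattern), seq$residues)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  })
  for (id in c("HRD", "DFG", "VAIK", "PLOOP")) {
    for (p in hits[[id]]) {
      others <- vapply(setdiff(c("HRD", "DFG", "VAIK", "PLOOP"), id),
        function(o) {
          exp_o <- p + (motif_defs()[[o]]$anchor - motif_defs()[[id]]$anchor)
          any(abs(hits[[o]] - exp_o) <= 8L)
        }, logical(1))
      if (sum(others) >= 1L) {
        start <- max(1L, p - (motif_defs()[[id]]$anchor - 449L) - 3L)
        end <- min(n, p + (624L - motif_defs()[[id]]$anchor) + 30L)
        return(list(span = c(start, end), confidence = "high",
                    anchor = id, anchor_aln = NULL))
      }
    }
  }
  list(span = c(1L, n), confidence = "low", anchor = "none", anchor_aln = NULL)
}

#' Scan for one catalytic motif
#'
#' Searches the motif's window (anchor-predicted position plus/minus
#' `window_pad`) and grades the hit: exact class-pattern match is
#' `"canonical"` (leftmost wins), otherwise the best positional match
#' retaining at least half of the pattern's anchor residues is
#' `"degenerate"` (its matched substring is reported as the variant, e.g.
#' `VLIQ`, `SKIR`, `HKD`-type strings), otherwise `"absent"`.  Without an
#' anchor alignment (low-confidence domains) only exact matches inside the
#' domain span are reported.
#'
#' @param seq A protein [seq_record()].
#' @param def One entry of [motif_defs()].
#' @param domain Result of [locate_kinase_domain()] (computed if NULL).
#' @param window_pad Half-width of the search window around the predicted
#'   motif position (default 10).
#' @return A `motif_hit`: list with `id`, `status`, `start`, `end`,
#'   `matched`, `key_pos`, `variant`.
#' @export
scan_motif <- function(seq, def, domain = NULL, window_pad = 10L) {
  if (is.null(domain)) domain <- locate_kinase_domain(seq)
  n <- seq_length(seq)
  plen <- nchar(def$exemplar)
  absent <- list(id = def$id, status = "absent", start = NA_integer_,
                 end = NA_integer_, matched = NA_character_,
                 key_pos = NA_integer_, variant = NA_character_)

  if (is.null(domain$anchor_aln)) {
    # no reliable coordinate prediction: accept exact matches in-domain only
    m <- regexpr(.pattern_regex(def$pattern),
                 substr(seq$residues, domain$span[1], domain$span[2]))
    if (m < 0) return(absent)
    start <- domain$span[1] + as.integer(m) - 1L
    return(list(id = def$id, status = "canonical", start = start,
                end = start + plen - 1L,
                matched = substr(seq$residues, start, start + plen - 1L),
                key_pos = start + def$key_offset - 1L,
                variant = NA_character_))
  }

  exp_pos <- .lift_braf(domain$anchor_aln, def$anchor)
  w1 <- max(1L, exp_pos - window_pad)
  w2 <- min(n, exp_pos + window_pad + plen - 1L)
  if (w2 - w1 + 1L < plen) return(absent)
  window <- substr(seq$residues, w1, w2)

  m <- regexpr(.pattern_regex(def$pattern), window)
  if (m > 0) {
    start <- w1 + as.integer(m) - 1L
    return(list(id = def$id, status = "canonical", start = start,
                end = start + plen - 1L,
                matched = substr(seq$residues, start, start + plen - 1L),
                key_pos = start + def$key_offset - 1L,
                variant = NA_character_))
  }

  classes <- .parse_pattern(def$pattern)
  n_anchor <- sum(!vapply(classes, is.null, logical(1)))
  sc <- chars(seq$residues)
  offs <- w1:(w2 - plen + 1L)
  scores <- vapply(offs, function(at) .anchor_score(sc, at, classes), integer(1))
  best <- max(scores)
  if (best * 2L >= n_anchor && best > 0L) {
    start <- offs[which.max(scores)] # leftmost tie-break
    matched <- substr(seq$residues, start, start + plen - 1L)
    return(list(id = def$id, status = "degenerate", start = start,
                end = start + plen - 1L, matched = matched,
                key_pos = start + def$key_offset - 1L, variant = matched))
  }
  absent
}

#' Locate the N-terminal acidic (NtA) motif
#'
#' The NtA phospho-acidic pair sits immediately N-terminal of the kinase
#' domain (B-RAF SSDD; sea urchin KSR3 S306/E307; hemichordate KSR3
#' D293/E294).  The locator reports the leftmost S/T/D/E-then-D/E pair in
#' the window just upstream of the P-loop.
#'
#' @param seq A protein [seq_record()].
#' @param annotation A [annotate_kinase()] result, or NULL to compute the
#'   anchoring on the fly.
#' @return A `motif_hit` with id `"NTA"` (`start`/`end` are the pair).
#' @export
locate_nta <- function(seq, annotation = NULL) {
  ploop_start <- .ploop_ref(seq, annotation)
  absent <- list(id = "NTA", status = "absent", start = NA_integer_,
                 end = NA_integer_, matched = NA_character_,
                 key_pos = NA_integer_, variant = NA_character_)
  if (is.na(ploop_start)) return(absent)
  w1 <- max(1L, ploop_start - 20L)
  w2 <- max(1L, ploop_start - 2L)
  if (w2 <= w1) return(absent)
  m <- regexpr("[STDE][DE]", substr(seq$residues, w1, w2))
  if (m < 0) return(absent)
  start <- w1 + as.integer(m) - 1L
  list(id = "NTA", status = "canonical", start = start, end = start + 1L,
       matched = substr(seq$residues, start, start + 1L),
       key_pos = start, variant = NA_character_)
}

# P-loop reference position: the P-loop hit if not absent, else the
# anchor-predicted position
.ploop_ref <- function(seq, annotation = NULL) {
  if (!is.null(annotation)) {
    h <- annotation$hits$PLOOP
    if (!is.na(h$start)) return(h$start)
    dom <- annotation$domain_info
  } else {
    dom <- locate_kinase_domain(seq)
    h <- scan_motif(seq, motif_defs()$PLOOP, dom)
    if (!is.na(h$start)) return(h$start)
  }
  if (!is.null(dom$anchor_aln)) return(.lift_braf(dom$anchor_aln, 464L))
  NA_integer_
}

#' Locate the C-terminal 14-3-3 binding site
#'
#' Matches the x-S-x-S-E-P consensus (sea urchin HSLSEP, hemichordate
#' HSQSEP, cnidarian GSHSEP, B-RAF RSASEP) in the C-terminal third of the
#' sequence.  The key residue is the serine directly preceding E-P.
#'
#' @param seq A protein [seq_record()].
#' @return A `motif_hit` with id `"CTERM_1433"`.
#' @export
locate_cterm_1433 <- function(seq) {
  n <- seq_length(seq)
  w1 <- max(1L, n - (n %/% 3L) + 1L)
  absent <- list(id = "CTERM_1433", status = "absent", start = NA_integer_,
                 end = NA_integer_, matched = NA_character_,
                 key_pos = NA_integer_, variant = NA_character_)
  m <- regexpr(".S.SEP", substr(seq$residues, w1, n))
  if (m < 0) return(absent)
  start <- w1 + as.integer(m) - 1L
  list(id = "CTERM_1433", status = "canonical", start = start,
       end = start + 5L, matched = substr(seq$residues, start, start + 5L),
       key_pos = start + 3L, variant = NA_character_)
}

#' Locate the N-terminal inhibitory 14-3-3 serine pair
#'
#' The paired serines (S-x-x-S; sea urchin KSR3 S84/S87, the position class
#' of the inhibitory 14-3-3 site of RAF/KSR proteins) are searched in the
#' linker between the C1/CRD domain and the kinase domain.  Note this site
#' is located by pattern, not by liftover: the RAF literature numbers the
#' equivalent site (S259) in C-RAF coordinates, which do not transfer
#' between homologs.
#'
#' @param seq A protein [seq_record()].
#' @param annotation Optional [annotate_kinase()] result.
#' @return A `motif_hit` with id `"NTERM_1433"`; `key_pos` is the first
#'   serine, `end` the second.
#' @export
locate_nterm_1433 <- function(seq, annotation = NULL) {
  crd <- locate_c1_crd(seq)
  w1 <- if (!is.na(crd$end)) crd$end + 1L else 1L
  nta <- if (!is.null(annotation)) annotation$hits$NTA else locate_nta(seq, annotation)
  w2 <- if (!is.na(nta$start)) nta$start - 1L else seq_length(seq)
  absent <- list(id = "NTERM_1433", status = "absent", start = NA_integer_,
                 end = NA_integer_, matched = NA_character_,
                 key_pos = NA_integer_, variant = NA_character_)
  if (w2 - w1 + 1L < 4L) return(absent)
  m <- regexpr("S..S", substr(seq$residues, w1, w2))
  if (m < 0) return(absent)
  start <- w1 + as.integer(m) - 1L
  list(id = "NTERM_1433", status = "canonical", start = start,
       end = start + 3L, matched = substr(seq$residues, start, start + 3L),
       key_pos = start, variant = NA_character_)
}

#' Locate the C1/CRD zinc-finger domain
#'
#' Matches a relaxed C1 cysteine-spacing pattern
#' (H-x(11,13)-C-x2-C-x(12,15)-C-x2-C); the key residues are the first two
#' cysteines of the match (e.g. C37 and C40 of the sea urchin KSR3
#' stand-in).
#'
#' @param seq A protein [seq_record()].
#' @return A `motif_hit` with id `"C1_CRD"`; `key_pos` is the first
#'   cysteine; the variant field carries "C<i>/C<j>" for the cysteine pair.
#' @export
locate_c1_crd <- function(seq) {
  absent <- list(id = "C1_CRD", status = "absent", start = NA_integer_,
                 end = NA_integer_, matched = NA_character_,
                 key_pos = NA_integer_, variant = NA_character_)
  m <- regexpr("H.{11,13}C.{2}C.{12,15}C.{2}C", seq$residues)
  if (m < 0) return(absent)
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  matched <- substr(seq$residues, start, end)
  cpos <- start + which(chars(matched) == "C") - 1L
  list(id = "C1_CRD", status = "canonical", start = start, end = end,
       matched = matched, key_pos = cpos[1],
       variant = paste0("C", cpos[1], "/C", cpos[2]))
}

#' Detect an accessory domain by exemplar alignment
#'
#' Local alignment of a packaged exemplar (see [domain_exemplars()]) against
#' the sequence; the domain is called present when the score reaches
#' `threshold`.  The default threshold (100) lies far above the empirical
#' maximum score of shuffled exemplars (null distribution) and far below
#' the self-alignment score of the exemplars, so presence calls are robust
#' to moderate substitution noise.
#'
#' @param seq A protein [seq_record()].
#' @param exemplar A protein [seq_record()] exemplar.
#' @param threshold Minimum local score for a "present" call.
#' @return List with `present`, `score` and `span` (c(start, end) in `seq`,
#'   or NAs when absent).
#' @export
detect_domain_by_exemplar <- function(seq, exemplar, threshold = 100) {
  aln <- pairwise_align(seq, exemplar, alignment_params(mode = "local"))
  pos <- aln$col_map$pos_a[!is.na(aln$col_map$pos_a)]
  list(present = aln$score >= threshold, score = aln$score,
       span = if (aln$score >= threshold && length(pos) > 0) {
         c(min(pos), max(pos))
       } else c(NA_integer_, NA_integer_))
}

#' Count ERK negative-feedback phosphorylation sites
#'
#' Counts strict P-x-S/T-P consensus matches outside the kinase domain
#' (the feedback sites of B-RAF and KSR1 lie in the flanking regions; KSR3
#' proteins lack them).
#'
#' @param seq A protein [seq_record()].
#' @param domain_span Optional c(start, end) kinase-domain span; matches
#'   starting inside it are excluded.  NULL counts the whole sequence.
#' @return Integer count (non-overlapping matches).
#' @export
count_erk_feedback_sites <- function(seq, domain_span = NULL) {
  m <- gregexpr("P.[ST]P", seq$residues)[[1]]
  if (m[1] == -1) return(0L)
  starts <- as.integer(m)
  if (!is.null(domain_span)) {
    starts <- starts[starts < domain_span[1] | starts > domain_span[2]]
  }
  length(starts)
}

#' Annotate a sequence with its kinase-domain motif architecture
#'
#' Runs the full locator battery (kinase-domain anchoring, the catalytic
#' motif scans, NtA, 14-3-3 sites, C1/CRD, RBD/CC-SAM exemplar detection,
#' ERK-feedback counting), fills the named region table and the
#' presence/absence fingerprint used for family classification.
#'
#' Regions are anchored to motif evidence: PLOOP is the P-loop match,
#' BETA3 the VAIK match +/-3, ALPHAC a window around the dimerization motif,
#' CATLOOP the HRD window, AS runs from the DFG position (observed or
#' predicted) to DFG+30, DIF is the dimer arginine +/-5, BETA7_BETA8 spans
#' from the catalytic-loop window to the start of the activation segment.
#'
#' @param seq A protein [seq_record()].
#' @param exemplars Accessory-domain exemplars, as [domain_exemplars()].
#' @param window_pad Motif search window half-width (see [scan_motif()]).
#' @param min_anchor_score See [locate_kinase_domain()].
#' @param exemplar_threshold See [detect_domain_by_exemplar()].
#' @return A `kinase_annotation` object: fields `id`, `domain` (span),
#'   `domain_confidence`, `hits` (list of motif hits), `regions`
#'   (data.frame region/start/end), `fingerprint` (named list).
#' @export
annotate_kinase <- function(seq, exemplars = domain_exemplars(),
                            window_pad = 10L, min_anchor_score = 200,
                            exemplar_threshold = 100) {
  dom <- locate_kinase_domain(seq, min_anchor_score)
  defs <- motif_defs()
  hits <- lapply(defs, function(d) scan_motif(seq, d, dom, window_pad))
  names(hits) <- names(defs)

  hits$NTA <- local({
    fake_ann <- list(hits = hits, domain_info = dom)
    locate_nta(seq, structure(fake_ann, class = "kinase_annotation"))
  })
  hits$CTERM_1433 <- locate_cterm_1433(seq)
  hits$C1_CRD <- locate_c1_crd(seq)
  hits$NTERM_1433 <- local({
    fake_ann <- list(hits = hits)
    locate_nterm_1433(seq, structure(fake_ann, class = "kinase_annotation"))
  })

  rbd <- detect_domain_by_exemplar(seq, exemplars$RBD, exemplar_threshold)
  ccsam <- detect_domain_by_exemplar(seq, exemplars$CC_SAM, exemplar_threshold)

  # region table; positions fall back to anchor-predicted coordinates when a
  # motif is absent, so degenerate kinases still get a full region map
  lift <- function(braf_pos) {
    if (!is.null(dom$anchor_aln)) return(.lift_braf(dom$anchor_aln, braf_pos))
    NA_integer_
  }
  span_of <- function(hit, braf_span) {
    if (!is.na(hit$start)) c(hit$start, hit$end)
    else c(lift(braf_span[1]), lift(braf_span[2]))
  }
  ploop <- span_of(hits$PLOOP, BRAF_COORDS$ploop)
  vaik <- span_of(hits$VAIK, BRAF_COORDS$vaik)
  rktr <- span_of(hits$DIMER_RKTR, BRAF_COORDS$rktr)
  hrd <- span_of(hits$HRD, BRAF_COORDS$hrd)
  dfg <- span_of(hits$DFG, BRAF_COORDS$dfg)
  beta3 <- c(vaik[1] - 3L, vaik[2] + 3L)
  alphac <- c(rktr[1] - 12L, rktr[2] + 5L)
  catloop <- c(hrd[1] - 4L, hrd[2] + 4L)
  as_span <- c(dfg[1], dfg[1] + 30L)
  dimer_key <- if (!is.na(hits$DIMER_RKTR$key_pos)) hits$DIMER_RKTR$key_pos else rktr[2]
  regions <- rbind(
    data.frame(region = "PLOOP", start = ploop[1], end = ploop[2]),
    data.frame(region = "BETA3", start = beta3[1], end = beta3[2]),
    data.frame(region = "BETA3_ALPHAC_LOOP", start = beta3[2] + 1L,
               end = alphac[1] - 1L),
    data.frame(region = "ALPHAC", start = alphac[1], end = alphac[2]),
    data.frame(region = "DIF", start = dimer_key - 5L, end = dimer_key + 5L),
    data.frame(region = "CATLOOP", start = catloop[1], end = catloop[2]),
    data.frame(region = "BETA7_BETA8", start = catloop[2] + 1L,
               end = as_span[1] - 1L),
    data.frame(region = "AS", start = as_span[1], end = as_span[2]),
    data.frame(region = "NTA",
               start = if (!is.na(hits$NTA$start)) hits$NTA$start else lift(446L),
               end = if (!is.na(hits$NTA$start)) hits$NTA$end else lift(449L)),
    data.frame(region = "CRD", start = hits$C1_CRD$start, end = hits$C1_CRD$end),
    data.frame(region = "CC_SAM", start = ccsam$span[1], end = ccsam$span[2])
  )
  n <- seq_length(seq)
  regions$start <- pmax(1L, regions$start)
  regions$end <- pmin(n, regions$end)

  present <- function(h) h$status %in% c("canonical", "degenerate")
  fingerprint <- list(
    has_cc_sam = ccsam$present,
    has_rbd = rbd$present,
    has_crd = present(hits$C1_CRD),
    ploop_canonical = identical(hits$PLOOP$status, "canonical"),
    vaik_canonical = identical(hits$VAIK$status, "canonical"),
    hrd_present = present(hits$HRD),
    dfg_present = present(hits$DFG),
    has_nta_acidic = present(hits$NTA),
    has_cterm_1433 = present(hits$CTERM_1433),
    erk_feedback_count = count_erk_feedback_sites(seq, dom$span)
  )
  structure(
    list(id = seq$id, domain = dom$span, domain_confidence = dom$confidence,
         domain_info = dom, hits = hits, regions = regions,
         fingerprint = fingerprint,
         rbd_score = rbd$score, ccsam_score = ccsam$score),
    class = "kinase_annotation"
  )
}

#' @export
print.kinase_annotation <- function(x, ...) {
  fp <- x$fingerprint
  cat(sprintf("<kinase_annotation %s> domain %d-%d (%s)\n", x$id,
              x$domain[1], x$domain[2], x$domain_confidence))
  for (h in x$hits) {
    cat(sprintf("  %-12s %-10s %s\n", h$id, h$status,
                if (!is.na(h$start)) sprintf("%d-%d %s", h$start, h$end, h$matched) else ""))
  }
  cat("  fingerprint:",
      paste(names(fp), vapply(fp, as.character, character(1)),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write annotation reports
#'
#' One motif per row as TSV, and a JSON document mirroring the full
#' annotation.
#' @param ann A `kinase_annotation`.
#' @param tsv,json Output paths (NULL to skip either).
#' @export
write_annotation <- function(ann, tsv = NULL, json = NULL) {
  tab <- do.call(rbind, lapply(ann$hits, function(h) {
    data.frame(id = ann$id, motif = h$id, status = h$status,
               start = h$start, end = h$end, matched = h$matched,
               key_pos = h$key_pos, variant = h$variant,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(tsv)) {
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- list(id = ann$id, domain = ann$domain,
                    domain_confidence = ann$domain_confidence,
                    motifs = tab[, -1], regions = ann$regions,
                    fingerprint = ann$fingerprint)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows", na = "null")
  }
  invisible(tab)
}
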