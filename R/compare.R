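# Divergence profiling, donor-specific residue detection and cross-homolog
# mutation transposition.

#' Read a multiple alignment
#'
#' Reads an aligned-FASTA or Clustal alignment, validates equal gapped
#' lengths and legal residues, and drops all-gap columns (the drop is
#' recorded in the `dropped_columns` attribute).
#'
#' @param path File path.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return A `multiple_alignment`: list with `ids`, `seqs` (named gapped
#'   strings, upper case) and `ncol`.
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    ids <- character(0); seqs <- character(0)
    cur <- NULL; buf <- character(0)
    flush <- function() {
      if (!is.null(cur)) {
        ids <<- c(ids, cur); seqs <<- c(seqs, collapse0(buf))
      }
    }
    for (line in lines) {
      line <- trimws(line)
      if (!nzchar(line)) next
      if (startsWith(line, ">")) {
        flush()
        cur <- strsplit(sub("^>", "", line), "\\s+")[[1]][1]
        buf <- character(0)
      } else buf <- c(buf, toupper(line))
    }
    flush()
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0 || !grepl("^CLUSTAL", lines[1])) {
      stop(path, " is not a Clustal alignment (missing CLUSTAL header)")
    }
    lines <- lines[-1]
    acc <- list()
    ids <- character(0)
    for (line in lines) {
      if (!nzchar(trimws(line))) next
      if (grepl("^\\s", line)) next                 # conservation line
      toks <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(toks) < 2) next
      id <- toks[1]
      chunk <- toupper(toks[2])
      if (!id %in% ids) { ids <- c(ids, id); acc[[id]] <- character(0) }
      acc[[id]] <- c(acc[[id]], chunk)
    }
    seqs <- vapply(ids, function(i) collapse0(acc[[i]]), character(1))
  }
  if (length(ids) == 0) stop("no sequences in ", path)
  if (anyDuplicated(ids)) stop("duplicate ids in ", path)
  if (length(unique(nchar(seqs))) != 1) {
    stop("ragged alignment in ", path, ": row lengths ",
         paste(unique(nchar(seqs)), collapse = ", "))
  }
  ok <- c(chars(paste0(AA_ALPHABET, "X")), "-")
  for (i in seq_along(ids)) {
    bad <- setdiff(unique(chars(seqs[i])), ok)
    if (length(bad) > 0) {
      stop("illegal character(s) ", paste(bad, collapse = " "),
           " in alignment row '", ids[i], "'")
    }
  }
  mat <- do.call(rbind, lapply(seqs, chars))
  allgap <- which(colSums(mat != "-") == 0)
  if (length(allgap) > 0) {
    mat <- mat[, -allgap, drop = FALSE]
    seqs <- apply(mat, 1, collapse0)
  }
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, ncol = nchar(seqs[[1]])),
            class = "multiple_alignment")
}

#' Build a multiple_alignment from gapped strings
#'
#' In-memory constructor used by the synthetic generator and tests.
#' @param seqs Named character vector of equal-length gapped strings.
#' @return A `multiple_alignment`.
#' @export
msa_from_strings <- function(seqs) {
  stopifnot(!is.null(names(seqs)), length(unique(nchar(seqs))) == 1)
  structure(list(ids = names(seqs), seqs = toupper(seqs),
                 ncol = nchar(seqs[[1]])),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d sequences x %d columns\n",
              length(x$ids), x$ncol))
  invisible(x)
}

#' Ungapped sequence of one alignment row
#' @param msa A `multiple_alignment`.
#' @param id Row id.
#' @return A protein [seq_record()].
#' @export
msa_row_record <- function(msa, id) {
  stopifnot(id %in% msa$ids)
  seq_record(id, gsub("-", "", msa$seqs[[id]], fixed = TRUE))
}

#' Per-position divergence profile against a reference
#'
#' For every alignment column in which the reference has a residue, the
#' fraction of the comparison set whose symbol differs from the reference.
#' By default a gap in a set sequence counts as divergent; columns where
#' the reference is gapped are skipped.
#'
#' @param msa A `multiple_alignment`.
#' @param ref_id Reference row id.
#' @param set_ids Ids of the comparison set (must not be empty; the
#'   reference itself is excluded if listed).
#' @param gap_divergent Should a gap in a set sequence count as divergent?
#' @return A `divergence_profile`: data.frame with columns `pos` (1-based
#'   reference position), `ref_residue`, `fraction`, `n_compared`, plus
#'   attributes `ref_id` and `columns` (the MSA column of each row).
#' @export
divergence_profile <- function(msa, ref_id, set_ids, gap_divergent = TRUE) {
  stopifnot(inherits(msa, "multiple_alignment"), ref_id %in% msa$ids)
  set_ids <- setdiff(set_ids, ref_id)
  missing <- setdiff(set_ids, msa$ids)
  if (length(missing) > 0) stop("not in MSA: ", paste(missing, collapse = ", "))
  if (length(set_ids) == 0) stop("empty comparison set")
  ref <- chars(msa$seqs[[ref_id]])
  set <- do.call(rbind, lapply(set_ids, function(i) chars(msa$seqs[[i]])))
  keep <- which(ref != "-")
  frac <- vapply(keep, function(cl) {
    col <- set[, cl]
    if (gap_divergent) {
      mean(col != ref[cl])
    } else {
      res <- col[col != "-"]
      if (length(res) == 0) return(NA_real_)
      mean(res != ref[cl])
    }
  }, numeric(1))
  out <- data.frame(pos = seq_along(keep), ref_residue = ref[keep],
                    fraction = frac, n_compared = length(set_ids),
                    stringsAsFactors = FALSE)
  attr(out, "ref_id") <- ref_id
  attr(out, "columns") <- keep
  class(out) <- c("divergence_profile", "data.frame")
  out
}

#' Mean divergence per annotated region, ranked
#'
#' Averages a divergence profile over the named regions of the reference
#' annotation and ranks regions from most to least divergent.  Regions with
#' no profiled reference position are omitted with a warning.
#'
#' @param profile A [divergence_profile()] (positions are reference
#'   coordinates).
#' @param ref_annotation The reference's [annotate_kinase()] result.
#' @return data.frame with columns `region`, `mean_divergence`,
#'   `n_positions`, `rank`, ordered by rank.
#' @export
region_summary <- function(profile, ref_annotation) {
  regions <- ref_annotation$regions
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (is.na(r$start) || is.na(r$end)) return(NULL)
    sel <- profile$pos >= r$start & profile$pos <= r$end
    if (!any(sel)) {
      warning("region ", r$region, " has no profiled position; omitted")
      return(NULL)
    }
    data.frame(region = r$region,
               mean_divergence = mean(profile$fraction[sel], na.rm = TRUE),
               n_positions = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_divergence, out$region), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Donor-specific residues
#'
#' Columns of the alignment in which at least `conservation` of the donor
#' sequences share one residue and that residue differs from the acceptor's
#' residue in the same column.  These are the candidate family-specific
#' positions used for mutation transposition.
#'
#' @param msa A `multiple_alignment` containing donors and acceptor.
#' @param donor_ids Donor row ids (non-empty).
#' @param acceptor_id Acceptor (reference) row id.
#' @param conservation Fraction of donors that must share the consensus
#'   residue (default 0.8).
#' @return data.frame with columns `acceptor_pos`, `acceptor_residue`,
#'   `donor_residue` (`"-"` for a donor-consensus gap), `donor_fraction`,
#'   `column`.  Rows where the acceptor is gapped are reported with
#'   `acceptor_pos = NA` (candidate insertions are outside the default
#'   transposition scope).
#' @export
donor_specific_residues <- function(msa, donor_ids, acceptor_id,
                                    conservation = 0.8) {
  stopifnot(inherits(msa, "multiple_alignment"))
  if (length(donor_ids) == 0) stop("empty donor set")
  missing <- setdiff(c(donor_ids, acceptor_id), msa$ids)
  if (length(missing) > 0) stop("not in MSA: ", paste(missing, collapse = ", "))
  acc <- chars(msa$seqs[[acceptor_id]])
  don <- do.call(rbind, lapply(donor_ids, function(i) chars(msa$seqs[[i]])))
  acc_pos <- cumsum(acc != "-")
  rows <- lapply(seq_along(acc), function(cl) {
    col <- don[, cl]
    tab <- sort(table(col), decreasing = TRUE)
    consensus <- names(tab)[1]
    frac <- tab[[1]] / length(col)
    if (frac < conservation) return(NULL)
    if (consensus == acc[cl]) return(NULL)
    if (acc[cl] == "-" && consensus == "-") return(NULL)
    data.frame(
      acceptor_pos = if (acc[cl] == "-") NA_integer_ else acc_pos[cl],
      acceptor_residue = if (acc[cl] == "-") NA_character_ else acc[cl],
      donor_residue = consensus, donor_fraction = unname(frac),
      column = cl, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(acceptor_pos = integer(0), acceptor_residue = character(0),
                      donor_residue = character(0), donor_fraction = numeric(0),
                      column = integer(0), stringsAsFactors = FALSE)
  }
  out
}

#' Transpose donor-specific residues onto the acceptor
#'
#' Turns donor-specific columns into candidate mutations of the acceptor in
#' standard notation: substitutions inside the regions of interest,
#' single-residue deletions where acceptor residues align to a donor
#' consensus gap, and segment swaps for contiguous runs of at least three
#' donor-specific substitutions (the run's individual substitutions are
#' folded into the swap).  Candidates are checked against the embedded
#' known-oncogenic lookup when the acceptor is the packaged B-RAF-like
#' reference.
#'
#' @param donor_hits A [donor_specific_residues()] result.
#' @param acceptor The acceptor [seq_record()].
#' @param acceptor_annotation The acceptor's [annotate_kinase()] result
#'   (supplies the region table).
#' @param regions Region names eligible for transposition; the default
#'   covers beta3, the beta3-alphaC loop, the alphaC helix, the
#'   dimerization interface, beta7-beta8 and the activation segment.
#' @return A data.frame of `candidate_mutation` rows: `acceptor_id`,
#'   `acceptor_pos`, `acceptor_residue`, `donor_residue`, `kind`
#'   (`substitution` / `deletion` / `segment_swap`), `label` (e.g.
#'   `L485R`), `hgvs` (e.g. `p.Leu485Arg`), `region`, `known_oncogenic`,
#'   `note`.
#' @export
transpose_mutations <- function(donor_hits, acceptor, acceptor_annotation,
                                regions = c("BETA3", "BETA3_ALPHAC_LOOP",
                                            "ALPHAC", "DIF", "BETA7_BETA8",
                                            "AS")) {
  reg <- acceptor_annotation$regions
  reg <- reg[reg$region %in% regions & !is.na(reg$start), ]
  in_region <- function(pos) {
    hit <- reg$region[pos >= reg$start & pos <= reg$end]
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  h <- donor_hits[!is.na(donor_hits$acceptor_pos), , drop = FALSE]
  h <- h[order(h$acceptor_pos), , drop = FALSE]
  h$region <- vapply(h$acceptor_pos, in_region, character(1))
  h <- h[!is.na(h$region), , drop = FALSE]

  subs <- h[h$donor_residue != "-", , drop = FALSE]
  dels <- h[h$donor_residue == "-", , drop = FALSE]

  # contiguous substitution runs of length >= 3 become segment swaps
  swap_rows <- list(); used <- rep(FALSE, nrow(subs))
  if (nrow(subs) > 0) {
    run_id <- cumsum(c(1L, diff(subs$acceptor_pos) != 1L))
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      if (length(idx) >= 3) {
        used[idx] <- TRUE
        from <- collapse0(subs$acceptor_residue[idx])
        to <- collapse0(subs$donor_residue[idx])
        p1 <- subs$acceptor_pos[idx[1]]; p2 <- subs$acceptor_pos[idx[length(idx)]]
        swap_rows[[length(swap_rows) + 1L]] <- data.frame(
          acceptor_pos = p1, acceptor_residue = from, donor_residue = to,
          kind = "segment_swap",
          label = sprintf("%s%d-%d>%s", from, p1, p2, to),
          region = subs$region[idx[1]], stringsAsFactors = FALSE
        )
      }
    }
  }
  sub_rows <- subs[!used, , drop = FALSE]
  out <- list()
  if (nrow(sub_rows) > 0) {
    out[[length(out) + 1L]] <- data.frame(
      acceptor_pos = sub_rows$acceptor_pos,
      acceptor_residue = sub_rows$acceptor_residue,
      donor_residue = sub_rows$donor_residue, kind = "substitution",
      label = sprintf("%s%d%s", sub_rows$acceptor_residue,
                      sub_rows$acceptor_pos, sub_rows$donor_residue),
      region = sub_rows$region, stringsAsFactors = FALSE
    )
  }
  if (nrow(dels) > 0) {
    out[[length(out) + 1L]] <- data.frame(
      acceptor_pos = dels$acceptor_pos,
      acceptor_residue = dels$acceptor_residue,
      donor_residue = "-", kind = "deletion",
      label = sprintf("del%s%d", dels$acceptor_residue, dels$acceptor_pos),
      region = dels$region, stringsAsFactors = FALSE
    )
  }
  out <- c(out, swap_rows)
  if (length(out) == 0) {
    res <- data.frame(acceptor_id = character(0), acceptor_pos = integer(0),
                      acceptor_residue = character(0),
                      donor_residue = character(0), kind = character(0),
                      label = character(0), hgvs = character(0),
                      region = character(0), known_oncogenic = logical(0),
                      note = character(0), stringsAsFactors = FALSE)
    class(res) <- c("candidate_mutations", "data.frame")
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$acceptor_pos, res$kind), ]
  res <- data.frame(acceptor_id = acceptor$id, res, stringsAsFactors = FALSE)

  # wild-type consistency guard
  first_res <- substr(res$acceptor_residue, 1, 1)
  stopifnot(all(first_res == residue_at(acceptor, res$acceptor_pos)))

  res$hgvs <- vapply(seq_len(nrow(res)), function(i) {
    if (res$kind[i] != "substitution") return(NA_character_)
    sprintf("p.%s%d%s", .aa3(res$acceptor_residue[i]), res$acceptor_pos[i],
            .aa3(res$donor_residue[i]))
  }, character(1))
  onc <- lapply(seq_len(nrow(res)), function(i) {
    known_oncogenic_lookup(res$acceptor_pos[i], res$donor_residue[i],
                           res$kind[i], acceptor$id)
  })
  res$known_oncogenic <- vapply(onc, function(x) x$flag, logical(1))
  res$note <- vapply(onc, function(x) x$note, character(1))
  # the alphaC QLQA segment swap is reported with both spellings of the
  # donor segment found in the source mutagenesis material
  qlqa <- res$kind == "segment_swap" & startsWith(res$acceptor_residue, "QLQA")
  res$note[qlqa] <- paste0("alphaC QLQA segment swap; donor segment reported",
                           " both as DIND and as DLND in mutagenesis primers")
  rownames(res) <- NULL
  class(res) <- c("candidate_mutations", "data.frame")
  res
}

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", X = "Xaa")
.aa3 <- function(aa) unname(.AA3[aa])

# Embedded catalogue of B-RAF positions with cancer-reported mutations at
# the sites this analysis touches, with variant-level detail where the
# literature distinguishes described from never-described changes.
.BRAF_ONCOGENIC <- list(
  "464" = list(known = c("E", "V", "R"), note = "G464E/V/R P-loop mutations reported in cancers"),
  "468" = list(known = c("K", "R", "N", "Q", "D"), note = "F468 substitutions reported in cancers"),
  "469" = list(known = c("A", "V", "S"), note = "G469A/V/S P-loop mutations reported in cancers"),
  "485" = list(known = c("F", "W", "S"), never = "R",
               note = "L485F/W/S reported in cancers; L485R never described (requires two base substitutions)"),
  "499" = list(known = "*", note = "K499 mutations reported in several cancers"),
  "506" = list(known = "*", never = "E",
               note = "R506 mutations reported in several cancers; R506E never described (requires two base substitutions)"),
  "588" = list(known = "*", note = "L588 mutations reported in several cancers"),
  "594" = list(known = "G", note = "D594G is oncogenic in humans"),
  "597" = list(known = c("H", "T", "G", "N", "M", "F", "V"),
               note = "L597 substitutions reported in cancers"),
  "600" = list(known = "E", note = "V600E is the prototypical activating mutation")
)

#' Known-oncogenic lookup for a candidate B-RAF mutation
#'
#' Checks a candidate substitution against the embedded static catalogue of
#' cancer-reported B-RAF positions (464, 468, 469, 485, 499, 506, 588, 594,
#' 597, 600).  The catalogue is variant-aware where the literature is:
#' L485F/W/S are flagged but L485R is not (never described), likewise
#' R506E.  No external database is ever queried.  For acceptors other than
#' the packaged B-RAF-like reference the flag is undetermined (`NA`).
#'
#' @param pos Acceptor position.
#' @param variant Donor residue (single letter), or anything else for
#'   non-substitutions.
#' @param kind Candidate kind (only `"substitution"` is looked up).
#' @param acceptor_id Acceptor sequence id.
#' @return List with `flag` (TRUE/FALSE/NA) and `note`.
#' @export
known_oncogenic_lookup <- function(pos, variant, kind = "substitution",
                                   acceptor_id = "BRAF_synth") {
  if (!identical(acceptor_id, "BRAF_synth")) {
    return(list(flag = NA, note = "acceptor is not the packaged B-RAF reference; flag undetermined"))
  }
  if (!identical(kind, "substitution")) {
    return(list(flag = FALSE, note = ""))
  }
  entry <- .BRAF_ONCOGENIC[[as.character(pos)]]
  if (is.null(entry)) return(list(flag = FALSE, note = ""))
  if (!is.null(entry$never) && variant %in% entry$never) {
    return(list(flag = FALSE, note = entry$note))
  }
  if (identical(entry$known, "*") || variant %in% entry$known) {
    return(list(flag = TRUE, note = entry$note))
  }
  list(flag = FALSE, note = paste0("position ", pos,
                                   " mutated in cancers, but this variant not in the embedded list"))
}

#' Write a divergence profile as TSV
#' @param profile A [divergence_profile()].
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write candidate mutations as TSV
#' @param candidates A [transpose_mutations()] result.
#' @param path Output path.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
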