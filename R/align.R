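#' Alignment parameters
#'
#' Scoring parameters for affine-gap pairwise alignment.  The default is the
#' standard protein setting: BLOSUM62 with gap-open 11 and gap-extend 1.
#' A gap of length L costs `gap_open + gap_extend * L` (same convention as
#' `Biostrings::pairwiseAlignment`).
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM70"`), or a numeric matrix with
#'   identical row/column dimnames.
#' @param gap_open Positive gap-opening cost; must be `>= gap_extend`.
#' @param gap_extend Positive per-column gap-extension cost.
#' @param mode `"global"` (Needleman-Wunsch-Gotoh) or `"local"`
#'   (Smith-Waterman-Gotoh).
#' @return An `alignment_params` object.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (!(gap_open >= gap_extend && gap_extend > 0)) {
    stop("need gap_open >= gap_extend > 0")
  }
  if (is.character(matrix)) {
    name <- matrix
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    matrix <- get(name, envir = e)
  } else {
    name <- "custom"
  }
  stopifnot(is.matrix(matrix), identical(rownames(matrix), colnames(matrix)))
  structure(
    list(matrix_name = name, matrix = matrix,
         gap_open = gap_open, gap_extend = gap_extend, mode = mode),
    class = "alignment_params"
  )
}

#' Pairwise affine-gap alignment
#'
#' Aligns two protein records with the Gotoh three-state recurrence, global
#' or local.  Traceback tie-breaking is fixed (diagonal, then gap-in-b, then
#' gap-in-a) so output is reproducible.
#'
#' @param a,b Protein [seq_record()]s.
#' @param params An [alignment_params()] object.
#' @return A `pairwise_alignment`: ids, the two equal-length gapped strings,
#'   the score and a per-column map (`col_map`) with columns
#'   `col, pos_a, res_a, pos_b, res_b` where gap positions are `NA`.
#'   Positions are 1-based in the input sequences.
#' @export
#' @examples
#' a <- seq_record("a", "MKVL"); b <- seq_record("b", "MKL")
#' pairwise_align(a, b)$score
pairwise_align <- function(a, b, params = alignment_params()) {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"))
  if (a$alphabet != "protein" || b$alphabet != "protein") {
    stop("pairwise_align expects protein records")
  }
  if (!nzchar(a$residues) || !nzchar(b$residues)) stop("empty sequence")
  res <- .gotoh_align_cpp(a$residues, b$residues,
                          params$matrix, paste(rownames(params$matrix), collapse = ""),
                          params$gap_open, params$gap_extend,
                          params$mode == "local")
  ca <- strsplit(res$aln_a, "")[[1]]
  cb <- strsplit(res$aln_b, "")[[1]]
  off_a <- if (params$mode == "local") res$start_a - 1L else 0L
  off_b <- if (params$mode == "local") res$start_b - 1L else 0L
  pos_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-") + off_a)
  pos_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-") + off_b)
  col_map <- data.frame(
    col = seq_along(ca),
    pos_a = as.integer(pos_a), res_a = ifelse(ca == "-", NA, ca),
    pos_b = as.integer(pos_b), res_b = ifelse(cb == "-", NA, cb),
    stringsAsFactors = FALSE
  )
  structure(
    list(id_a = a$id, id_b = b$id, aln_a = res$aln_a, aln_b = res$aln_b,
         score = res$score, mode = params$mode, params = params,
         col_map = col_map),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment %s/%s> %s, score %.1f, %d columns\n",
              x$id_a, x$id_b, x$mode, x$score, nrow(x$col_map)))
  invisible(x)
}

#' Map a residue position through a pairwise alignment
#'
#' Residue-coordinate liftover: returns the position in sequence b occupying
#' the same alignment column as position `pos` of sequence a, or `NA` when
#' that column is a gap in b (no homologous residue).  Both coordinates are
#' 1-based.
#'
#' @param aln A [pairwise_align()] result.
#' @param pos 1-based position in sequence a (for local alignments, within
#'   the aligned span).
#' @return Integer position in b, or `NA_integer_` for no match.
#' @export
map_position <- function(aln, pos) {
  stopifnot(inherits(aln, "pairwise_alignment"), length(pos) == 1L)
  pos <- as.integer(pos)
  avail <- aln$col_map$pos_a[!is.na(aln$col_map$pos_a)]
  if (pos < 1L || (aln$mode == "global" && pos > max(avail))) {
    stop("position ", pos, " outside sequence a (length ", max(avail), ")")
  }
  hit <- which(!is.na(aln$col_map$pos_a) & aln$col_map$pos_a == pos)
  if (length(hit) == 0) {
    if (aln$mode == "local") return(NA_integer_)
    stop("position ", pos, " outside sequence a")
  }
  aln$col_map$pos_b[hit]
}

#' Swap the two sequences of an alignment
#'
#' Returns the same alignment viewed from the other sequence, so that
#' `map_position(swap_alignment(aln), j)` inverts `map_position(aln, i)` on
#' matched columns.
#' @param aln A `pairwise_alignment`.
#' @export
swap_alignment <- function(aln) {
  cm <- aln$col_map
  structure(
    list(id_a = aln$id_b, id_b = aln$id_a, aln_a = aln$aln_b, aln_b = aln$aln_a,
         score = aln$score, mode = aln$mode, params = aln$params,
         col_map = data.frame(col = cm$col, pos_a = cm$pos_b, res_a = cm$res_b,
                              pos_b = cm$pos_a, res_b = cm$res_a,
                              stringsAsFactors = FALSE)),
    class = "pairwise_alignment"
  )
}

#' Percent identity of a pairwise alignment
#'
#' Identical columns divided by columns in which both sequences have a
#' residue.  Errors if there is no residue-residue column.
#'
#' @param aln A `pairwise_alignment`.
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln) {
  cm <- aln$col_map
  both <- !is.na(cm$pos_a) & !is.na(cm$pos_b)
  if (!any(both)) stop("no residue-residue column: identity undefined")
  sum(cm$res_a[both] == cm$res_b[both]) / sum(both)
}

#' Write a pairwise alignment as aligned FASTA
#' @param aln A `pairwise_alignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  write_fasta(list(
    structure(list(id = aln$id_a, description = "", residues = aln$aln_a,
                   alphabet = "protein"), class = "seq_record"),
    structure(list(id = aln$id_b, description = "", residues = aln$aln_b,
                   alphabet = "protein"), class = "seq_record")
  ), path)
}

#' Write the column map of a pairwise alignment as TSV
#' @param aln A `pairwise_alignment`.
#' @param path Output path.
#' @export
write_alignment_tsv <- function(aln, path) {
  utils::write.table(aln$col_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
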