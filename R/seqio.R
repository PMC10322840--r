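#' @useDynLib ksrtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"
DNA_ALPHABET <- "ACGT"

alphabet_chars <- function(alphabet) {
  switch(alphabet,
    protein = paste0(AA_ALPHABET, "X"),
    dna = paste0(DNA_ALPHABET, "N"),
    stop("unknown alphabet: ", alphabet)
  )
}

#' Construct a sequence record
#'
#' A `seq_record` holds one identified protein or DNA sequence.  Residues are
#' uppercased on construction and validated against the declared alphabet
#' (protein: the 20 amino acids plus X; dna: ACGT plus N).  Gap characters
#' are rejected: gapped sequences belong to alignments ([read_msa()]), not to
#' plain sequence records.
#'
#' @param id Accession or label (non-empty string).
#' @param residues Sequence string (non-empty).
#' @param alphabet `"protein"` or `"dna"`.
#' @param description Optional free-text description.
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `residues`, `alphabet`.
#' @export
#' @examples
#' seq_record("toy", "MKV")
seq_record <- function(id, residues, alphabet = "protein", description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("empty sequence for record '", id, "'")
  ok <- strsplit(alphabet_chars(alphabet), "")[[1]]
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), ok)
  if (length(bad) > 0) {
    stop("record '", id, "': illegal ", alphabet, " character(s): ",
         paste(bad, collapse = " "))
  }
  structure(
    list(id = id, description = description, residues = residues,
         alphabet = alphabet),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s> %s residues (%s)%s\n", x$id,
              nchar(x$residues), x$alphabet,
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Sequence length of a record
#' @param x A `seq_record`.
#' @export
seq_length <- function(x) nchar(x$residues)

#' Residue letter(s) at 1-based position(s)
#' @param x A `seq_record`.
#' @param pos Integer vector of 1-based positions.
#' @export
residue_at <- function(x, pos) {
  stopifnot(all(pos >= 1L), all(pos <= seq_length(x)))
  vapply(pos, function(p) substr(x$residues, p, p), character(1))
}

#' Read sequences from a FASTA file
#'
#' Parses a FASTA file into a list of [seq_record()]s.  Residues are
#' uppercased; order is preserved; the id is the first whitespace-delimited
#' token of the header and must be unique within the file.  Malformed input
#' (junk before the first header, illegal characters, gap characters) raises
#' an error naming the offending line.
#'
#' @param path File path.
#' @param alphabet `"protein"` or `"dna"`.
#' @return Named list of `seq_record`s (names are the ids).
#' @export
read_fasta <- function(path, alphabet = "protein") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines but keep numbering of the originals
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(structure(list(), names = character(0)))
  ok <- strsplit(alphabet_chars(alphabet), "")[[1]]
  records <- list()
  cur_id <- NULL; cur_desc <- ""; cur_seq <- character(0)
  flush <- function() {
    if (is.null(cur_id)) return()
    if (!is.null(records[[cur_id]])) {
      stop("duplicate id '", cur_id, "' in ", path)
    }
    records[[cur_id]] <<- seq_record(cur_id, paste(cur_seq, collapse = ""),
                                     alphabet = alphabet,
                                     description = cur_desc)
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush()
      header <- sub("^>", "", line)
      if (!nzchar(trimws(header))) {
        stop("malformed FASTA header at line ", ln, " of ", path)
      }
      toks <- strsplit(trimws(header), "\\s+")[[1]]
      cur_id <- toks[[1]]
      cur_desc <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
      cur_seq <- character(0)
    } else {
      if (is.null(cur_id)) {
        stop("sequence data before first header at line ", ln, " of ", path)
      }
      line <- toupper(gsub("\\s", "", line))
      bad <- setdiff(unique(strsplit(line, "")[[1]]), ok)
      if (length(bad) > 0) {
        stop("illegal ", alphabet, " character(s) ",
             paste(bad, collapse = " "), " at line ", ln, " of ", path)
      }
      cur_seq <- c(cur_seq, line)
    }
  }
  flush()
  records
}

#' Write sequence records as FASTA
#'
#' Standard FASTA output, 60 residues per line.  Headers are `>id` or
#' `>id description` when a description is present.
#'
#' @param records A `seq_record` or list of them.
#' @param path Output file path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in records) {
    header <- if (nzchar(rec$description)) {
      paste(rec$id, rec$description)
    } else rec$id
    writeLines(paste0(">", header), con)
    n <- nchar(rec$residues)
    if (n > 0) {
      starts <- seq(1L, n, by = 60L)
      writeLines(substring(rec$residues, starts, pmin(starts + 59L, n)), con)
    }
  }
  invisible(NULL)
}

#' Translate a DNA record to protein
#'
#' Standard-genetic-code translation from the given frame offset.
#' Translation stops at the first stop codon (the stop is not emitted); a
#' trailing partial codon is dropped; codons containing N translate to X.
#'
#' @param dna A `seq_record` with `alphabet = "dna"`.
#' @param frame Reading frame, 1, 2 or 3.
#' @return A protein `seq_record` with the same id (description notes the
#'   frame).
#' @export
#' @examples
#' translate_record(seq_record("x", "ATGGCT", alphabet = "dna"))
translate_record <- function(dna, frame = 1L) {
  stopifnot(inherits(dna, "seq_record"), dna$alphabet == "dna")
  frame <- as.integer(frame)
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3")
  s <- substring(dna$residues, frame)
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) stop("no complete codon in frame ", frame)
  s <- substr(s, 1L, 3L * n_codons)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(s),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
  aa <- sub("\\*.*$", "", aa)
  if (!nzchar(aa)) stop("translation of '", dna$id, "' is empty (immediate stop codon)")
  seq_record(dna$id, aa, alphabet = "protein",
             description = trimws(paste(dna$description,
                                        sprintf("[translated frame %d]", frame))))
}
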