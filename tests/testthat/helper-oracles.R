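# Independent oracles used by the test suite.  These deliberately avoid the
# package's dynamic-programming code paths: alignment scores come from
# exhaustive enumeration of all alignments, tree topologies from exhaustive
# scoring of all candidate topologies.

# All alignment "move templates" for sequence lengths (la, lb): strings over
# D (residue-residue column), U (gap in b), L (gap in a), with no gap-gap
# columns.  Returned as a list of move vectors.
enumerate_move_templates <- function(la, lb) {
  out <- list()
  recurse <- function(i, j, moves) {
    if (i == la && j == lb) {
      out[[length(out) + 1L]] <<- moves
      return(invisible(NULL))
    }
    if (i < la && j < lb) recurse(i + 1L, j + 1L, c(moves, "D"))
    if (i < la) recurse(i + 1L, j, c(moves, "U"))
    if (j < lb) recurse(i, j + 1L, c(moves, "L"))
  }
  recurse(0L, 0L, character(0))
  out
}

# affine gap cost of a move template: each maximal run of U (or of L) is one
# gap of its run length
template_gap_cost <- function(moves, gap_open, gap_extend) {
  r <- rle(moves)
  gaps <- r$lengths[r$values != "D"]
  if (length(gaps) == 0) return(0)
  sum(gap_open + gap_extend * gaps)
}

# Exhaustive-enumeration alignment score for one pair of sequences
# (character strings), global affine-gap model.
enumeration_align_score <- function(a, b, submat, gap_open, gap_extend,
                                    templates = NULL) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (is.null(templates)) templates <- enumerate_move_templates(length(ca), length(cb))
  best <- -Inf
  for (mv in templates) {
    i <- cumsum(mv != "L"); j <- cumsum(mv != "U")
    d <- mv == "D"
    s <- sum(submat[cbind(ca[i[d]], cb[j[d]])]) -
      template_gap_cost(mv, gap_open, gap_extend)
    if (s > best) best <- s
  }
  best
}

# Vectorised enumeration scoring of MANY pairs of fixed lengths (la, lb):
# A and B are matrices of single characters (rows = pairs).  Returns the
# vector of optimal scores.
enumeration_align_scores_batch <- function(A, B, submat, gap_open, gap_extend) {
  la <- ncol(A); lb <- ncol(B)
  templates <- enumerate_move_templates(la, lb)
  best <- rep(-Inf, nrow(A))
  for (mv in templates) {
    i <- cumsum(mv != "L"); j <- cumsum(mv != "U")
    d <- which(mv == "D")
    gc <- template_gap_cost(mv, gap_open, gap_extend)
    s <- rep(-gc, nrow(A))
    for (k in d) s <- s + submat[cbind(A[, i[k]], B[, j[k]])]
    best <- pmax(best, s)
  }
  best
}

# Build an additive distance matrix from a tree with branch lengths
tree_distances <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

# Exhaustive-topology oracle: among all unrooted topologies, the one whose
# least-squares branch-length fit reproduces the distances best.
best_topology_by_exhaustive_ls <- function(d) {
  taxa <- rownames(d)
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  ssq <- vapply(trees, function(tr) {
    fit <- phangorn::nnls.tree(d, tr, method = "unrooted")
    fit$edge.length[fit$edge.length < 0] <- 0
    sum((ape::cophenetic.phylo(fit)[taxa, taxa] - d)^2)
  }, numeric(1))
  trees[[which.min(ssq)]]
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Hand-constructible pairwise alignment object (bypasses the aligner) for
# testing coordinate mapping on fixed gapped strings.
manual_alignment <- function(aln_a, aln_b, id_a = "a", id_b = "b") {
  ca <- strsplit(aln_a, "")[[1]]; cb <- strsplit(aln_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  pos_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  pos_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  structure(
    list(id_a = id_a, id_b = id_b, aln_a = aln_a, aln_b = aln_b,
         score = NA_real_, mode = "global", params = NULL,
         col_map = data.frame(col = seq_along(ca),
                              pos_a = as.integer(pos_a),
                              res_a = ifelse(ca == "-", NA, ca),
                              pos_b = as.integer(pos_b),
                              res_b = ifelse(cb == "-", NA, cb),
                              stringsAsFactors = FALSE)),
    class = "pairwise_alignment"
  )
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}
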