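# RAF / KSR1-2 / KSR3 classification and tree-based corroboration.

#' Classify a sequence into the RAF / KSR1-2 / KSR3 families
#'
#' Pure function of the architecture fingerprint, using the family
#' discriminators in rule order: the RAS-binding domain is unique to RAF;
#' the CC-SAM domain is unique to KSR1/2; KSR3 has a CRD but has lost both
#' the HRD catalytic loop and the DFG motif.  A fingerprint carrying both
#' RBD and CC-SAM is contradictory and yields UNKNOWN (low confidence)
#' rather than a guess.
#'
#' @param annotation A [annotate_kinase()] result.
#' @return A `family_call`: list with `id`, `label` (`"RAF"`, `"KSR1_2"`,
#'   `"KSR3"`, `"UNKNOWN"`), `rules` (ordered trace of fired rules) and
#'   `confidence` (`"high"`/`"low"`).
#' @export
classify_family <- function(annotation) {
  fp <- annotation$fingerprint
  rules <- character(0)
  if (fp$has_rbd && fp$has_cc_sam) {
    return(structure(list(id = annotation$id, label = "UNKNOWN",
                          rules = "conflict: RBD and CC-SAM both present",
                          confidence = "low"), class = "family_call"))
  }
  label <- "UNKNOWN"
  if (fp$has_rbd) {
    label <- "RAF"
    rules <- c(rules, "has_rbd -> RAF")
  } else {
    rules <- c(rules, "no RBD")
    if (fp$has_cc_sam) {
      label <- "KSR1_2"
      rules <- c(rules, "has_cc_sam -> KSR1_2")
    } else {
      rules <- c(rules, "no CC-SAM")
      if (fp$has_crd && !fp$dfg_present && !fp$hrd_present) {
        label <- "KSR3"
        rules <- c(rules, "has_crd & no DFG & no HRD -> KSR3")
      }
    }
  }
  conf <- if (label == "UNKNOWN") "low" else annotation$domain_confidence
  structure(list(id = annotation$id, label = label,
                 rules = if (label == "UNKNOWN" && length(rules) == 0) "no rule satisfied" else rules,
                 confidence = conf),
            class = "family_call")
}

#' @export
print.family_call <- function(x, ...) {
  cat(sprintf("<family_call %s> %s (%s): %s\n", x$id, x$label, x$confidence,
              paste(x$rules, collapse = "; ")))
  invisible(x)
}

#' Pairwise distance matrix from a multiple alignment
#'
#' The p-distance of a pair is the fraction of differing columns among the
#' columns where both sequences have residues; `correction = "poisson"`
#' applies -ln(1 - p).
#'
#' @param msa A [read_msa()] result (or any `multiple_alignment`).
#' @param correction `"p"` or `"poisson"`.
#' @return A symmetric `dist`-convertible matrix with zero diagonal, taxa in
#'   MSA order.
#' @export
distance_matrix <- function(msa, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  stopifnot(inherits(msa, "multiple_alignment"))
  n <- length(msa$ids)
  if (n < 3) stop("need at least 3 sequences")
  mat <- do.call(rbind, lapply(msa$seqs, chars))
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(both)) {
        stop("sequences '", msa$ids[i], "' and '", msa$ids[j],
             "' share no residue columns")
      }
      p <- sum(mat[i, both] != mat[j, both]) / sum(both)
      if (correction == "poisson") {
        if (p >= 1) stop("Poisson correction undefined at p = 1 for pair '",
                         msa$ids[i], "'/'", msa$ids[j], "'")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration (via `ape::nj`) with negative
#' branch lengths clamped to zero.  Deterministic for a fixed input matrix.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An `ape::phylo` unrooted tree.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap supports on the neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and places majority-rule support values (percent of
#' replicates containing each internal bipartition) on the full-data tree.
#'
#' @param msa A `multiple_alignment` with at least 4 sequences.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; identical seeds give identical supports.
#' @param correction Distance correction, see [distance_matrix()].
#' @return The full-data NJ tree with `node.label` set to supports in
#'   `[0, 100]` (rounded to one decimal) and an attribute
#'   `"replicate_trees"` (a `multiPhylo` of the replicate trees).
#' @export
bootstrap_tree <- function(msa, replicates = 1000L, seed = 1L,
                           correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  stopifnot(inherits(msa, "multiple_alignment"))
  if (length(msa$ids) < 4) stop("bootstrap needs at least 4 sequences")
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be >= 1")
  full <- nj_tree(distance_matrix(msa, correction))
  ncol <- msa$ncol
  reps <- with_seed(seed, {
    lapply(seq_len(replicates), function(i) {
      cols <- sample.int(ncol, ncol, replace = TRUE)
      m2 <- msa
      m2$seqs <- vapply(msa$seqs, function(s) {
        collapse0(chars(s)[cols])
      }, character(1))
      nj_tree(distance_matrix(m2, correction))
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- round(100 * counts / replicates, 1)
  attr(full, "replicate_trees") <- reps
  full
}

#' Bootstrap support for one taxon group
#'
#' Convenience accessor: the support value of the internal edge separating
#' `taxa` from the rest of the tree, or `NA` if the group is not a clade of
#' the (unrooted) tree.
#'
#' @param tree A [bootstrap_tree()] result.
#' @param taxa Character vector of tip labels.
#' @return Numeric support in `[0, 100]`, or `NA`.
#' @export
clade_support <- function(tree, taxa) {
  stopifnot(!is.null(tree$node.label))
  tips <- tree$tip.label
  if (!all(taxa %in% tips)) stop("unknown tip label(s)")
  target <- sort(match(taxa, tips))
  ntip <- length(tips)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    desc <- .tips_below(tree, node)
    if (identical(sort(desc), target) ||
        identical(sort(setdiff(seq_len(ntip), desc)), target)) {
      return(tree$node.label[node - ntip])
    }
  }
  NA_real_
}

.tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Per-species family complement table
#'
#' Counts the family calls per species, one row per species, with columns
#' RAF, KSR1_2, KSR3 and UNKNOWN.
#'
#' @param calls List of [classify_family()] results.
#' @param species Character vector of species labels, parallel to `calls`.
#' @return A data.frame with columns `species`, `RAF`, `KSR1_2`, `KSR3`,
#'   `UNKNOWN`.
#' @export
complement_table <- function(calls, species) {
  stopifnot(length(calls) == length(species))
  levels <- c("RAF", "KSR1_2", "KSR3", "UNKNOWN")
  if (length(calls) == 0) {
    out <- data.frame(species = character(0))
    for (l in levels) out[[l]] <- integer(0)
    return(out)
  }
  labels <- vapply(calls, function(x) x$label, character(1))
  tab <- table(factor(species, levels = unique(species)),
               factor(labels, levels = levels))
  out <- data.frame(species = rownames(tab), stringsAsFactors = FALSE)
  for (l in levels) out[[l]] <- as.integer(tab[, l])
  rownames(out) <- NULL
  out
}

#' Write a tree with supports as Newick
#' @param tree An `ape::phylo`; internal-node labels (supports) are kept.
#' @param path Output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(NULL)
}
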