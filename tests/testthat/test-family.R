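test_that("family rules classify the three reference architectures", {
  expect_equal(classify_family(annotate_kinase(braf))$label, "RAF")
  expect_equal(classify_family(annotate_kinase(pl_ksr1))$label, "KSR1_2")
  call3 <- classify_family(annotate_kinase(pl_ksr3))
  expect_equal(call3$label, "KSR3")
  expect_gt(length(call3$rules), 0)
})

test_that("classification is a pure function of the fingerprint with UNKNOWN fallbacks", {
  blank <- function(fp_overrides) {
    fp <- list(has_cc_sam = FALSE, has_rbd = FALSE, has_crd = FALSE,
               ploop_canonical = FALSE, vaik_canonical = FALSE,
               hrd_present = FALSE, dfg_present = FALSE,
               has_nta_acidic = FALSE, has_cterm_1433 = FALSE,
               erk_feedback_count = 0L)
    fp[names(fp_overrides)] <- fp_overrides
    structure(list(id = "x", fingerprint = fp, domain_confidence = "high"),
              class = "kinase_annotation")
  }
  expect_equal(classify_family(blank(list()))$label, "UNKNOWN")
  # contradictory architecture: UNKNOWN rather than a guess
  conflicted <- classify_family(blank(list(has_rbd = TRUE, has_cc_sam = TRUE)))
  expect_equal(conflicted$label, "UNKNOWN")
  expect_equal(conflicted$confidence, "low")
  # KSR3 rule needs CRD and loss of both catalytic motifs
  expect_equal(classify_family(blank(list(has_crd = TRUE)))$label, "KSR3")
  expect_equal(classify_family(blank(list(has_crd = TRUE, dfg_present = TRUE)))$label,
               "UNKNOWN")
  # identical fingerprints always give identical labels
  expect_equal(classify_family(blank(list(has_rbd = TRUE)))$label,
               classify_family(blank(list(has_rbd = TRUE)))$label)
})

test_that("p-distances and the Poisson correction match hand counts", {
  msa <- msa_from_strings(c(a = "MKV", b = "MRV", c = "MRL"))
  d <- distance_matrix(msa, "p")
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["a", "c"], 2 / 3)
  expect_equal(d["b", "c"], 1 / 3)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  same <- msa_from_strings(c(a = "MKV", b = "MKV", c = "MKV"))
  expect_true(all(distance_matrix(same) == 0))
  # poisson(p = 0) = 0
  expect_true(all(distance_matrix(same, "poisson") == 0))

  nooverlap <- msa_from_strings(c(a = "MK--", b = "--VL", c = "MKVL"))
  expect_error(distance_matrix(nooverlap), "'a' and 'b'")
})

test_that("neighbor joining recovers a hand-drawn additive 4-taxon tree", {
  tr <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):0);")
  d <- tree_distances(tr)
  nj <- nj_tree(d)
  expect_true(same_topology(nj, tr))
  # path-length oracle: NJ branch lengths reproduce the additive distances
  expect_equal(tree_distances(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("3 taxa give the unique star resolution and taxon order is immaterial", {
  msa <- msa_from_strings(c(a = "MKVL", b = "MRVL", c = "MRLL"))
  d <- distance_matrix(msa)
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3)
  d6 <- tree_distances(ape::read.tree(
    text = "(((A:1,B:2):1,(C:2,D:1):2):1,(E:3,(F:1,G:1):1):1);"))
  t1 <- nj_tree(d6)
  perm <- withr::with_seed(4, sample(rownames(d6)))
  t2 <- nj_tree(d6[perm, perm])
  expect_true(same_topology(t1, t2))
})

test_that("NJ matches the exhaustive least-squares topology oracle on additive matrices", {
  skip_if_not_installed("phangorn")
  withr::with_seed(21, {
    for (n in c(5, 6)) {
      for (rep in 1:3) {
        tr <- ape::rtree(n, rooted = FALSE)
        tr$edge.length <- stats::runif(length(tr$edge.length), 0.5, 3)
        d <- tree_distances(tr)
        nj <- nj_tree(d)
        expect_true(same_topology(nj, tr))
        oracle <- best_topology_by_exhaustive_ls(d)
        expect_true(same_topology(nj, oracle))
      }
    }
  })
})

test_that("bootstrap supports are deterministic per seed and bounded", {
  fs <- make_family_set(2, noise = 0.03, seed = 5)
  t1 <- bootstrap_tree(fs$msa, replicates = 40, seed = 9)
  t2 <- bootstrap_tree(fs$msa, replicates = 40, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100))
  expect_error(bootstrap_tree(fs$msa, replicates = 0, seed = 1), "replicates")
})

test_that("bootstrap support estimates stabilize as replicates grow", {
  fs <- make_family_set(3, noise = 0.04, seed = 13)
  taxa <- grep("^KSR3", fs$truth$id, value = TRUE)
  support_at <- function(reps, seed) {
    clade_support(bootstrap_tree(fs$msa, replicates = reps, seed = seed), taxa)
  }
  spread <- function(reps) {
    s <- vapply(1:4, function(k) support_at(reps, seed = 100 + k), numeric(1))
    max(s) - min(s)
  }
  expect_lte(spread(120), spread(15) + 1e-9)
})

test_that("newick round trip preserves topology and supports", {
  fs <- make_family_set(2, noise = 0.03, seed = 5)
  tr <- bootstrap_tree(fs$msa, replicates = 25, seed = 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, f)
  back <- ape::read.tree(f)
  expect_true(same_topology(tr, back))
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(as.numeric(back$node.label[back$node.label != ""]),
               as.numeric(tr$node.label[back$node.label != ""]))
})

test_that("complement tables count family calls per species", {
  expect_equal(nrow(complement_table(list(), character(0))), 0)
  call <- function(id, label) {
    structure(list(id = id, label = label, rules = "r", confidence = "high"),
              class = "family_call")
  }
  calls <- list(call("a1", "RAF"), call("a2", "KSR3"), call("a3", "KSR3"),
                call("b1", "UNKNOWN"))
  tab <- complement_table(calls, c("spA", "spA", "spA", "spB"))
  expect_equal(tab$RAF, c(1, 0))
  expect_equal(tab$KSR3, c(2, 0))
  expect_equal(tab$UNKNOWN, c(0, 1))
  # generator-known composition is recovered exactly
  fs <- make_family_set(2, noise = 0, seed = 2)
  calls2 <- lapply(fs$records, function(r) classify_family(annotate_kinase(r)))
  tab2 <- complement_table(calls2, rep("synthetic_sp", length(calls2)))
  expect_equal(tab2$RAF, 2); expect_equal(tab2$KSR1_2, 2)
  expect_equal(tab2$KSR3, 2); expect_equal(tab2$UNKNOWN, 0)
})
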