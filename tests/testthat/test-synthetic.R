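test_that("archetype generation is deterministic and exact at zero noise", {
  spec <- archetype_spec("KSR3", noise = 0, indel_rate = 0, seed = 4)
  a1 <- make_archetype(spec); a2 <- make_archetype(spec)
  expect_identical(a1$record$residues, a2$record$residues)
  expect_identical(a1$record$residues, pl_ksr3$residues)
  raf <- make_archetype(archetype_spec("RAF", seed = 99))
  expect_identical(raf$record$residues, braf$residues)
  # different seeds at nonzero noise give different sequences
  n1 <- make_archetype(archetype_spec("RAF", noise = 0.05, seed = 1))
  n2 <- make_archetype(archetype_spec("RAF", noise = 0.05, seed = 2))
  expect_false(identical(n1$record$residues, n2$record$residues))
})

test_that("archetype specs are validated", {
  expect_error(archetype_spec("RAF", noise = 0.7), "noise")
  expect_error(archetype_spec("KSR1_2", indel_rate = 0.5), "indel_rate")
  expect_error(archetype_spec("RAF", species = "Sk"), "species")
})

test_that("annotation agrees with generator ground truth across seeds and noise", {
  for (fam in c("RAF", "KSR1_2", "KSR3")) {
    for (s in 1:10) {
      a <- make_archetype(archetype_spec(fam, noise = 0.03, seed = s))
      ann <- annotate_kinase(a$record)
      expect_identical(ann$fingerprint, a$truth$fingerprint,
                       info = paste(fam, s))
      # domain span close to generator truth
      expect_lt(abs(ann$domain[1] - a$truth$domain[1]), 8)
      expect_lt(abs(ann$domain[2] - a$truth$domain[2]), 8)
    }
  }
})

test_that("family sets have the advertised size, truth table and alignment geometry", {
  fs <- make_family_set(3, noise = 0.02, seed = 6)
  expect_length(fs$records, 9)
  expect_equal(nrow(fs$truth), 9)
  expect_equal(as.integer(table(fs$truth$family)[c("KSR1_2", "KSR3", "RAF")]),
               c(3L, 3L, 3L))
  expect_length(fs$msa$ids, 9)
  # every ungapped alignment row is a substring of its full-length sequence
  for (id in fs$msa$ids) {
    core <- gsub("-", "", fs$msa$seqs[[id]], fixed = TRUE)
    expect_true(grepl(core, fs$records[[id]]$residues, fixed = TRUE), info = id)
  }
  # n = 1 at zero noise reproduces the three archetypes
  fs0 <- make_family_set(1, noise = 0, seed = 1)
  expect_identical(fs0$records$RAF_01$residues, braf$residues)
  expect_identical(fs0$records$KSR1_01$residues, pl_ksr1$residues)
  expect_identical(fs0$records$KSR3_01$residues, pl_ksr3$residues)
})

test_that("indels stay in linkers and ground-truth key positions follow them", {
  a <- make_archetype(archetype_spec("KSR3", noise = 0.02, indel_rate = 0.05,
                                     seed = 12))
  k <- a$truth$key_positions
  expect_equal(residue_at(a$record, k[["dimer_arginine"]]), "R")
  expect_equal(residue_at(a$record, k[["nta_start"]]), "S")
  expect_equal(residue_at(a$record, k[["cterm_serine"]]), "S")
  # kinase-core alignment row is untouched by linker indels
  b <- make_archetype(archetype_spec("KSR3", noise = 0.02, indel_rate = 0,
                                     seed = 12))
  expect_identical(a$truth$msa_row, b$truth$msa_row)
  # and the annotator still recovers the fingerprint
  expect_identical(annotate_kinase(a$record)$fingerprint, a$truth$fingerprint)
})

test_that("classifier recovers all labels at zero noise", {
  fs <- make_family_set(30, noise = 0, seed = 2026)
  labels <- vapply(fs$records, function(r) {
    classify_family(annotate_kinase(r))$label
  }, character(1))
  truth <- fs$truth$family[match(names(labels), fs$truth$id)]
  expect_gte(length(labels), 90)
  expect_equal(unname(labels), truth)
})

test_that("mutation injection guards wild type and is reversible", {
  sub <- list(kind = "substitution", acceptor_pos = 485L,
              acceptor_residue = "L", donor_residue = "R", label = "L485R")
  mut <- inject_mutation(braf, sub)
  expect_equal(residue_at(mut, 485), "R")
  expect_match(mut$id, "L485R$")
  # revert: involution restores the original residues
  back <- inject_mutation(mut, list(kind = "substitution", acceptor_pos = 485L,
                                    acceptor_residue = "R", donor_residue = "L",
                                    label = "R485L"))
  expect_identical(back$residues, braf$residues)
  # deletion shortens by exactly one
  del <- inject_mutation(braf, list(kind = "deletion", acceptor_pos = 487L,
                                    acceptor_residue = "V", label = "delV487"))
  expect_equal(seq_length(del), seq_length(braf) - 1)
  # segment swap replaces the span
  swap <- inject_mutation(braf, list(kind = "segment_swap", acceptor_pos = 494L,
                                     acceptor_residue = "QLQA",
                                     donor_residue = "DIND",
                                     label = "QLQA494>DIND"))
  expect_equal(substr(swap$residues, 494, 497), "DIND")
  # wild-type mismatch is refused (numbering-drift guard)
  expect_error(inject_mutation(braf, list(kind = "substitution",
                                          acceptor_pos = 485L,
                                          acceptor_residue = "K",
                                          donor_residue = "R",
                                          label = "K485R")),
               "wild-type mismatch")
})
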