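test_that("MSA ingest validates, normalizes all-gap columns, and reads both dialects", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "MK-V", ">s2", "MRLV"), fa)
  msa <- read_msa(fa)
  expect_equal(msa$ids, c("s1", "s2"))
  expect_equal(msa$ncol, 4)

  # single ungapped sequence: columns = length
  writeLines(c(">only", "MKVL"), fa)
  expect_equal(read_msa(fa)$ncol, 4)

  # all-gap column dropped
  writeLines(c(">s1", "M-KV", ">s2", "M-RV"), fa)
  expect_equal(read_msa(fa)$ncol, 3)

  # ragged rows and illegal characters are format errors naming the row
  writeLines(c(">s1", "MKV", ">s2", "MKVL"), fa)
  expect_error(read_msa(fa), "ragged")
  writeLines(c(">s1", "MJV", ">s2", "MKV"), fa)
  expect_error(read_msa(fa), "'s1'")

  # a Clustal block parses identically to its aligned-FASTA twin
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               "s1   MK-VLE", "s2   MKRVLE", ""), cl)
  writeLines(c(">s1", "MK-VLE", ">s2", "MKRVLE"), fa)
  m1 <- read_msa(fa, "fasta"); m2 <- read_msa(cl, "clustal")
  expect_equal(m1$seqs, m2$seqs)
})

test_that("divergence profile matches the hand-computed toy alignment", {
  msa <- msa_from_strings(c(ref = "MKV", s1 = "MRV", s2 = "M-L"))
  prof <- divergence_profile(msa, "ref", c("s1", "s2"))
  expect_equal(prof$fraction, c(0, 1, 1 / 2))
  expect_equal(prof$ref_residue, c("M", "K", "V"))
  expect_equal(prof$n_compared, c(2, 2, 2))
  # gaps can be excluded from the denominator instead
  prof2 <- divergence_profile(msa, "ref", c("s1", "s2"), gap_divergent = FALSE)
  expect_equal(prof2$fraction, c(0, 1, 1 / 2))
  # set = reference alone: all zero
  prof3 <- divergence_profile(msa_from_strings(c(ref = "MKV", dup = "MKV")),
                              "ref", "dup")
  expect_equal(prof3$fraction, c(0, 0, 0))
  # column where all set members differ
  msa4 <- msa_from_strings(c(ref = "MK", s1 = "MR", s2 = "MQ"))
  expect_equal(divergence_profile(msa4, "ref", c("s1", "s2"))$fraction[2], 1)
  expect_error(divergence_profile(msa, "ref", character(0)), "empty")
})

test_that("profile columns where the reference is gapped are skipped and fractions are permutation-invariant", {
  msa <- msa_from_strings(c(ref = "M-KV", s1 = "MAKL", s2 = "MARV"))
  prof <- divergence_profile(msa, "ref", c("s1", "s2"))
  expect_equal(nrow(prof), 3)              # gap column skipped
  expect_true(all(prof$fraction >= 0 & prof$fraction <= 1))
  prof_swapped <- divergence_profile(msa, "ref", c("s2", "s1"))
  expect_equal(prof$fraction, prof_swapped$fraction)
})

test_that("region summary ranks a constructed elevated region first", {
  ann <- annotate_kinase(braf)
  prof <- data.frame(pos = 446:654, ref_residue = "A",
                     fraction = 0.05, n_compared = 10)
  rs_uniform <- suppressWarnings(region_summary(prof, ann))
  expect_true(all(abs(rs_uniform$mean_divergence - 0.05) < 1e-12))
  prof$fraction[prof$pos >= 464 & prof$pos <= 469] <- 0.9
  rs <- suppressWarnings(region_summary(prof, ann))
  expect_equal(rs$region[1], "PLOOP")
})

test_that("synthetic KSR3 set diverges from RAF mostly in P-loop, alphaC and activation segment", {
  fs <- make_family_set(8, noise = 0.02, seed = 31)
  raf_ref <- make_archetype(archetype_spec("RAF", seed = 1), id = "RAF_ref")
  rows <- c(RAF_ref = raf_ref$truth$msa_row,
            fs$msa$seqs[grepl("^KSR3", names(fs$msa$seqs))])
  msa <- msa_from_strings(rows)
  prof <- divergence_profile(msa, "RAF_ref", setdiff(names(rows), "RAF_ref"))
  prof$pos <- prof$pos + 445L   # kinase-core row starts at B-RAF position 446
  rs <- suppressWarnings(region_summary(prof, annotate_kinase(braf)))
  expect_setequal(rs$region[1:3], c("PLOOP", "ALPHAC", "AS"))
})

test_that("donor-specific residue detection is conservative, correct and monotone", {
  # donors identical to acceptor: nothing reported
  msa0 <- msa_from_strings(c(acc = "MKVL", d1 = "MKVL", d2 = "MKVL"))
  expect_equal(nrow(donor_specific_residues(msa0, c("d1", "d2"), "acc")), 0)
  expect_error(donor_specific_residues(msa0, character(0), "acc"), "empty")

  # 4 donors A,A,A,C against acceptor G at threshold 0.75
  msa1 <- msa_from_strings(c(acc = "G", d1 = "A", d2 = "A", d3 = "A", d4 = "C"))
  hit <- donor_specific_residues(msa1, paste0("d", 1:4), "acc", 0.75)
  expect_equal(hit$donor_residue, "A")
  expect_equal(hit$acceptor_pos, 1)
  expect_equal(nrow(donor_specific_residues(msa1, paste0("d", 1:4), "acc", 0.8)), 0)

  # threshold monotonicity on a larger synthetic alignment
  fs <- make_family_set(6, noise = 0.05, seed = 17)
  raf_ref <- make_archetype(archetype_spec("RAF", seed = 1), id = "RAF_ref")
  rows <- c(RAF_ref = raf_ref$truth$msa_row,
            fs$msa$seqs[grepl("^KSR3", names(fs$msa$seqs))])
  msa <- msa_from_strings(rows)
  donors <- setdiff(names(rows), "RAF_ref")
  strict <- donor_specific_residues(msa, donors, "RAF_ref", 1.0)
  loose <- donor_specific_residues(msa, donors, "RAF_ref", 0.6)
  expect_true(all(strict$column %in% loose$column))
})

test_that("transposition reproduces the B-RAF mutant panel from KSR3 donors", {
  fs <- make_family_set(6, noise = 0.01, seed = 3)
  raf_ref <- make_archetype(archetype_spec("RAF", seed = 1), id = "BRAF_synth")
  rows <- c(BRAF_synth = raf_ref$truth$msa_row,
            fs$msa$seqs[grepl("^KSR3", names(fs$msa$seqs))])
  msa <- msa_from_strings(rows)
  hits <- donor_specific_residues(msa, setdiff(names(rows), "BRAF_synth"),
                                  "BRAF_synth")
  hits$acceptor_pos <- hits$acceptor_pos + 445L
  ann <- annotate_kinase(braf)
  cand <- transpose_mutations(hits, braf, ann)

  expect_true(all(c("L485R", "K499L", "R506S", "D587K", "L588V") %in% cand$label))
  expect_true("delV487" %in% cand$label)
  swaps <- cand[cand$kind == "segment_swap", ]
  expect_true(any(startsWith(swaps$label, "QLQA494-497>")))
  expect_match(swaps$note[startsWith(swaps$label, "QLQA494-497>")], "DIND")
  # the known-oncogenic embedded list: described vs never-described variants
  expect_false(cand$known_oncogenic[cand$label == "L485R"])
  expect_true(cand$known_oncogenic[cand$label == "K499L"])
  expect_true(cand$known_oncogenic[cand$label == "R506S"])
  expect_true(cand$known_oncogenic[cand$label == "L588V"])
  # HGVS-style notation accompanies substitutions
  expect_equal(cand$hgvs[cand$label == "L485R"], "p.Leu485Arg")

  # donor set equal to the acceptor produces no candidates
  same <- msa_from_strings(c(BRAF_synth = raf_ref$truth$msa_row,
                             d1 = raf_ref$truth$msa_row,
                             d2 = raf_ref$truth$msa_row))
  none <- donor_specific_residues(same, c("d1", "d2"), "BRAF_synth")
  expect_equal(nrow(transpose_mutations(none, braf, ann)), 0)
})

test_that("applying an emitted substitution places the donor residue at the mapped site", {
  fs <- make_family_set(5, noise = 0, seed = 8)
  raf_ref <- make_archetype(archetype_spec("RAF", seed = 1), id = "BRAF_synth")
  rows <- c(BRAF_synth = raf_ref$truth$msa_row,
            fs$msa$seqs[grepl("^KSR3", names(fs$msa$seqs))])
  msa <- msa_from_strings(rows)
  hits <- donor_specific_residues(msa, setdiff(names(rows), "BRAF_synth"),
                                  "BRAF_synth")
  hits$acceptor_pos <- hits$acceptor_pos + 445L
  cand <- transpose_mutations(hits, braf, annotate_kinase(braf))
  subs <- cand[cand$kind == "substitution", ]
  for (i in seq_len(nrow(subs))) {
    mut <- inject_mutation(braf, subs[i, ])
    expect_equal(residue_at(mut, subs$acceptor_pos[i]), subs$donor_residue[i])
    expect_equal(seq_length(mut), seq_length(braf))
  }
})

test_that("known-oncogenic lookup distinguishes described, never-described and foreign acceptors", {
  expect_true(known_oncogenic_lookup(485, "F")$flag)
  expect_false(known_oncogenic_lookup(485, "R")$flag)
  expect_false(known_oncogenic_lookup(506, "E")$flag)
  expect_true(known_oncogenic_lookup(600, "E")$flag)
  expect_false(known_oncogenic_lookup(123, "A")$flag)
  expect_true(is.na(known_oncogenic_lookup(485, "F", acceptor_id = "other")$flag))
})

test_that("landmark validation passes on the packaged references and detects drift", {
  tab <- landmark_table()
  refs <- list(braf, pl_ksr3, sk_ksr3, nv_ksr3, pl_ksr1)
  rep_ok <- validate_landmarks(tab, refs)
  expect_true(all(rep_ok$pass))

  # a uniform +2 shift fails (nearly) everything and the shift is diagnosed
  shifted <- seq_record("Pl_KSR3_synth", paste0("GG", pl_ksr3$residues))
  rep_shift <- validate_landmarks(tab, list(shifted))
  expect_lt(sum(rep_shift$pass), 3)
  expect_equal(unname(attr(rep_shift, "suggested_offsets")["Pl_KSR3_synth"]), 2)

  # a single point mismatch yields exactly one failure and no offset suggestion
  v <- strsplit(braf$residues, "")[[1]]; v[485] <- "W"
  point <- seq_record("BRAF_synth", paste(v, collapse = ""))
  rep_point <- validate_landmarks(tab, list(point))
  expect_equal(sum(!rep_point$pass), 1)
  expect_length(attr(rep_point, "suggested_offsets"), 0)

  # a configurable constant offset shifts the expected positions
  tab_off <- landmark_table(offset = c(Pl_KSR3_synth = 2))
  expect_true(all(validate_landmarks(tab_off, list(shifted))$pass))
})
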