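test_that("the B-RAF-like reference carries all canonical motifs at canonical positions", {
  ann <- annotate_kinase(braf)
  expect_equal(ann$domain_confidence, "high")
  # domain span brackets the kinase domain
  expect_lte(ann$domain[1], 464); expect_gte(ann$domain[2], 600)

  h <- ann$hits
  expect_equal(h$PLOOP$status, "canonical")
  expect_equal(h$PLOOP$key_pos, 464)          # first P-loop glycine
  expect_equal(h$VAIK$status, "canonical")
  expect_equal(h$VAIK$key_pos, 483)           # catalytic lysine
  expect_equal(h$HRD$status, "canonical")
  expect_equal(h$HRD$key_pos, 576)            # catalytic aspartate
  expect_equal(h$DFG$status, "canonical")
  expect_equal(h$DFG$key_pos, 594)
  expect_equal(h$DIMER_RKTR$status, "canonical")
  expect_equal(h$DIMER_RKTR$key_pos, 509)     # dimerization arginine
  fp <- ann$fingerprint
  expect_true(fp$has_rbd); expect_false(fp$has_cc_sam)
  expect_true(fp$has_crd)
  expect_equal(fp$erk_feedback_count, 2)
})

test_that("the KSR3 stand-in shows the degenerate pseudokinase fingerprint", {
  ann <- annotate_kinase(pl_ksr3)
  h <- ann$hits
  expect_equal(h$PLOOP$status, "degenerate")
  expect_match(h$PLOOP$variant, "^E.G..G$")   # Glu-X-Gly-X-X-Gly class
  expect_equal(h$VAIK$status, "degenerate")
  expect_equal(h$VAIK$variant, "VLIQ")
  expect_equal(h$HRD$status, "absent")
  expect_equal(h$DFG$status, "absent")
  expect_equal(h$DIMER_RKTR$status, "degenerate")
  expect_equal(h$DIMER_RKTR$variant, "SKIR")
  expect_equal(h$DIMER_RKTR$key_pos, 364)
  fp <- ann$fingerprint
  expect_false(fp$has_cc_sam); expect_false(fp$has_rbd)
  expect_true(fp$has_crd)
  expect_equal(fp$erk_feedback_count, 0)
})

test_that("the KSR1 stand-in has CC-SAM, canonical VAIK and an HKD catalytic loop", {
  ann <- annotate_kinase(pl_ksr1)
  expect_true(ann$fingerprint$has_cc_sam)
  expect_false(ann$fingerprint$has_rbd)
  expect_equal(ann$hits$VAIK$status, "canonical")
  expect_equal(ann$hits$HRD$status, "degenerate")
  expect_equal(ann$hits$HRD$variant, "HKD")
  expect_equal(ann$hits$DIMER_RKTR$key_pos, 608)
})

test_that("NtA locator finds the acidic pair of each homolog", {
  expect_equal(locate_nta(pl_ksr3)[c("start", "end", "matched")],
               list(start = 306L, end = 307L, matched = "SE"))
  expect_equal(locate_nta(sk_ksr3)[c("start", "end", "matched")],
               list(start = 293L, end = 294L, matched = "DE"))
  # all-glycine pre-beta3 window: no candidate
  poly <- seq_record("g", collapse_chars(rep("G", 50)))
  dom <- list(span = c(1L, 50L), confidence = "low", anchor = "none",
              anchor_aln = NULL)
  expect_equal(locate_nta(poly)$status, "absent")
})

test_that("C-terminal 14-3-3 sites sit at the published key serines", {
  expect_equal(locate_cterm_1433(pl_ksr3)$matched, "HSLSEP")
  expect_equal(locate_cterm_1433(pl_ksr3)$key_pos, 586)
  expect_equal(locate_cterm_1433(sk_ksr3)$matched, "HSQSEP")
  expect_equal(locate_cterm_1433(sk_ksr3)$key_pos, 572)
  expect_equal(locate_cterm_1433(nv_ksr3)$matched, "GSHSEP")
  expect_equal(locate_cterm_1433(nv_ksr3)$key_pos, 618)
  poly <- seq_record("a", collapse_chars(rep("A", 90)))
  expect_equal(locate_cterm_1433(poly)$status, "absent")
})

test_that("N-terminal 14-3-3 serine pair and C1/CRD cysteines are located", {
  nterm <- locate_nterm_1433(pl_ksr3)
  expect_equal(nterm$key_pos, 84)
  expect_equal(nterm$end, 87)
  serine_free <- seq_record("x", collapse_chars(rep(c("A", "G"), 60)))
  expect_equal(locate_nterm_1433(serine_free)$status, "absent")

  crd <- locate_c1_crd(pl_ksr3)
  expect_equal(crd$variant, "C37/C40")
  expect_equal(crd$key_pos, 37)
  cys_free <- seq_record("x", collapse_chars(rep("A", 120)))
  expect_equal(locate_c1_crd(cys_free)$status, "absent")
})

test_that("exemplar domain detection separates true domains from shuffles", {
  ex <- domain_exemplars()
  # exemplar against itself: present, maximal score
  self <- detect_domain_by_exemplar(ex$CC_SAM, ex$CC_SAM)
  expect_true(self$present)
  # KSR1 carries CC-SAM, KSR3 does not
  expect_true(detect_domain_by_exemplar(pl_ksr1, ex$CC_SAM)$present)
  expect_false(detect_domain_by_exemplar(pl_ksr3, ex$CC_SAM)$present)
  expect_true(detect_domain_by_exemplar(braf, ex$RBD)$present)
  expect_false(detect_domain_by_exemplar(pl_ksr1, ex$RBD)$present)
  # 100 shuffles of the exemplar all score below the default threshold
  res <- strsplit(ex$CC_SAM$residues, "")[[1]]
  shuffle_scores <- withr::with_seed(42, vapply(1:100, function(i) {
    shuf <- seq_record("shuf", collapse_chars(sample(res)))
    detect_domain_by_exemplar(ex$CC_SAM, shuf)$score
  }, numeric(1)))
  expect_lt(max(shuffle_scores), 100)
  expect_gt(self$score, 3 * max(shuffle_scores))
})

test_that("ERK feedback site counting obeys the strict P-x-S/T-P consensus", {
  poly <- seq_record("a", collapse_chars(rep("A", 30)))
  expect_equal(count_erk_feedback_sites(poly), 0)
  toy <- seq_record("t", "AAPVSPAAPGTPAA")
  expect_equal(count_erk_feedback_sites(toy), 2)
  # sites flanking a domain are counted, sites inside are not
  expect_equal(count_erk_feedback_sites(toy, domain_span = c(6, 8)), 2)
  expect_equal(count_erk_feedback_sites(toy, domain_span = c(1, 14)), 0)
})

test_that("random sequences fall back to a low-confidence whole-sequence domain", {
  rnd <- seq_record("r", collapse_chars(sample_aa(50, seed = 9)))
  dom <- locate_kinase_domain(rnd)
  expect_equal(dom$confidence, "low")
  expect_equal(dom$span, c(1L, 50L))
})

test_that("every reported hit matches its sequence slice and scans are append-stable", {
  for (rec in list(braf, pl_ksr3, pl_ksr1)) {
    ann <- annotate_kinase(rec)
    for (h in ann$hits) {
      if (is.na(h$start)) next
      expect_equal(substr(rec$residues, h$start, h$end), h$matched)
    }
    # appending residues after the domain span does not move catalytic hits
    extended <- seq_record(rec$id, paste0(rec$residues,
                                          collapse_chars(rep("A", 40))))
    dom2 <- locate_kinase_domain(extended)
    for (id in c("PLOOP", "VAIK", "HRD", "DFG", "DIMER_RKTR")) {
      h1 <- ann$hits[[id]]
      h2 <- scan_motif(extended, motif_defs()[[id]], dom2)
      expect_equal(h2$status, h1$status, info = paste(rec$id, id))
      expect_equal(h2$start, h1$start, info = paste(rec$id, id))
    }
  }
})

test_that("annotation reports are written as TSV and JSON", {
  ann <- annotate_kinase(pl_ksr3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  tab <- write_annotation(ann, tsv = tsv, json = js)
  expect_true(file.exists(tsv)); expect_true(file.exists(js))
  expect_equal(nrow(read.delim(tsv)), length(ann$hits))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$id, "Pl_KSR3_synth")
  expect_false(parsed$fingerprint$dfg_present)
})
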