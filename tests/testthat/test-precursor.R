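test_that("signal cleavage is recovered on planted signals", {
  set.seed(31)
  for (k in 1:20) {
    sig <- venomtx:::draw_signal_peptide()
    downstream <- paste0("FYEE", random_protein(30))
    cut <- predict_signal_peptide(paste0(sig, downstream))
    expect_equal(cut, nchar(sig))
  }
})

test_that("sequences without a hydrophobic core yield no signal call", {
  expect_true(is.na(predict_signal_peptide(paste0("M", strrep("S", 40)))))
  expect_warning(res <- predict_signal_peptide("MKLV"), "shorter")
  expect_true(is.na(res))
})

test_that("signal-cut recovery rates hold over many generator precursors", {
  set.seed(32)
  n <- 500
  exact <- 0L; near <- 0L
  for (k in seq_len(n)) {
    g <- generate_precursor_cdna("C1-C2-C3C4-C5-C6",
                                 with_propeptide = k %% 2 == 0,
                                 amidation = "none")
    true_cut <- nchar(g$truth$signal)
    cut <- predict_signal_peptide(g$truth$protein)
    if (!is.na(cut)) {
      exact <- exact + (cut == true_cut)
      near <- near + (abs(cut - true_cut) <= 2)
    }
  }
  expect_gte(exact / n, 0.80)
  expect_gte(near / n, 0.95)
})

test_that("quadruplet-motif cut follows the acidic-P2P4 last-R rule", {
  expect_equal(find_pqm_cut("AEEARGDCLLW"), 5L)
  expect_true(is.na(find_pqm_cut("AEEAGGDCLLW")))   # R lost by mutation
  expect_true(is.na(find_pqm_cut("AAASGDCLLW")))    # no R before first C
  # latest qualifying R before the first cysteine wins
  expect_equal(find_pqm_cut("AEEARGDEDARSSCLLW"), 11L)
  # R beyond the first cysteine never cuts
  expect_true(is.na(find_pqm_cut("AAACDDERLLW")))
  # D acceptance is switchable
  expect_equal(find_pqm_cut("ADDARGDCLLW"), 5L)
  expect_true(is.na(find_pqm_cut("ADDARGDCLLW", acidic = "E")))
})

test_that("amidation tails are stripped exactly and idempotently", {
  expect_equal(detect_amidation("GSCKCNLILGR"),
               list(amidated = TRUE, trimmed_mature = "GSCKCNLIL"))
  expect_equal(detect_amidation("AWDGK"),
               list(amidated = TRUE, trimmed_mature = "AWD"))
  expect_equal(detect_amidation("AWDKKL"),
               list(amidated = FALSE, trimmed_mature = "AWDKKL"))
  expect_equal(detect_amidation("AWDGKR"),
               list(amidated = TRUE, trimmed_mature = "AWD"))
  set.seed(33)
  for (k in 1:30) {
    s <- paste0(venomtx:::mature_from_scaffold("C1-C2-C3-C4"),
                sample(c("", "G", "GK", "GR"), 1))
    once <- detect_amidation(s)
    twice <- detect_amidation(once$trimmed_mature)
    expect_false(twice$amidated)
    expect_equal(twice$trimmed_mature, once$trimmed_mature)
  }
})

test_that("completeness flags follow start/stop evidence", {
  expect_equal(flag_partial(TRUE, TRUE, TRUE), "full_length")
  expect_equal(flag_partial(TRUE, FALSE, TRUE), "c_truncated")
  expect_equal(flag_partial(FALSE, TRUE, FALSE, first_cys_pos = 30),
               "n_truncated")
  expect_equal(flag_partial(FALSE, TRUE, FALSE, first_cys_pos = 4),
               "mature_only")
})

test_that("segmentation tiles full-length precursors exactly", {
  set.seed(34)
  for (scaffold in c("C1-C2-C3C4-C5-C6", "C1-C2-C3C4-C5-C6-C7-C8",
                     "C1-C2")) {
    for (ami in c("none", "G", "GK", "GR")) {
      g <- generate_precursor_cdna(scaffold, with_propeptide = TRUE,
                                   amidation = ami)
      seg <- segment_precursor(g$truth$protein)
      expect_equal(seg$completeness, "full_length")
      expect_equal(seg$signal, g$truth$signal)
      expect_equal(seg$propeptide, g$truth$propeptide)
      expect_equal(seg$mature, g$truth$mature)
      expect_equal(seg$amidated, ami != "none")
      tail_len <- nchar(g$truth$amidation_tail)
      expect_equal(nchar(seg$signal) + nchar(seg$propeptide) +
                     nchar(seg$mature) + tail_len,
                   nchar(g$truth$protein))
    }
  }
})

test_that("an external signal cleavage site overrides the heuristic", {
  set.seed(35)
  g <- generate_precursor_cdna("C1-C2-C3-C4", TRUE, "none")
  seg <- segment_precursor(g$truth$protein,
                           signal_override = nchar(g$truth$signal))
  expect_equal(seg$signal, g$truth$signal)
})

test_that("premature stops and readthrough are flagged within a contig", {
  modal <- "MKLLVAEEARGDCLLWDDCK"
  short <- substr(modal, 1, 12)
  long <- paste0(modal, "RNQWE")
  notes <- flag_stop_anomalies(c(modal, modal, modal, short, long))
  expect_equal(notes, c("", "", "", "premature_stop", "stop_readthrough"))
  expect_equal(flag_stop_anomalies(character(0)), character(0))
})
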