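test_that("modified peptide masses match hand-checked values", {
  # free glycine, C2H5NO2
  expect_equal(peptide_mass("G"), 75.067, tolerance = 1e-4)
  expect_equal(peptide_mass("G", scale = "monoisotopic"), 75.03203,
               tolerance = 1e-4)
  # the two Edman-determined matures, 3 disulfides + amidation each
  expect_equal(peptide_mass(HP1_MATURE, 3, TRUE), 4883.39, tolerance = 0.1)
  expect_equal(peptide_mass(HP2_MATURE, 3, TRUE), 4560.26, tolerance = 0.1)
})

test_that("mass validation rejects impossible inputs", {
  expect_error(peptide_mass("ABZ"), "nonstandard")
  expect_error(peptide_mass("ACDEF", n_disulfides = 1), "cysteines")
})

test_that("modification delta composes hydrogens and amidation", {
  expect_equal(modification_delta(3, TRUE), -7.0324, tolerance = 5e-3)
  expect_equal(round(abs(modification_delta(3, TRUE))), 7)
  expect_equal(modification_delta(0, FALSE), 0)
  expect_equal(modification_delta(1, FALSE), -2.01588, tolerance = 1e-3)
})

test_that("mass identities hold across random peptides", {
  set.seed(61)
  for (k in 1:20) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    # additivity for unmodified peptides
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.01528,
                 tolerance = 1e-6)
    # average exceeds monoisotopic, increasingly with length
    expect_gt(peptide_mass(a), peptide_mass(a, scale = "monoisotopic"))
  }
  short <- random_protein(5); long <- paste0(short, random_protein(40))
  gap_s <- peptide_mass(short) - peptide_mass(short, scale = "monoisotopic")
  gap_l <- peptide_mass(long) - peptide_mass(long, scale = "monoisotopic")
  expect_gt(gap_l, gap_s)
})

test_that("peaks match under both protonation interpretations", {
  hp1 <- peptide_mass(HP1_MATURE, 3, TRUE)
  cand <- data.frame(name = "HptTx-208", mass = hp1)
  peaks <- data.frame(mz = c(4884.7012, 2442.8003), intensity = c(100, 40))
  m <- match_peaks(peaks, cand, tolerance_da = 2)
  m1 <- m[m$peak_mz == 4884.7012, ]
  expect_equal(m1$charge_interpretation, "M+H")
  expect_lt(abs(m1$delta_da), 1)
  m2 <- m[m$peak_mz == 2442.8003, ]
  expect_equal(m2$charge_interpretation, "M+2H_over_2")
  expect_true(all(abs(m$delta_da) <= 2))

  expect_equal(nrow(match_peaks(peaks, cand[0, ], 2)), 0L)
})

test_that("the two charge forms of one mass reconstruct identically", {
  set.seed(62)
  for (M in runif(10, 1500, 9000)) {
    mz1 <- M + 1.00728
    mz2 <- M / 2 + 1.00728
    m_from_1 <- mz1 - 1.00728
    m_from_2 <- 2 * mz2 - 2 * 1.00728
    expect_equal(m_from_1, m_from_2, tolerance = 1e-6 / M)
    peaks <- data.frame(mz = c(mz1, mz2), intensity = c(1, 1))
    res <- match_peaks(peaks, data.frame(name = "x", mass = M), 0.01)
    expect_equal(nrow(res), 2L)
    expect_equal(sort(unique(res$charge_interpretation)),
                 c("M+2H_over_2", "M+H"))
  }
})

test_that("Edman prefixes anchor purified toxins to their clones", {
  db <- data.frame(name = c("HptTx-208", "HptTx-133"),
                   mature = c(HP1_MATURE, HP2_MATURE),
                   amidated = c(TRUE, TRUE), stringsAsFactors = FALSE)
  hit <- identify_by_nterm("ADSGGDAGGDAG", db, observed_mw = 4883.7)
  expect_equal(hit$name, "HptTx-208")
  expect_true(hit$mw_check_passed)
  expect_equal(hit$prefix_mismatches, 0L)

  expect_equal(nrow(identify_by_nterm("WWWWWWW", db, 4000)), 0L)

  # two paralogs sharing the prefix rank by mass error
  db2 <- rbind(db, data.frame(name = "HptTx-208b",
                              mature = paste0(HP1_MATURE, "AAA"),
                              amidated = TRUE))
  both <- identify_by_nterm("ADSGGDAGGDAG", db2, observed_mw = 4883.7)
  expect_equal(both$name, c("HptTx-208", "HptTx-208b"))
  expect_true(abs(both$delta_da[1]) < abs(both$delta_da[2]))

  # one-mismatch fallback only when no exact match exists
  near <- sub("^A", "S", "ADSGGDAGGDAG")
  h2 <- identify_by_nterm(near, db, observed_mw = 4883.7)
  expect_equal(h2$name, "HptTx-208")
  expect_equal(h2$prefix_mismatches, 1L)
})

test_that("molecular-weight histograms bin inside the acquisition window", {
  h <- mw_distribution(c(4000, 4010), bin_width = 500)
  expect_equal(sum(h$count), 2L)
  expect_equal(h$count[h$bin_lo == 4000], 2L)

  h0 <- mw_distribution(numeric(0))
  expect_true(all(h0$count == 0L))

  set.seed(63)
  masses <- runif(200, 500, 11000)
  h2 <- mw_distribution(masses)
  expect_equal(sum(h2$count), sum(masses >= 1000 & masses <= 10000))
})
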