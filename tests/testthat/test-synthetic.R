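test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- generator_config(seed = 71, n_transcripts = 60)
  a <- generate_library(cfg)
  b <- generate_library(cfg)
  expect_identical(a$ests, b$ests)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$peaklists, b$peaklists)
})

test_that("precursor cDNAs round-trip through the analysis rules", {
  set.seed(72)
  for (scaffold in c("C1-C2-C3C4-C5-C6", "C1-C2",
                     "C1-C2-C3C4-C5-C6C7-C8-C9-C10")) {
    g <- generate_precursor_cdna(scaffold, TRUE, "GR")
    expect_equal(extract_framework(g$truth$mature)$notation, scaffold)
    full <- paste0(g$truth$mature, g$truth$amidation_tail)
    ami <- detect_amidation(full)
    expect_true(ami$amidated)
    expect_equal(ami$trimmed_mature, g$truth$mature)
    # the emitted cDNA translates back to the planted precursor
    orfs <- translate_orfs(g$cdna, min_orf_aa = 20)
    expect_true(g$truth$protein %in% orfs$protein)
  }
  g2 <- generate_precursor_cdna("C1-C2-C3-C4", with_propeptide = FALSE,
                                amidation = "none")
  downstream <- sub(g2$truth$signal, "", g2$truth$protein, fixed = TRUE)
  expect_true(is.na(find_pqm_cut(downstream)))
})

test_that("category proportions are realized within binomial bounds", {
  lib <- generate_library(generator_config(seed = 73, n_transcripts = 1000))
  counts <- table(lib$manifest$category)
  for (cat in c("toxin", "cellular", "no_match")) {
    p <- generator_config()$category_proportions[[cat]]
    bound <- 2.58 * sqrt(1000 * p * (1 - p))   # 99% binomial band
    expect_lt(abs(counts[[cat]] - 1000 * p), bound + 1)
  }
  expect_equal(sum(counts), 1000L)
})

test_that("the manifest is internally consistent with its sequences", {
  lib <- generate_library(generator_config(seed = 74, n_transcripts = 150))
  m <- lib$manifest
  expect_equal(sort(m$id), sort(lib$ests$id))
  expect_false(any(duplicated(m$id)))
  tox <- m[m$category == "toxin" & m$anomalies == "", ]
  for (i in seq_len(nrow(tox))) {
    expect_equal(extract_framework(tox$mature[i])$notation, tox$notation[i])
    n_cys <- extract_framework(tox$mature[i])$n_cys
    expect_equal(tox$mature_mass[i],
                 peptide_mass(tox$mature[i], n_cys %/% 2, tox$amidated[i]))
    stem <- paste0(tox$signal[i], tox$propeptide[i], tox$mature[i])
    expect_true(startsWith(tox$protein[i], stem))
    tail <- substring(tox$protein[i], nchar(stem) + 1)
    expect_true(tail %in% c("", "G", "GK", "GR"))
    expect_equal(tox$amidated[i], nzchar(tail))
  }
})

test_that("zero fragmentation leaves every toxin transcript full length", {
  lib <- generate_library(generator_config(
    seed = 75, n_transcripts = 120, fragmentation_prob = 0,
    transcriptome_prob = 0,
    mutation_rates = list(point = 0, cys_loss = 0, stop_gain = 0,
                          stop_readthrough = 0)))
  m <- lib$manifest
  expect_true(all(m$anomalies == ""))
  tox <- m[m$category == "toxin", ]
  expect_true(all(substr(tox$protein, 1, 1) == "M"))
  expect_true(all(lib$ests$source == "library"))
  # every planted family is represented
  expect_setequal(unique(tox$family), LETTERS[1:13])
})

test_that("peak lists carry the planted masses in both charge forms", {
  lib <- generate_library(generator_config(seed = 76, n_transcripts = 200))
  masses <- unique(round(lib$manifest$mature_mass[
    lib$manifest$category == "toxin" & lib$manifest$anomalies == ""], 4))
  masses <- masses[!is.na(masses) & masses >= 1000 & masses <= 10000]
  all_mz <- unlist(lapply(lib$peaklists, `[[`, "mz"))
  singly <- round(masses + 1.00728, 4)
  expect_true(all(singly %in% round(all_mz, 4)))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(category_proportions =
                                  c(toxin = 0.6, cellular = 0.3,
                                    no_match = 0.3)), "sum to 1")
  expect_error(generator_config(mutation_rates = list(point = -0.1,
                                                      cys_loss = 0,
                                                      stop_gain = 0,
                                                      stop_readthrough = 0)),
               "rates")
})
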