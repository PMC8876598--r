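test_that("six-frame ORF finding handles minimal and reverse cases", {
  o <- translate_orfs("ATGAAATGA", min_orf_aa = 1)
  met <- o[o$has_start, ]
  expect_true(any(met$frame == 1 & met$protein == "MK" & met$has_stop))

  rc <- revcomp("ATGAAATGA")
  o2 <- translate_orfs(rc, min_orf_aa = 1)
  expect_true(any(o2$frame < 0 & o2$protein == "MK" & o2$has_stop))
})

test_that("ORF set matches a brute-force six-frame scanner", {
  skip_if_not_installed("seqinr")
  set.seed(7)
  for (len in c(300, 1000, 3000)) {
    s <- random_dna(len)
    mine <- translate_orfs(s, min_orf_aa = 25)
    mine_keys <- sort(unique(paste(mine$frame, mine$aa_start, mine$protein)))
    expect_equal(mine_keys, orf_oracle(s, 25))
  }
})

test_that("ORFs spanning undetermined bases are discarded", {
  s <- paste0("ATG", strrep("GCA", 30), "NAT", strrep("GCA", 10), "TGA")
  o <- translate_orfs(s, min_orf_aa = 10)
  expect_false(any(grepl("X", o$protein)))
})

test_that("local alignment equals an exhaustive DP oracle on small pairs", {
  subst <- venomtx:::get_subst_matrix("BLOSUM62")
  set.seed(11)
  aas <- rownames(subst)[1:20]
  for (k in 1:8) {
    a <- paste(sample(aas, sample(10:30, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(10:30, 1), TRUE), collapse = "")
    mine <- local_align(a, b)
    expect_equal(mine$score, sw_score_oracle(a, b, subst))
    expect_equal(mine$score, local_align(b, a)$score)  # symmetry
  }
})

test_that("identical sequences align at 100 percent identity", {
  s <- paste(rep("ACDEFGHIKL", 5), collapse = "")
  r <- local_align(s, s)
  expect_equal(r$identity_pct, 100)
  expect_error(local_align(s, s, matrix = "NOSUCH"), "unknown")
})

test_that("classification recovers categories and respects the cutoff", {
  refs <- load_reference_set()
  set.seed(5)
  tox_ref <- refs[refs$id == "TOXFAM_C", ]
  hk_ref <- refs[refs$category == "cellular", ][1, ]

  # EST encoding a toxin exemplar verbatim
  tox_est <- est_records(data.frame(
    id = "t1",
    seq = paste0("ATG", venomtx:::reverse_translate(tox_ref$seq), "TGA")),
    "library")
  ann <- classify_ests(tox_est, refs, min_orf_aa = 15)
  expect_equal(ann$category, "toxin_like")
  expect_equal(ann$best_hit_id, "TOXFAM_C")
  expect_equal(ann$identity_pct, 100)
  expect_lte(ann$evalue, 1e-5)

  # EST encoding a housekeeping fragment
  frag <- substr(hk_ref$seq, 20, 90)
  hk_est <- est_records(data.frame(
    id = "h1", seq = paste0("ATG", venomtx:::reverse_translate(frag), "TGA")),
    "library")
  expect_equal(classify_ests(hk_est, refs, min_orf_aa = 15)$category,
               "cellular")

  # uniform-random codons stay below the cutoff
  rnd <- est_records(data.frame(id = paste0("r", 1:10),
                                seq = vapply(rep(402, 10), random_dna, "")),
                     "library")
  ann_r <- classify_ests(rnd, refs)
  expect_true(all(ann_r$category == "no_match"))
})

test_that("classification is reference-closed under added references", {
  refs <- load_reference_set()
  set.seed(6)
  ests <- est_records(data.frame(
    id = c("t1", "r1"),
    seq = c(paste0("ATG", venomtx:::reverse_translate(
      refs$seq[refs$id == "TOXFAM_K"]), "TGA"),
      random_dna(400))), "library")
  before <- classify_ests(ests, refs)
  more <- rbind(refs, data.frame(id = "EXTRA", seq = random_protein(80),
                                 category = "cellular", provenance = "x"))
  after <- classify_ests(ests, more)
  hit_before <- before$category != "no_match"
  expect_true(all(after$category[hit_before] != "no_match"))
})

test_that("toxin names compose the partial/transcriptome suffixes in order", {
  expect_equal(name_toxin(208, FALSE, FALSE, "HptTx"), "HptTx-208")
  expect_equal(name_toxin(1151, TRUE, TRUE, "HptTx"), "HptTx-1151-P-T")
  expect_equal(name_toxin(5, FALSE, TRUE, "HptTx"), "HptTx-5-T")
})
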