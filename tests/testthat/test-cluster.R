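test_that("identical copies form one contig, unalignable sequences none", {
  set.seed(3)
  base <- random_dna(400)
  five <- est_records(data.frame(id = paste0("e", 1:5),
                                 seq = rep(base, 5)), "library")
  cs <- cluster_ests(five)
  expect_length(cs$clusters, 1L)
  expect_equal(cs$table$size, 5L)
  expect_equal(cs$table$bin, "2-5")

  rnd <- est_records(data.frame(id = paste0("r", 1:3),
                                seq = vapply(rep(350, 3), random_dna, "")),
                     "library")
  cs2 <- cluster_ests(rnd)
  expect_length(cs2$clusters, 3L)
  expect_equal(cs2$n_singletons, 3L)
})

test_that("chained overlaps reproduce the brute-force single-linkage", {
  skip_if_not_installed("igraph")
  set.seed(9)
  # three genes; per gene, 5'-shifted fragments chained by ~80% overlaps,
  # plus lightly mutated full copies and unrelated singletons
  seqs <- character(0)
  for (g in 1:3) {
    gene <- random_dna(500)
    for (off in c(0, 100, 200)) {
      seqs <- c(seqs, substring(gene, off + 1, off + 300))
    }
    mut <- venomtx:::apply_point_mutations(gene, 0.02)
    seqs <- c(seqs, mut)
  }
  seqs <- c(seqs, vapply(rep(300, 4), random_dna, ""))
  seqs <- sample(seqs)
  ests <- est_records(data.frame(id = sprintf("q%02d", seq_along(seqs)),
                                 seq = seqs), "library")
  cs <- cluster_ests(ests, min_overlap_nt = 100, min_identity_pct = 95)
  mine <- integer(nrow(ests))
  for (k in seq_along(cs$clusters)) {
    mine[match(cs$clusters[[k]]$member_est_ids, ests$id)] <- k
  }
  oracle <- cluster_oracle(ests$seq, 100, 95)
  expect_true(same_partition(mine, oracle))
})

test_that("clusters partition the input and bins balance", {
  lib <- generate_library(generator_config(seed = 21, n_transcripts = 120))
  cs <- cluster_ests(lib$ests)
  members <- unlist(lapply(cs$clusters, `[[`, "member_est_ids"),
                    use.names = FALSE)
  expect_equal(sort(members), sort(lib$ests$id))      # disjoint cover
  expect_equal(sum(cs$bins$n_ests), nrow(lib$ests))
  expect_equal(sum(cs$bins$n_clusters), length(cs$clusters))
  expect_equal(cs$n_singletons + cs$n_contigs, length(cs$clusters))
})

test_that("raising the identity threshold only refines the partition", {
  lib <- generate_library(generator_config(seed = 22, n_transcripts = 100))
  loose <- cluster_ests(lib$ests, min_identity_pct = 90)
  tight <- cluster_ests(lib$ests, min_identity_pct = 99)
  of_loose <- rep(names(loose$clusters),
                  lengths(lapply(loose$clusters, `[[`, "member_est_ids")))
  names(of_loose) <- unlist(lapply(loose$clusters, `[[`, "member_est_ids"))
  for (cl in tight$clusters) {
    expect_length(unique(of_loose[cl$member_est_ids]), 1L)
  }
  expect_gte(length(tight$clusters), length(loose$clusters))
})

test_that("unique gene and protein counts distinguish synonymy", {
  base <- "ATGGCTAGCGATAAACTGCTGCTGGAA"
  ests <- est_records(data.frame(id = paste0("e", 1:4),
                                 seq = rep(paste0(base, strrep("A", 12)), 4)),
                      "library")
  prots <- stats::setNames(rep("MASDKLLE", 4), ests$id)
  cs <- cluster_ests(ests, min_overlap_nt = 20, proteins = prots)
  expect_equal(unname(count_unique(cs$clusters[[1]])), c(1L, 1L))

  # one synonymous substitution: two genes, one protein
  syn <- sub("CTGCTGGAA", "CTGTTGGAA", base)   # CTG->TTG, both leucine
  ests2 <- est_records(data.frame(id = c("a", "b"),
                                  seq = c(paste0(base, strrep("A", 12)),
                                          paste0(syn, strrep("A", 12)))),
                       "library")
  cs2 <- cluster_ests(ests2, min_overlap_nt = 20, min_identity_pct = 90,
                      proteins = stats::setNames(rep("MASDKLLE", 2),
                                                 c("a", "b")))
  expect_length(cs2$clusters, 1L)
  expect_equal(unname(count_unique(cs2$clusters[[1]])), c(2L, 1L))
})

test_that("unique counts recover the generator's planted synonymy", {
  lib <- generate_library(generator_config(
    seed = 23, n_transcripts = 150,
    category_proportions = c(toxin = 1, cellular = 0, no_match = 0),
    fragmentation_prob = 0, transcriptome_prob = 0))
  cs <- cluster_ests(lib$ests)
  m <- lib$manifest
  for (cl in cs$clusters) {
    rows <- m[match(cl$member_est_ids, m$id), ]
    expect_equal(length(cl$unique_gene_seqs),
                 length(unique(trim_polya(lib$ests$seq[
                   match(cl$member_est_ids, lib$ests$id)]))))
    # distinct precursor proteins planted in this cluster
    expect_equal(length(unique(rows$protein)) >= 1, TRUE)
  }
})

test_that("category percentages reproduce printed-style arithmetic", {
  s <- summarize_categories(c(toxin_like = 531, cellular = 255,
                              no_match = 205))
  expect_equal(s$pct[s$category == "toxin_like"], 53.58)
  expect_equal(s$pct[s$category == "cellular"], 25.73)
  expect_equal(s$pct[s$category == "no_match"], 20.69)

  s1 <- summarize_categories(c(a = 1, b = 0, c = 0))
  expect_equal(s1$pct, c(100, 0, 0))

  set.seed(4)
  for (k in 1:20) {
    counts <- sample(0:500, 3)
    if (sum(counts) == 0) next
    expect_lt(abs(sum(summarize_categories(
      stats::setNames(counts, c("x", "y", "z")))$pct) - 100), 0.021)
  }
  expect_equal(nrow(summarize_categories(integer(0))), 0L)
})
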