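# Independent reference implementations used to cross-check the package's
# alignment, ORF and clustering paths on small instances.

# mature toxin sequences determined by Edman degradation + mass matching
HP1_MATURE <- "ADSGGDAGGDAGADDEGSCKWMFQSCEPPAKCCDGWTCYKGRCNLIL"
HP2_MATURE <- "DDDKKECIGHMGWCAWTDGECCEGYRCKLWCRKIIDWL"

# Smith-Waterman with affine gaps (Gotoh), plain dynamic programming.
# A gap of length k costs open + k * ext.
sw_score_oracle <- function(a, b, subst, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - (open + ext), Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - (open + ext), Iy[i, j - 1] - ext)
      s <- subst[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                Iy[i - 1, j - 1]))
      best <- max(best, M[i, j])
    }
  }
  best
}

# brute-force six-frame ORF scan built on seqinr's translation
orf_oracle <- function(seq, min_orf_aa) {
  stopifnot(requireNamespace("seqinr", quietly = TRUE))
  out <- list()
  chars <- tolower(strsplit(seq, "")[[1]])
  for (fr in 0:2) {
    for (sens in c("F", "R")) {
      aa <- paste(seqinr::translate(chars, frame = fr, sens = sens),
                  collapse = "")
      res <- strsplit(aa, "")[[1]]
      stops <- which(res == "*")
      starts <- c(1L, stops + 1L)
      ends <- c(stops - 1L, length(res))
      for (k in seq_along(starts)) {
        a <- starts[k]; b <- ends[k]
        if (b < a) next
        cand <- integer(0)
        if (a == 1L) cand <- a
        seg <- res[a:b]
        m1 <- which(seg == "M")[1]
        if (!is.na(m1)) cand <- union(cand, a + m1 - 1L)
        if (a != 1L && is.na(m1)) next
        for (st in cand) {
          prot <- paste(res[st:b], collapse = "")
          if (nchar(prot) < min_orf_aa) next
          if (grepl("X", prot, fixed = TRUE)) next
          frame <- if (sens == "F") fr + 1L else -(fr + 1L)
          out[[length(out) + 1L]] <- paste(frame, st, prot)
        }
      }
    }
  }
  sort(unique(unlist(out)))
}

# single-linkage clustering oracle: align every pair (no prefilter, no
# duplicate collapsing) and take connected components with igraph
cluster_oracle <- function(seqs, min_overlap_nt, min_identity_pct) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  n <- length(seqs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  edges <- integer(0)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (seqs[i] == seqs[j]) {
        edges <- c(edges, i, j); next
      }
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[i]), Biostrings::DNAString(seqs[j]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      if (Biostrings::nchar(aln) >= min_overlap_nt &&
            Biostrings::pid(aln) >= min_identity_pct) {
        edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# do two labelings induce the same partition of 1..n?
same_partition <- function(a, b) {
  identical(as.integer(match(a, unique(a))),
            as.integer(match(b, unique(b))))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
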