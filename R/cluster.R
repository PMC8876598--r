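# Contig/singleton clustering of ESTs by overlap identity, size-bin
# bookkeeping and unique gene / unique protein counting.

# union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}
uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

CLUSTER_SIZE_BINS <- c("singleton", "2-5", "6-10", "11-15", "16-30", ">30")

#' Size-bin label for a cluster
#' @param size Number of member ESTs.
#' @return One of `"singleton"`, `"2-5"`, `"6-10"`, `"11-15"`, `"16-30"`,
#'   `">30"` (bin edges inclusive).
#' @export
cluster_size_bin <- function(size) {
  cut(size, breaks = c(0, 1, 5, 10, 15, 30, Inf),
      labels = CLUSTER_SIZE_BINS)
}

#' Cluster ESTs into contigs and singletons
#'
#' Single-linkage clustering under the pairwise relation "the best local
#' nucleotide alignment spans at least `min_overlap_nt` columns at or above
#' `min_identity_pct` identity". The transitive closure is computed with a
#' union-find structure; identical sequences are collapsed before alignment
#' and candidate pairs are pre-screened by a shared exact k-mer (a pair that
#' can reach 95% identity over 100 nt shares many exact words, so the screen
#' only removes hopeless pairs).
#'
#' @param ests EST table ([est_records()]); typically one annotation category
#'   at a time.
#' @param min_overlap_nt Minimum alignment span (columns) to link two ESTs.
#' @param min_identity_pct Minimum percent identity over the aligned columns.
#' @param proteins Optional named character vector (names = EST ids) of the
#'   predicted precursor protein per EST, used for unique-protein counting.
#' @param prefilter_k Word size of the shared k-mer screen.
#' @return An object of class `cluster_set`: a list with `clusters` (list of
#'   contigs, each with `id`, `member_est_ids`, `consensus_nt`,
#'   `unique_gene_seqs`, `unique_protein_seqs`), `table` (one row per
#'   cluster) and `bins` (per-size-bin counts of contigs, ESTs, unique genes
#'   and unique proteins).
#' @export
cluster_ests <- function(ests, min_overlap_nt = 100, min_identity_pct = 95,
                         proteins = NULL, prefilter_k = 15) {
  n <- nrow(ests)
  parent <- uf_new(n)
  if (n > 1) {
    # collapse exact duplicates first
    uniq <- !duplicated(ests$seq)
    first_idx <- match(ests$seq, ests$seq[uniq])
    rep_rows <- which(uniq)
    for (i in which(!uniq)) {
      parent <- uf_union(parent, i, rep_rows[first_idx[i]])
    }
    u <- length(rep_rows)
    if (u > 1) {
      useqs <- ests$seq[rep_rows]
      # candidate pairs sharing an informative exact k-mer; k-mers are taken
      # from poly-A-trimmed sequence and low-complexity words are skipped so
      # that shared homopolymer runs do not link everything to everything
      kmers <- lapply(trim_polya(useqs), function(s) {
        km <- .kmer_set(s, prefilter_k)
        km[vapply(km, function(w)
          length(unique(strsplit(w, "", fixed = TRUE)[[1]])) >= 3, logical(1))]
      })
      km2seq <- new.env(hash = TRUE, parent = emptyenv())
      for (a in seq_len(u)) {
        for (kmer in kmers[[a]]) {
          km2seq[[kmer]] <- c(km2seq[[kmer]], a)
        }
      }
      hitsets <- as.list(km2seq)
      hitsets <- hitsets[lengths(hitsets) > 1]
      hitsets <- lapply(hitsets, function(h) sort(unique(h)))
      hitsets <- hitsets[!duplicated(vapply(hitsets, paste,
                                            character(1), collapse = " "))]
      if (length(hitsets)) {
        pair_mat <- unique(do.call(rbind, lapply(hitsets, function(h)
          t(utils::combn(h, 2)))))
        i1 <- pair_mat[, 1]; i2 <- pair_mat[, 2]
        # skip pairs already linked via duplicates (cannot happen here) and
        # align the rest
        mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                        mismatch = -3)
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAStringSet(useqs[i1]),
          Biostrings::DNAStringSet(useqs[i2]),
          type = "local", substitutionMatrix = mat,
          gapOpening = 5, gapExtension = 2)
        widths <- Biostrings::nchar(aln)
        pids <- Biostrings::pid(aln)
        link <- widths >= min_overlap_nt & pids >= min_identity_pct
        for (p in which(link)) {
          parent <- uf_union(parent, rep_rows[i1[p]], rep_rows[i2[p]])
        }
      }
    }
  }
  comp <- if (n) uf_components(parent) else integer(0)
  groups <- split(seq_len(n), comp)
  clusters <- lapply(groups, function(idx) {
    ids <- ests$id[idx]
    seqs <- ests$seq[idx]
    genes <- unique(trim_polya(seqs))
    prots <- if (!is.null(proteins)) {
      unique(stats::na.omit(unname(proteins[ids])))
    } else character(0)
    list(id = paste0("CL_", sort(ids)[1]),
         member_est_ids = ids,
         consensus_nt = seqs[which.max(nchar(seqs))],  # longest member
         unique_gene_seqs = genes,
         unique_protein_seqs = prots)
  })
  names(clusters) <- vapply(clusters, `[[`, character(1), "id")
  clusters <- clusters[order(names(clusters))]
  tab <- data.frame(
    cluster_id = names(clusters),
    size = vapply(clusters, function(cl) length(cl$member_est_ids), 1L),
    n_unique_genes = vapply(clusters, function(cl)
      length(cl$unique_gene_seqs), 1L),
    n_unique_proteins = vapply(clusters, function(cl)
      length(cl$unique_protein_seqs), 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$bin <- as.character(cluster_size_bin(tab$size))
  bins <- do.call(rbind, lapply(CLUSTER_SIZE_BINS, function(b) {
    sel <- tab$bin == b
    data.frame(bin = b, n_clusters = sum(sel), n_ests = sum(tab$size[sel]),
               n_unique_genes = sum(tab$n_unique_genes[sel]),
               n_unique_proteins = sum(tab$n_unique_proteins[sel]),
               stringsAsFactors = FALSE)
  }))
  structure(list(clusters = clusters, table = tab, bins = bins,
                 n_ests = n,
                 n_singletons = sum(tab$size == 1),
                 n_contigs = sum(tab$size > 1)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", x$n_ests, "ESTs in",
      length(x$clusters), "clusters (",
      x$n_singletons, "singletons,", x$n_contigs, "contigs )\n")
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Count unique genes and proteins in a contig
#'
#' Unique genes are distinct member nucleotide sequences after poly-A
#' trimming (so synonymous variants count separately); unique proteins are
#' distinct predicted precursor protein strings (synonymous variants
#' collapse).
#'
#' @param contig One element of `cluster_set$clusters`.
#' @return Named integer vector `c(n_unique_genes, n_unique_proteins)`.
#' @export
count_unique <- function(contig) {
  c(n_unique_genes = length(contig$unique_gene_seqs),
    n_unique_proteins = length(contig$unique_protein_seqs))
}

#' Per-category counts and percentages
#'
#' @param x Either an annotation data frame (from [classify_ests()]) or a
#'   named integer vector of category counts.
#' @return Data frame with `category`, `n` and `pct` (percent of total,
#'   rounded to 2 decimals). Percentages sum to 100 up to rounding. An empty
#'   input yields a zero-row summary rather than dividing by zero.
#' @export
summarize_categories <- function(x) {
  counts <- if (is.data.frame(x)) {
    tapply(rep(1L, nrow(x)), x$category, sum)
  } else {
    x
  }
  if (is.null(counts) || !length(counts) || sum(counts) == 0) {
    return(data.frame(category = character(), n = integer(),
                      pct = numeric(), stringsAsFactors = FALSE))
  }
  counts <- counts[!is.na(counts)]
  data.frame(category = names(counts), n = as.integer(counts),
             pct = round(100 * as.integer(counts) / sum(counts), 2),
             stringsAsFactors = FALSE, row.names = NULL)
}
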