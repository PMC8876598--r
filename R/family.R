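# Family grouping of mature toxins by combined sequence homology and
# cysteine-framework compatibility; identity histograms against a reference
# toxin set.

#' Pairwise global identity matrix
#'
#' Percent identity over the columns of the best global (Needleman-Wunsch)
#' alignment, BLOSUM62 with gap penalties 11/1; the diagonal is 100.
#' Identical sequences are collapsed before alignment.
#'
#' @param matures Character vector of mature peptides (optionally named).
#' @return Symmetric numeric matrix of identities (percent).
#' @export
pairwise_identity_matrix <- function(matures) {
  stopifnot(length(matures) >= 1)
  n <- length(matures)
  subst <- get_subst_matrix("BLOSUM62")
  uniq <- unique(matures)
  map <- match(matures, uniq)
  u <- length(uniq)
  um <- matrix(100, u, u)
  if (u > 1) {
    uset <- Biostrings::AAStringSet(uniq)
    for (i in seq_len(u - 1)) {
      js <- (i + 1):u
      aln <- Biostrings::pairwiseAlignment(
        uset[js], Biostrings::AAString(uniq[i]), type = "global",
        substitutionMatrix = subst, gapOpening = 11, gapExtension = 1)
      pids <- Biostrings::pid(aln)
      um[i, js] <- pids
      um[js, i] <- pids
    }
  }
  m <- um[map, map, drop = FALSE]
  dimnames(m) <- list(names(matures), names(matures))
  m
}

#' Group toxins into families
#'
#' Single-linkage clustering over the relation "global identity at least
#' `identity_threshold_pct`, or at least `relaxed_threshold_pct` when the
#' cysteine frameworks are compatible (framework distance at most
#' `framework_max_dist`)". Inputs are sorted canonically by name before
#' linkage, so the partition does not depend on input order. Family labels
#' (`A`, `B`, ...) are assigned in decreasing family-size order, ties by
#' first-member name; subclusters number the strict-identity components
#' within each family.
#'
#' @param toxins Data frame with columns `name` and `mature`; a `notation`
#'   column (cysteine-framework notation) is used for the relaxed rule and
#'   computed from `mature` when absent.
#' @param identity_threshold_pct Strict identity threshold (percent).
#' @param relaxed_threshold_pct Relaxed threshold used with framework
#'   compatibility.
#' @param framework_max_dist Maximum [framework_distance()] for the relaxed
#'   rule.
#' @return Data frame `name`, `family_label`, `subcluster`,
#'   `linkage_identity_pct` (highest identity to another family member; 100
#'   for singleton families).
#' @export
assign_families <- function(toxins, identity_threshold_pct = 40,
                            relaxed_threshold_pct = 25,
                            framework_max_dist = 1) {
  stopifnot(all(c("name", "mature") %in% names(toxins)))
  toxins <- toxins[order(toxins$name), , drop = FALSE]
  n <- nrow(toxins)
  if (!"notation" %in% names(toxins)) {
    toxins$notation <- vapply(toxins$mature, function(m)
      extract_framework(m)$notation, character(1))
  }
  idm <- pairwise_identity_matrix(toxins$mature)
  # framework distances between the distinct notations only
  nots <- unique(toxins$notation)
  fd <- matrix(0L, length(nots), length(nots))
  if (length(nots) > 1) {
    for (i in seq_along(nots)) for (j in seq_along(nots)) {
      if (j > i) {
        d <- framework_distance(nots[i], nots[j])
        fd[i, j] <- d; fd[j, i] <- d
      }
    }
  }
  nidx <- match(toxins$notation, nots)
  fdm <- fd[nidx, nidx, drop = FALSE]
  link <- idm >= identity_threshold_pct |
    (idm >= relaxed_threshold_pct & fdm <= framework_max_dist)
  parent <- uf_new(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (link[i, j]) parent <- uf_union(parent, i, j)
    }
  }
  comp <- uf_components(parent)
  groups <- split(seq_len(n), comp)
  sizes <- lengths(groups)
  first_names <- vapply(groups, function(g) toxins$name[g[1]], character(1))
  ord <- order(-sizes, first_names)
  labels <- make_family_labels(length(groups))
  fam_label <- character(n)
  subcluster <- integer(n)
  link_id <- numeric(n)
  for (k in seq_along(ord)) {
    g <- groups[[ord[k]]]
    fam_label[g] <- labels[k]
    # subclusters: strict-identity components within the family
    sub_parent <- uf_new(length(g))
    if (length(g) > 1) {
      for (a in seq_len(length(g) - 1)) for (b in (a + 1):length(g)) {
        if (idm[g[a], g[b]] >= identity_threshold_pct) {
          sub_parent <- uf_union(sub_parent, a, b)
        }
      }
    }
    sub_comp <- uf_components(sub_parent)
    subcluster[g] <- match(sub_comp, unique(sub_comp))
    link_id[g] <- if (length(g) == 1) 100 else
      vapply(seq_along(g), function(a)
        max(idm[g[a], g[-a]]), numeric(1))
  }
  data.frame(name = toxins$name, family_label = fam_label,
             subcluster = subcluster,
             linkage_identity_pct = round(link_id, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

make_family_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(n)]
}

#' Best-hit identity histogram against a reference toxin set
#'
#' Each query contributes the identity of its best-scoring local alignment
#' hit to one bin `[k*w, (k+1)*w)` (top bin closed at 100); queries with no
#' hit passing the e-value cutoff fall in a `no_hit` bin. Bin counts always
#' sum to the number of queries.
#'
#' @param queries Character vector of protein sequences.
#' @param refs Reference set data frame (`id`, `seq`).
#' @param bin_width_pct Bin width in identity percent.
#' @param evalue_cutoff Minimum significance for counting a hit.
#' @return Data frame `bin`, `count`, with a final `no_hit` row.
#' @export
identity_histogram <- function(queries, refs, bin_width_pct = 10,
                               evalue_cutoff = 1e-5) {
  stopifnot(nrow(refs) > 0, bin_width_pct > 0)
  lo <- seq(0, 100 - bin_width_pct, by = bin_width_pct)
  labels <- paste0(lo, "-", lo + bin_width_pct)
  counts <- stats::setNames(integer(length(labels) + 1), c(labels, "no_hit"))
  if (length(queries)) {
    subst <- get_subst_matrix("BLOSUM62")
    db_len <- sum(nchar(refs$seq))
    qset <- Biostrings::AAStringSet(queries)
    score_m <- matrix(NA_real_, length(queries), nrow(refs))
    for (j in seq_len(nrow(refs))) {
      score_m[, j] <- Biostrings::pairwiseAlignment(
        qset, Biostrings::AAString(refs$seq[j]), type = "local",
        substitutionMatrix = subst, gapOpening = 11, gapExtension = 1,
        scoreOnly = TRUE)
    }
    for (i in seq_along(queries)) {
      best_j <- which.max(score_m[i, ])
      ev <- sw_evalue(score_m[i, best_j], nchar(queries[i]), db_len)
      if (ev > evalue_cutoff) {
        counts["no_hit"] <- counts["no_hit"] + 1L
      } else {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(queries[i]),
          Biostrings::AAString(refs$seq[best_j]), type = "local",
          substitutionMatrix = subst, gapOpening = 11, gapExtension = 1)
        p <- Biostrings::pid(aln)
        k <- min(length(labels), floor(p / bin_width_pct) + 1)
        counts[k] <- counts[k] + 1L
      }
    }
  }
  data.frame(bin = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}
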