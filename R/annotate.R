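# Six-frame translation, local alignment with e-values, and three-way EST
# classification (toxin-like / cellular / no-match) against a bundled
# reference protein set.

#' Reverse-complement a DNA string
#' @param seq Character vector of DNA sequences.
#' @return Reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

translate_frame <- function(seq, frame) {
  s <- if (frame > 0) substring(seq, frame) else substring(revcomp(seq), -frame)
  n_codon <- nchar(s) %/% 3
  if (n_codon == 0) return("")
  starts <- seq(1, by = 3, length.out = n_codon)
  codons <- substring(s, starts, starts + 2)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # codons containing N or other ambiguity codes
  paste(aa, collapse = "")
}

#' Find open reading frames in all six frames
#'
#' Scans the six reading frames of an EST. Candidate ORFs are
#' methionine-to-stop, or open-ended at either sequence terminus so that 5'-
#' or 3'-truncated fragments still yield their partial protein. ORFs whose
#' codons include an undetermined base (translated `X`) are discarded rather
#' than fabricating residues.
#'
#' @param seq A single DNA sequence.
#' @param min_orf_aa Minimum ORF length in amino acids.
#' @return A data frame with one row per ORF: `frame` (in -3..-1, 1..3),
#'   `aa_start` (1-based position within the frame translation), `protein`,
#'   `has_start` (begins with Met) and `has_stop` (ends at a stop codon).
#' @export
translate_orfs <- function(seq, min_orf_aa = 25) {
  out <- list()
  for (frame in c(1, 2, 3, -1, -2, -3)) {
    aa <- translate_frame(seq, frame)
    if (!nzchar(aa)) next
    res <- strsplit(aa, "", fixed = TRUE)[[1]]
    stops <- which(res == "*")
    seg_start <- c(1L, stops + 1L)
    seg_end <- c(stops - 1L, length(res))
    for (k in seq_along(seg_start)) {
      a <- seg_start[k]; b <- seg_end[k]
      if (b < a) next
      open5 <- (a == 1L)
      open3 <- (b == length(res))   # no trailing stop codon
      segment <- res[a:b]
      cand <- list()
      if (open5) {
        cand[[length(cand) + 1L]] <- c(start = a)
      }
      m <- which(segment == "M")
      if (length(m) && !(open5 && m[1] == 1L)) {
        cand[[length(cand) + 1L]] <- c(start = a + m[1] - 1L)
      } else if (!open5 && !length(m)) {
        next  # internal stop-to-stop segment without Met: not an ORF
      }
      for (cc in cand) {
        st <- cc[["start"]]
        prot <- paste(res[st:b], collapse = "")
        if (nchar(prot) < min_orf_aa) next
        if (grepl("X", prot, fixed = TRUE)) next
        out[[length(out) + 1L]] <- data.frame(
          frame = frame, aa_start = st, protein = prot,
          has_start = substr(prot, 1, 1) == "M",
          has_stop = !open3, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), aa_start = integer(),
                      protein = character(), has_start = logical(),
                      has_stop = logical(), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, out)
  orfs[!duplicated(orfs[c("frame", "aa_start", "protein")]), , drop = FALSE]
}

.matrix_registry <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                      "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                      "PAM250")

get_subst_matrix <- function(name) {
  if (!name %in% .matrix_registry) {
    stop("unknown substitution matrix: ", name)
  }
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal local (Smith-Waterman) protein alignment
#'
#' @param query,subject Protein sequences (single strings).
#' @param matrix Substitution matrix name (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @return A list with `score`, `identity_pct` (identical residues over
#'   aligned columns, gaps included), `aligned` (query/subject start and end
#'   of the local alignment) and `width` (alignment length in columns).
#' @export
local_align <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(query), nzchar(subject))
  m <- get_subst_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = m,
    gapOpening = gap_open, gapExtension = gap_extend)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  list(score = Biostrings::score(aln),
       identity_pct = Biostrings::pid(aln),
       aligned = c(q_start = Biostrings::start(pat), q_end = Biostrings::end(pat),
                   s_start = Biostrings::start(sub), s_end = Biostrings::end(sub)),
       width = Biostrings::nchar(aln))
}

#' Expectation value for a Smith-Waterman score
#'
#' Karlin-Altschul-style tail estimate `E = K * m * n * exp(-lambda * S)`
#' with Gumbel parameters fitted once against a shuffled-sequence null for
#' BLOSUM62 with gap penalties 11/1 (see the package vignette).
#'
#' @param score Raw local alignment score(s).
#' @param m Query length (aa).
#' @param n Subject or database length (aa).
#' @param lambda,K Gumbel parameters.
#' @return Expected number of chance alignments scoring at least `score`.
#' @export
sw_evalue <- function(score, m, n, lambda = SW_EVALUE_LAMBDA,
                      K = SW_EVALUE_K) {
  K * m * n * exp(-lambda * score)
}

.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Classify ESTs against a reference protein set
#'
#' Translates each EST in six frames, aligns every candidate ORF against
#' every reference protein by Smith-Waterman, and annotates the EST with the
#' best-scoring hit whose e-value passes the cutoff. The category
#' (`toxin_like` or `cellular`) is inherited from the best hit's reference;
#' ESTs without a passing hit are `no_match`. Ties on score are broken by
#' higher identity, then lexicographic reference id.
#'
#' @param ests EST table ([est_records()]).
#' @param refs Reference set (data frame with `id`, `seq`, `category` in
#'   `toxin`/`cellular`), e.g. from [load_reference_set()].
#' @param evalue_cutoff Maximum e-value for an annotating hit.
#' @param min_orf_aa Minimum ORF length considered.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @param prefilter_k Word length of the shared-k-mer prefilter; ORF/reference
#'   pairs sharing no exact `k`-mer are skipped (set `0` to disable). Any
#'   alignment able to pass the e-value cutoff shares many exact words, so
#'   the filter only prunes hopeless pairs.
#' @return Annotation data frame: `est_id`, `category`, `best_hit_id`,
#'   `score`, `evalue`, `identity_pct`, `frame`, `orf_protein`,
#'   `orf_has_start`, `orf_has_stop`, `secondary_orf_hit`.
#' @export
classify_ests <- function(ests, refs, evalue_cutoff = 1e-5, min_orf_aa = 25,
                          matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          prefilter_k = 4) {
  stopifnot(nrow(refs) > 0)
  subst <- get_subst_matrix(matrix)
  db_len <- sum(nchar(refs$seq))

  orf_list <- lapply(seq_len(nrow(ests)), function(i) {
    o <- translate_orfs(ests$seq[i], min_orf_aa = min_orf_aa)
    if (nrow(o)) o$est_id <- ests$id[i]
    o
  })
  orfs <- do.call(rbind, orf_list[vapply(orf_list, nrow, 1L) > 0])

  no_match_row <- function(id) {
    data.frame(est_id = id, category = "no_match",
               best_hit_id = NA_character_, score = NA_real_,
               evalue = NA_real_, identity_pct = NA_real_,
               frame = NA_integer_, orf_protein = NA_character_,
               orf_has_start = NA, orf_has_stop = NA,
               secondary_orf_hit = FALSE, stringsAsFactors = FALSE)
  }
  if (is.null(orfs) || nrow(orfs) == 0) {
    return(do.call(rbind, lapply(ests$id, no_match_row)))
  }

  n_orf <- nrow(orfs)
  scores <- matrix(NA_real_, n_orf, nrow(refs))
  if (prefilter_k > 0) {
    orf_kmers <- lapply(orfs$protein, .kmer_set, k = prefilter_k)
  }
  orf_set <- Biostrings::AAStringSet(orfs$protein)
  for (j in seq_len(nrow(refs))) {
    idx <- seq_len(n_orf)
    if (prefilter_k > 0) {
      ref_km <- .kmer_set(refs$seq[j], prefilter_k)
      keep <- vapply(orf_kmers, function(km) any(km %in% ref_km), logical(1))
      idx <- idx[keep]
    }
    if (!length(idx)) next
    scores[idx, j] <- Biostrings::pairwiseAlignment(
      orf_set[idx], Biostrings::AAString(refs$seq[j]), type = "local",
      substitutionMatrix = subst, gapOpening = gap_open,
      gapExtension = gap_extend, scoreOnly = TRUE)
  }
  evalues <- SW_EVALUE_K * nchar(orfs$protein) * db_len *
    exp(-SW_EVALUE_LAMBDA * scores)

  # Winner per EST among cells passing the cutoff.
  rows <- vector("list", nrow(ests))
  win_orf <- integer(0); win_ref <- integer(0); win_est <- integer(0)
  for (i in seq_len(nrow(ests))) {
    id <- ests$id[i]
    oi <- which(orfs$est_id == id)
    if (!length(oi)) { rows[[i]] <- no_match_row(id); next }
    pass <- which(!is.na(evalues[oi, , drop = FALSE]) &
                    evalues[oi, , drop = FALSE] <= evalue_cutoff,
                  arr.ind = TRUE)
    if (!nrow(pass)) { rows[[i]] <- no_match_row(id); next }
    cand_orf <- oi[pass[, 1]]; cand_ref <- pass[, 2]
    sc <- scores[cbind(cand_orf, cand_ref)]
    best <- which(sc == max(sc))
    if (length(best) > 1) {
      # break ties: Met-started ORF, then identity, then reference id
      pid <- vapply(best, function(b) {
        Biostrings::pid(Biostrings::pairwiseAlignment(
          Biostrings::AAString(orfs$protein[cand_orf[b]]),
          Biostrings::AAString(refs$seq[cand_ref[b]]), type = "local",
          substitutionMatrix = subst, gapOpening = gap_open,
          gapExtension = gap_extend))
      }, numeric(1))
      ord <- order(-as.integer(orfs$has_start[cand_orf[best]]), -pid,
                   refs$id[cand_ref[best]])
      best <- best[ord[1]]
    }
    win_orf <- c(win_orf, cand_orf[best])
    win_ref <- c(win_ref, cand_ref[best])
    win_est <- c(win_est, i)
    secondary <- length(unique(cand_orf[!(cand_orf == cand_orf[best])])) > 0
    rows[[i]] <- data.frame(
      est_id = id,
      category = ifelse(refs$category[cand_ref[best]] == "toxin",
                        "toxin_like", "cellular"),
      best_hit_id = refs$id[cand_ref[best]],
      score = scores[cand_orf[best], cand_ref[best]],
      evalue = evalues[cand_orf[best], cand_ref[best]],
      identity_pct = NA_real_,
      frame = orfs$frame[cand_orf[best]],
      orf_protein = orfs$protein[cand_orf[best]],
      orf_has_start = orfs$has_start[cand_orf[best]],
      orf_has_stop = orfs$has_stop[cand_orf[best]],
      secondary_orf_hit = secondary, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)

  # identity of the winning alignments, batched per reference
  if (length(win_est)) {
    for (j in unique(win_ref)) {
      sel <- win_ref == j
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(orfs$protein[win_orf[sel]]),
        Biostrings::AAString(refs$seq[j]), type = "local",
        substitutionMatrix = subst, gapOpening = gap_open,
        gapExtension = gap_extend)
      ann$identity_pct[win_est[sel]] <- Biostrings::pid(aln)
    }
  }
  ann
}

#' Compose a toxin name
#'
#' Names follow the `<prefix>-<n>` convention with `-P` appended for partial
#' sequences and `-T` for transcriptome-derived sequences, in that order.
#'
#' @param clone_number Non-negative clone number.
#' @param is_partial Partial (truncated) sequence?
#' @param from_transcriptome Derived from transcriptome assembly?
#' @param prefix Name stem, e.g. `"HptTx"`.
#' @return The toxin name string.
#' @examples
#' name_toxin(208, FALSE, FALSE, "HptTx")   # "HptTx-208"
#' name_toxin(1151, TRUE, TRUE, "HptTx")    # "HptTx-1151-P-T"
#' @export
name_toxin <- function(clone_number, is_partial = FALSE,
                       from_transcriptome = FALSE, prefix = "HptTx") {
  stopifnot(all(clone_number >= 0))
  paste0(prefix, "-", clone_number,
         ifelse(is_partial, "-P", ""),
         ifelse(from_transcriptome, "-T", ""))
}

#' Load the bundled reference protein set
#'
#' The package ships a curated reference FASTA of toxin-like and cellular
#' (housekeeping) exemplar proteins used for three-way classification. The
#' exemplars are synthetic constructs (see the file header and the package
#' vignette) apart from two mature toxin sequences determined directly by
#' Edman degradation and MALDI-TOF mass matching. Categories are read from a
#' `category=` tag in each FASTA header.
#'
#' @param path Optional path to an alternative reference FASTA with
#'   `category=toxin|cellular` header tags.
#' @return Data frame with `id`, `seq`, `category`, `provenance`.
#' @export
load_reference_set <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_set_synthetic.fasta",
                        package = "venomtx")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  category <- ifelse(grepl("category=toxin", headers), "toxin",
                     ifelse(grepl("category=cellular", headers), "cellular",
                            NA_character_))
  if (anyNA(category)) stop("reference entries must carry a category= tag")
  provenance <- sub("^\\S+\\s*", "", headers)
  data.frame(id = ids, seq = toupper(as.character(set)), category = category,
             provenance = provenance, stringsAsFactors = FALSE, row.names = NULL)
}
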