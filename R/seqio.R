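# Reading/writing FASTA and peak lists, EST containers, quality filtering.

#' Read a FASTA file into a data frame
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file and validates it
#' against the requested alphabet. Sequence ids are the first
#' whitespace-delimited token of each header; lowercase letters are upcased.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` (IUPAC nucleotide codes) or `"protein"`
#'   (20 standard residues plus `X`).
#' @return A data frame with columns `id`, `seq` and `length` in file order.
#'   An empty file yields a zero-row data frame.
#' @details Duplicate ids and illegal characters (including alignment gaps
#'   `-` and `.`) are hard errors naming the offending record.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  empty <- data.frame(id = character(), seq = character(),
                      length = integer(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) return(empty)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  allowed <- if (alphabet == "dna") DNA_IUPAC else c(AA_STANDARD, "X", "*")
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[i], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad)) {
      stop("illegal character(s) ", paste(bad, collapse = ","),
           " in record '", ids[i], "'")
    }
  }
  data.frame(id = ids, seq = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x Either a data frame with columns `id` and `seq`, or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (characters per sequence line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  if (is.data.frame(x)) {
    ids <- x$id; seqs <- x$seq
  } else {
    ids <- names(x); seqs <- unname(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Build an EST record table
#'
#' Attaches library/transcriptome provenance and quality-control slots to a
#' sequence table as read by [read_fasta()].
#'
#' @param fasta A data frame with columns `id` and `seq` (DNA).
#' @param source `"library"` (cDNA-library clone) or `"transcriptome"`
#'   (assembled transcript fragment).
#' @return A data frame with columns `id`, `seq`, `source`, `length_nt` and
#'   `is_high_quality` (`NA` until [qc_filter()] is applied).
#' @export
est_records <- function(fasta, source = c("library", "transcriptome")) {
  source <- match.arg(source)
  data.frame(id = fasta$id, seq = toupper(fasta$seq), source = source,
             length_nt = nchar(fasta$seq), is_high_quality = NA,
             stringsAsFactors = FALSE)
}

#' Quality-filter ESTs by insert length
#'
#' High-quality ESTs are those whose insert is strictly longer than
#' `qc_min_len` nucleotides. Input is assumed to be insert-only (vector and
#' adapter already removed); an optional 5'/3' flanking-motif pair is trimmed
#' first when given.
#'
#' @param ests EST table from [est_records()].
#' @param qc_min_len Minimum length in nt; records must exceed it strictly.
#' @param flank5,flank3 Optional literal flanking motifs removed (with
#'   everything outside them) before measuring length.
#' @return A list with elements `passing` and `failing`, both EST tables with
#'   `is_high_quality` filled in; row order of the input is preserved within
#'   each element and their union is the input.
#' @export
qc_filter <- function(ests, qc_min_len = 300, flank5 = NULL, flank3 = NULL) {
  stopifnot(qc_min_len >= 0)
  if (!is.null(flank5)) {
    hit <- regexpr(flank5, ests$seq, fixed = TRUE)
    keep <- hit > 0
    ests$seq[keep] <- substring(ests$seq[keep],
                                hit[keep] + attr(hit, "match.length")[keep])
  }
  if (!is.null(flank3)) {
    hit <- regexpr(flank3, ests$seq, fixed = TRUE)
    keep <- hit > 0
    ests$seq[keep] <- substring(ests$seq[keep], 1, hit[keep] - 1)
  }
  ests$length_nt <- nchar(ests$seq)
  pass <- ests$length_nt > qc_min_len
  ests$is_high_quality <- pass
  list(passing = ests[pass, , drop = FALSE],
       failing = ests[!pass, , drop = FALSE])
}

#' Read a MALDI-TOF peak list
#'
#' Reads a two-column tabular file (m/z, intensity), tab- or
#' whitespace-separated, with one optional header line. Peaks are returned
#' sorted ascending by m/z.
#'
#' @param path Path to the peak-list file.
#' @return A data frame with columns `mz` and `intensity`.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(mz = numeric(), intensity = numeric()))
  }
  first <- strsplit(trimws(lines[1]), "[\t ,]+")[[1]]
  if (suppressWarnings(is.na(as.numeric(first[1])))) lines <- lines[-1]
  if (length(lines) == 0) {
    return(data.frame(mz = numeric(), intensity = numeric()))
  }
  fields <- strsplit(trimws(lines), "[\t ,]+")
  mz <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  intensity <- vapply(fields, function(f) {
    if (length(f) >= 2) as.numeric(f[2]) else NA_real_
  }, numeric(1))
  if (anyNA(mz)) stop("malformed m/z value in ", path)
  if (any(mz < 0)) stop("negative m/z value in ", path)
  if (any(!is.na(intensity) & intensity < 0)) {
    stop("negative intensity in ", path)
  }
  ord <- order(mz)
  data.frame(mz = mz[ord], intensity = intensity[ord])
}

#' Trim a 3' poly-A tail
#'
#' Removes a terminal run of `A` of at least `min_run` bases. Used when
#' comparing cDNAs for unique-gene counting, where tail length is a cloning
#' artefact rather than sequence difference.
#'
#' @param seq Character vector of DNA sequences.
#' @param min_run Minimum run length that counts as a tail.
#' @return The trimmed sequences.
#' @export
trim_polya <- function(seq, min_run = 8) {
  pat <- sprintf("A{%d,}$", min_run)
  sub(pat, "", seq)
}
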