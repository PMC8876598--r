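# Segmentation of toxin precursors: signal peptide, propeptide (processing
# quadruplet motif), mature peptide, C-terminal amidation, completeness.

#' Predict the signal-peptide cleavage site
#'
#' Rule-based stand-in for a neural signal-peptide predictor. A candidate
#' cleavage position `c` (the signal ends at residue `c`) is scored as the
#' length of the hydrophobic core (longest run of residues in the h-region
#' zone, positions 4-18, whose 3-residue Kyte-Doolittle window average is at
#' least `kd_core`) plus a bonus of 2 when the residue at position `c`
#' (the -1 site) is small (A/G/S/C/T) and 1 when position `c - 2` (the -3
#' site) is small. Candidates range over positions `min_cut`..`max_cut`; the
#' highest-scoring (earliest on ties) wins, and `NA` is returned when no
#' candidate reaches `threshold`. When signal-peptide cleavage sites computed
#' by an external predictor are available they can be supplied downstream via
#' the `signal_override` argument of [segment_precursor()] instead.
#'
#' @param seq Precursor protein; full-length candidates start with `M`.
#' @param min_cut,max_cut Allowed cleavage-position range (residues).
#' @param kd_core Hydropathy threshold for the core run.
#' @param threshold Minimum score for a confident call.
#' @return The cleavage position (the signal peptide is `1..cut`) or `NA`.
#'   Sequences shorter than 15 aa return `NA` with a warning.
#' @export
predict_signal_peptide <- function(seq, min_cut = 15, max_cut = 35,
                                   kd_core = 1.6, threshold = 7) {
  n <- nchar(seq)
  if (n < 15) {
    warning("sequence shorter than 15 aa; no signal peptide predicted")
    return(NA_integer_)
  }
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  kd <- unname(KD_HYDROPATHY[res])
  kd[is.na(kd)] <- 0
  # 3-residue window average hydropathy
  win <- vapply(seq_len(n), function(i) {
    mean(kd[max(1, i - 1):min(n, i + 1)])
  }, numeric(1))
  zone <- 4:min(18, n)
  hydro <- win[zone] >= kd_core
  core <- 0L
  run <- 0L
  for (h in hydro) {
    run <- if (h) run + 1L else 0L
    core <- max(core, run)
  }
  cuts <- min_cut:min(max_cut, n - 1L)
  if (!length(cuts)) return(NA_integer_)
  small <- res %in% SIGNAL_SMALL_RESIDUES
  score <- core + 2 * small[cuts] + 1 * small[cuts - 2]
  best <- which.max(score)   # earliest position on ties
  if (score[best] < threshold) return(NA_integer_)
  cuts[best]
}

#' Locate the propeptide/mature cleavage by the processing quadruplet motif
#'
#' The processing quadruplet motif (PQM) is a four-residue motif ending in
#' arginine and enriched in acidic residues that marks the propeptide-to-
#' mature cleavage in spider toxin precursors. Operationally: scanning the
#' region downstream of the signal peptide, a position qualifies when it
#' holds `R` (P1) and at least one of the three preceding residues (P2-P4)
#' is acidic; the latest qualifying `R` before the first cysteine wins and
#' the propeptide ends at that `R`.
#'
#' @param downstream_seq Sequence after the signal-peptide cut.
#' @param max_pro_len Maximum propeptide length scanned.
#' @param acidic Residues accepted as the acidic P2-P4 partner (`E` alone
#'   for a stricter reading, `c("E","D")` by default).
#' @return The cut position (propeptide is `1..cut`) or `NA` when no
#'   propeptide is present and the mature peptide starts immediately.
#' @examples
#' find_pqm_cut("AEEARGDCLLW")   # cut after the R at position 5
#' find_pqm_cut("AEEAGGDCLLW")   # R lost by mutation: no propeptide
#' @export
find_pqm_cut <- function(downstream_seq, max_pro_len = 40,
                         acidic = c("E", "D")) {
  res <- strsplit(downstream_seq, "", fixed = TRUE)[[1]]
  n <- length(res)
  first_c <- which(res == "C")[1]
  limit <- min(max_pro_len, n - 1L,
               if (!is.na(first_c)) first_c - 1L else n - 1L)
  if (is.na(limit) || limit < 1) return(NA_integer_)
  cut <- NA_integer_
  for (i in seq_len(limit)) {
    if (res[i] != "R") next
    p234 <- res[max(1, i - 3):max(1, i - 1)]
    if (i > 1 && any(p234 %in% acidic)) cut <- i
  }
  cut
}

#' Detect a C-terminal amidation signal
#'
#' A terminal glycine (optionally followed by the basic processing residues
#' K/R) signals enzymatic amidation of the preceding residue. Recognised
#' tails, checked longest first, are `GKR`, `GK`, `GR` and `G`; the tail is
#' stripped and the residue before it becomes the amidated C-terminus.
#'
#' @param mature_plus_tail Mature peptide possibly still carrying the signal.
#' @return List with `amidated` (logical) and `trimmed_mature`.
#' @examples
#' detect_amidation("GSCKCNLILGR")  # TRUE, "GSCKCNLIL"
#' detect_amidation("AWDGK")        # TRUE, "AWD"
#' @export
detect_amidation <- function(mature_plus_tail) {
  s <- mature_plus_tail
  for (tail in c("GKR", "GK", "GR", "G")) {
    if (nchar(s) > nchar(tail) && endsWith(s, tail)) {
      return(list(amidated = TRUE,
                  trimmed_mature = substr(s, 1, nchar(s) - nchar(tail))))
    }
  }
  list(amidated = FALSE, trimmed_mature = s)
}

#' Classify precursor completeness
#'
#' @param has_start ORF begins at a methionine codon.
#' @param has_stop ORF ends at a stop codon.
#' @param signal_found A signal-peptide cleavage site was found.
#' @param first_cys_pos Position of the first cysteine in the ORF protein;
#'   a start-less ORF that opens essentially at the cysteine scaffold is
#'   called `mature_only` rather than `n_truncated`.
#' @param source `"library"` or `"transcriptome"`.
#' @return One of `"full_length"`, `"n_truncated"`, `"c_truncated"`,
#'   `"mature_only"`.
#' @export
flag_partial <- function(has_start, has_stop, signal_found = TRUE,
                         first_cys_pos = NA, source = "library") {
  if (has_start && has_stop) return("full_length")
  if (has_start) return("c_truncated")
  if (!is.na(first_cys_pos) && first_cys_pos <= 12) return("mature_only")
  "n_truncated"
}

#' Segment a toxin precursor
#'
#' Applies, in order: signal-peptide prediction (or an externally supplied
#' cleavage site), the processing-quadruplet-motif propeptide cut on the
#' downstream region, amidation detection on the remainder, and completeness
#' classification. For full-length records the four parts (signal,
#' propeptide, mature, stripped amidation tail) tile the precursor exactly.
#'
#' @param protein Precursor protein string (one ORF translation).
#' @param name Toxin name carried through to the output.
#' @param has_start,has_stop ORF evidence from [translate_orfs()].
#' @param source `"library"` or `"transcriptome"`.
#' @param signal_override Optional externally computed signal cleavage
#'   position (e.g. imported from a neural predictor's output table);
#'   overrides the built-in heuristic when not `NA`.
#' @param max_pro_len,acidic Passed to [find_pqm_cut()].
#' @param ... Passed to [predict_signal_peptide()].
#' @return A one-row data frame: `name`, `full_seq`, `signal`, `propeptide`,
#'   `mature`, `amidated`, `completeness`, `notes`.
#' @export
segment_precursor <- function(protein, name = NA_character_,
                              has_start = TRUE, has_stop = TRUE,
                              source = "library", signal_override = NA,
                              max_pro_len = 40, acidic = c("E", "D"), ...) {
  notes <- character(0)
  signal <- ""
  downstream <- protein
  sig_cut <- NA_integer_
  if (has_start && substr(protein, 1, 1) == "M") {
    sig_cut <- if (!is.na(signal_override)) as.integer(signal_override) else
      suppressWarnings(predict_signal_peptide(protein, ...))
    if (!is.na(sig_cut)) {
      signal <- substr(protein, 1, sig_cut)
      downstream <- substring(protein, sig_cut + 1)
    }
  }
  signal_found <- !is.na(sig_cut)
  pro <- ""
  pqm <- if (nzchar(downstream)) {
    find_pqm_cut(downstream, max_pro_len = max_pro_len, acidic = acidic)
  } else NA_integer_
  if (!is.na(pqm)) {
    pro <- substr(downstream, 1, pqm)
    downstream <- substring(downstream, pqm + 1)
  }
  ami <- detect_amidation(downstream)
  mature <- ami$trimmed_mature
  first_cys <- regexpr("C", protein, fixed = TRUE)
  completeness <- flag_partial(has_start, has_stop, signal_found,
                               if (first_cys > 0) first_cys else NA, source)
  if (!signal_found && has_start) notes <- c(notes, "no_signal_predicted")
  data.frame(name = name, full_seq = protein, signal = signal,
             propeptide = pro, mature = mature, amidated = ami$amidated,
             completeness = completeness,
             notes = paste(notes, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Flag premature stops and stop-codon readthrough within a cluster
#'
#' Members of one contig are expected to encode near-identical precursors;
#' a member whose protein is a proper prefix of the cluster's modal protein
#' carries a premature stop (a sense codon mutated to a stop codon), while a
#' member that extends the modal protein carries a stop-codon readthrough
#' (the stop codon mutated to a sense codon, extending the mature peptide).
#'
#' @param proteins Character vector of member precursor proteins (may repeat).
#' @return Character vector of notes per member: `""`, `"premature_stop"` or
#'   `"stop_readthrough"`.
#' @export
flag_stop_anomalies <- function(proteins) {
  notes <- rep("", length(proteins))
  if (length(proteins) < 2) return(notes)
  modal <- names(sort(table(proteins), decreasing = TRUE))[1]
  for (i in seq_along(proteins)) {
    p <- proteins[i]
    if (is.na(p) || p == modal) next
    if (nchar(p) <= nchar(modal) - 4 && startsWith(modal, p)) {
      notes[i] <- "premature_stop"
    } else if (nchar(p) >= nchar(modal) + 4 && startsWith(p, modal)) {
      notes[i] <- "stop_readthrough"
    }
  }
  notes
}
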