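# Theoretical peptide masses with disulfide/amidation corrections, MALDI
# peak matching under M+H+ and (M+2H+)/2 interpretations, Edman-prefix
# identification, molecular-weight histograms.

#' Theoretical mass of a (modified) peptide
#'
#' Residue-mass sum plus one water, minus two hydrogens per disulfide bond
#' and, when amidated, the C-terminal acid-to-amide correction (~0.98 Da).
#' Average masses correspond to what a linear-mode MALDI-TOF instrument
#' reports for an unresolved isotope envelope; monoisotopic masses to the
#' lightest isotopologue.
#'
#' @param sequence Peptide of standard amino acids.
#' @param n_disulfides Number of disulfide bonds; requires at least
#'   `2 * n_disulfides` cysteines.
#' @param amidated C-terminal amide instead of free acid?
#' @param scale `"average"` or `"monoisotopic"`.
#' @return Mass in Da.
#' @export
peptide_mass <- function(sequence, n_disulfides = 0, amidated = FALSE,
                         scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  stopifnot(nzchar(sequence), n_disulfides >= 0)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), AA_STANDARD)
  if (length(bad)) {
    stop("nonstandard residue(s): ", paste(bad, collapse = ","))
  }
  n_cys <- sum(res == "C")
  if (2 * n_disulfides > n_cys) {
    stop("n_disulfides (", n_disulfides, ") exceeds available cysteines (",
         n_cys, ")")
  }
  tab <- if (scale == "average") AA_MASS_AVG else AA_MASS_MONO
  water <- if (scale == "average") WATER_AVG else WATER_MONO
  sum(tab[res]) + water +
    modification_delta(n_disulfides, amidated, scale)
}

#' Total mass correction for disulfides and amidation
#'
#' @param n_disulfides Number of disulfide bonds (each removes 2 H).
#' @param amidated C-terminal amidation (removes ~0.98 Da)?
#' @param scale `"average"` or `"monoisotopic"`.
#' @return The (non-positive) correction in Da to add to the linear free
#'   peptide mass.
#' @examples
#' modification_delta(3, TRUE)   # about -7 Da
#' @export
modification_delta <- function(n_disulfides, amidated = FALSE,
                               scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  stopifnot(n_disulfides >= 0)
  h <- if (scale == "average") HYDROGEN_AVG else HYDROGEN_MONO
  amide <- if (scale == "average") AMIDATION_DELTA_AVG else
    AMIDATION_DELTA_MONO
  -(2 * h * n_disulfides) - (if (amidated) amide else 0)
}

#' Default disulfide count for a mature peptide
#'
#' The number of pairs in the assigned connectivity template when one is
#' known, otherwise all cysteines paired up (`floor(n_cys / 2)`).
#'
#' @param n_cys Number of cysteines.
#' @param template_id Assigned template id or `NA`.
#' @return Integer disulfide count.
#' @export
default_disulfides <- function(n_cys, template_id = NA) {
  if (!is.na(template_id)) {
    reg <- disulfide_templates()
    for (t in reg) if (t$id == template_id) return(nrow(t$pairs))
  }
  n_cys %/% 2L
}

#' Match MALDI peaks to candidate peptide masses
#'
#' Every peak is tested under the singly-protonated interpretation
#' (`M = mz - 1.00728`) and the doubly-protonated one
#' (`M = 2 mz - 2 * 1.00728`, a peak printed at half the neutral mass).
#' All pairings within tolerance are reported, best absolute mass error
#' first.
#'
#' @param peaks Peak list (data frame with `mz`, from [read_peaklist()]).
#' @param candidates Data frame with `name` and `mass` (theoretical Da).
#' @param tolerance_da Maximum |observed - theoretical| in Da.
#' @return Data frame `peak_mz`, `candidate`, `charge_interpretation`
#'   (`"M+H"` or `"M+2H_over_2"`), `observed_m`, `theoretical_m`, `delta_da`,
#'   `within_tolerance` (always `TRUE` in the returned rows).
#' @export
match_peaks <- function(peaks, candidates, tolerance_da = 2.0) {
  stopifnot(tolerance_da > 0)
  out <- data.frame(peak_mz = numeric(), candidate = character(),
                    charge_interpretation = character(),
                    observed_m = numeric(), theoretical_m = numeric(),
                    delta_da = numeric(), within_tolerance = logical(),
                    stringsAsFactors = FALSE)
  if (!nrow(peaks) || !nrow(candidates)) return(out)
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    mz <- peaks$mz[i]
    for (interp in c("M+H", "M+2H_over_2")) {
      m <- if (interp == "M+H") mz - PROTON_MASS else
        2 * mz - 2 * PROTON_MASS
      delta <- m - candidates$mass
      hit <- which(abs(delta) <= tolerance_da)
      for (h in hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          peak_mz = mz, candidate = candidates$name[h],
          charge_interpretation = interp, observed_m = m,
          theoretical_m = candidates$mass[h], delta_da = delta[h],
          within_tolerance = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(out)
  res <- do.call(rbind, rows)
  res[order(abs(res$delta_da)), , drop = FALSE]
}

#' Identify a purified peptide from its Edman N-terminal prefix
#'
#' Finds precursors whose mature peptide starts with the chemically
#' sequenced N-terminal prefix (exact match; when none matches exactly,
#' prefixes with at most one mismatch are accepted), then cross-checks each
#' candidate's theoretical mass against the observed molecular weight.
#'
#' @param edman_prefix N-terminal residues (at least 5).
#' @param db Precursor table with columns `name`, `mature`, `amidated`;
#'   an optional `n_disulfides` column overrides [default_disulfides()].
#' @param observed_mw Experimentally determined neutral mass (Da).
#' @param tolerance_da Tolerance for the mass cross-check.
#' @param scale Mass scale.
#' @return Candidates ranked by |mass error| with `name`, `mature`,
#'   `theoretical_mw`, `delta_da`, `mw_check_passed`, `prefix_mismatches`.
#' @export
identify_by_nterm <- function(edman_prefix, db, observed_mw,
                              tolerance_da = 2.0,
                              scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  stopifnot(nchar(edman_prefix) >= 5)
  mism <- function(mature) {
    if (nchar(mature) < nchar(edman_prefix)) return(Inf)
    a <- strsplit(substr(mature, 1, nchar(edman_prefix)), "")[[1]]
    b <- strsplit(edman_prefix, "")[[1]]
    sum(a != b)
  }
  mm <- vapply(db$mature, mism, numeric(1))
  sel <- which(mm == 0)
  if (!length(sel)) sel <- which(mm <= 1)
  if (!length(sel)) {
    return(data.frame(name = character(), mature = character(),
                      theoretical_mw = numeric(), delta_da = numeric(),
                      mw_check_passed = logical(),
                      prefix_mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(sel, function(i) {
    n_cys <- lengths(regmatches(db$mature[i],
                                gregexpr("C", db$mature[i], fixed = TRUE)))
    nss <- if ("n_disulfides" %in% names(db)) db$n_disulfides[i] else
      default_disulfides(n_cys)
    mw <- peptide_mass(db$mature[i], n_disulfides = nss,
                       amidated = isTRUE(db$amidated[i]), scale = scale)
    data.frame(name = db$name[i], mature = db$mature[i],
               theoretical_mw = mw, delta_da = observed_mw - mw,
               mw_check_passed = abs(observed_mw - mw) <= tolerance_da,
               prefix_mismatches = as.integer(mm[i]),
               stringsAsFactors = FALSE)
  }))
  res[order(abs(res$delta_da)), , drop = FALSE]
}

#' Histogram of peptide molecular weights
#'
#' Bins masses over a fixed acquisition window (default 1000-10000 Da, the
#' mass range below which matrix peaks dominate and above which venom
#' proteins rather than peptides elute).
#'
#' @param masses Numeric vector of masses (Da).
#' @param bin_width Bin width in Da.
#' @param window Acquisition window `c(lo, hi)`.
#' @return Data frame `bin_lo`, `bin_hi`, `count`; counts sum to the number
#'   of in-window masses.
#' @export
mw_distribution <- function(masses, bin_width = 500,
                            window = c(1000, 10000)) {
  stopifnot(bin_width > 0, length(window) == 2, window[1] < window[2])
  edges <- seq(window[1], window[2], by = bin_width)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  counts <- integer(length(edges) - 1)
  inw <- masses[masses >= window[1] & masses <= window[2]]
  if (length(inw)) {
    idx <- pmin(findInterval(inw, edges), length(counts))
    t <- table(idx)
    counts[as.integer(names(t))] <- as.integer(t)
  }
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             count = counts)
}
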