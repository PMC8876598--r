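# Deterministic synthetic venom-gland library generator with a ground-truth
# manifest. Emulates: toxin precursor cDNAs (signal + optional propeptide
# ending in a processing-quadruplet motif + cysteine-scaffolded mature +
# optional amidation tail + stop + poly-A), cellular transcripts derived
# from housekeeping exemplars, unmatchable codon-shuffled sequences,
# copy-number skew, point mutations including cysteine loss and stop-codon
# gain/readthrough, and 5'/3' fragmentation.

# codon table: amino acid -> synonymous codons
.rev_codon <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

.sample1 <- function(x) x[sample.int(length(x), 1)]

reverse_translate <- function(protein) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(res, function(a) .sample1(.rev_codon[[a]]), character(1)),
        collapse = "")
}

# residue pools used when drawing sequence; mature regions avoid C (which
# would perturb the framework) and R (which could fabricate a quadruplet
# motif upstream of the first cysteine)
.MATURE_POOL <- setdiff(AA_STANDARD, c("C", "R"))
.H_REGION_POOL <- c("L", "I", "V", "F", "M")

draw_residues <- function(n, pool = .MATURE_POOL) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

#' Draw a mature peptide realizing a cysteine-framework scaffold
#'
#' Cysteines are placed according to the adjacency notation (zero spacer
#' between juxtaposed labels, 2-8 residues otherwise) with short leading and
#' trailing segments; peptides are padded at the C-terminal segment to at
#' least `min_len` residues, the length below which even an exact database
#' hit loses alignment significance. Drawn residues exclude cysteine and
#' arginine, and the final residue avoids G/K/R so that an un-amidated
#' peptide never mimics an amidation signal.
#'
#' @param scaffold Framework notation, e.g. `"C1-C2-C3C4-C5-C6"`.
#' @param min_len Minimum mature length in residues.
#' @return A mature peptide string whose [extract_framework()] notation
#'   equals `scaffold`.
#' @export
mature_from_scaffold <- function(scaffold, min_len = 24) {
  sig <- parse_notation(scaffold)
  lead <- draw_residues(sample(2:6, 1))
  parts <- lead
  if (sig$n_cys > 0) {
    parts <- c(parts, "C")
    if (sig$n_cys > 1) {
      for (k in seq_len(sig$n_cys - 1)) {
        gap <- if (sig$adjacent[k]) 0 else sample(2:8, 1)
        parts <- c(parts, if (gap) draw_residues(gap) else "", "C")
      }
    }
  }
  tail_len <- sample(3:6, 1)
  body <- paste(parts, collapse = "")
  tail_len <- max(tail_len, min_len - nchar(body))
  s <- paste0(body, draw_residues(tail_len))
  enforce_tail(s)
}

# final residue must not look like an amidation signal on its own
enforce_tail <- function(mature) {
  last <- substr(mature, nchar(mature), nchar(mature))
  if (last %in% c("G", "K", "R")) {
    substr(mature, nchar(mature), nchar(mature)) <- "L"
  }
  mature
}

#' Substitute residues at a fixed per-site rate
#'
#' Substitutions never touch cysteines and never introduce cysteine or
#' arginine, so the framework and the quadruplet-motif context of the
#' original sequence are preserved; the terminal-residue constraint of
#' [mature_from_scaffold()] is re-enforced.
#'
#' @param protein Input protein.
#' @param rate Per-site substitution probability.
#' @return Mutated protein.
#' @export
mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(res)) < rate & res != "C")
  for (i in hit) {
    res[i] <- .sample1(setdiff(.MATURE_POOL, res[i]))
  }
  enforce_tail(paste(res, collapse = ""))
}

draw_signal_peptide <- function() {
  paste0("M", draw_residues(2, c("K", "R", "N", "Q", "E", "D")),
         draw_residues(sample(9:12, 1), .H_REGION_POOL),
         .sample1(c("A", "G", "S", "T")),        # -3: small
         .sample1(c("Q", "N", "H", "Y", "P")),   # -2: neither small nor apolar
         .sample1(c("A", "G", "S")))             # -1: small
}

draw_propeptide <- function() {
  interior <- draw_residues(sample(2:12, 1),
                            c("E", "D", "S", "A", "N", "Q", "T"))
  quad <- sample(c("A", "S", "N", "E", "D"), 3, replace = TRUE)
  quad[sample.int(3, 1)] <- .sample1(c("E", "D"))  # guarantee an acidic P2-P4
  paste0(interior, paste(quad, collapse = ""), "R")
}

draw_utr5 <- function() {
  repeat {
    u <- draw_residues(sample(10:40, 1), c("A", "C", "G", "T"))
    if (!grepl("ATG", u, fixed = TRUE)) return(u)
  }
}

draw_utr3 <- function() {
  # in frame with the CDS: a few sense codons, a guaranteed in-frame stop,
  # then unconstrained sequence (supports stop-readthrough ground truth)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  k1 <- sample(3:7, 1)
  paste0(paste(sample(sense, k1, replace = TRUE), collapse = ""), "TAA",
         draw_residues(sample(150:400, 1), c("A", "C", "G", "T")))
}

#' Generate one toxin precursor cDNA with its ground truth
#'
#' Emits `5'UTR + ATG...signal + [propeptide ending in a qualifying
#' quadruplet motif] + mature (cysteines per scaffold) + amidation tail +
#' TGA + 3'UTR + poly-A`, with codons drawn uniformly over synonymous sets.
#' Draws depend only on the R random-number state, so a fixed seed gives
#' byte-identical output.
#'
#' @param scaffold Cysteine-framework notation for the mature peptide.
#' @param with_propeptide Include a propeptide?
#' @param amidation One of `"none"`, `"G"`, `"GK"`, `"GR"`.
#' @param mature Optional pre-drawn mature peptide (overrides `scaffold`).
#' @return List with `cdna` and `truth` (a one-row data frame with the
#'   planted segmentation, amidation flag, framework notation and mature
#'   mass).
#' @export
generate_precursor_cdna <- function(scaffold, with_propeptide = TRUE,
                                    amidation = c("none", "G", "GK", "GR"),
                                    mature = NULL) {
  amidation <- match.arg(amidation)
  if (is.null(mature)) mature <- mature_from_scaffold(scaffold)
  signal <- draw_signal_peptide()
  pro <- if (with_propeptide) draw_propeptide() else ""
  tail <- if (amidation == "none") "" else amidation
  protein <- paste0(signal, pro, mature, tail)
  cds <- paste0(reverse_translate(protein), "TGA")
  cdna <- paste0(draw_utr5(), cds, draw_utr3(),
                 strrep("A", sample(15:30, 1)))
  truth <- data.frame(
    protein = protein, signal = signal, propeptide = pro, mature = mature,
    amidation_tail = tail, amidated = amidation != "none",
    notation = extract_framework(mature)$notation,
    mature_mass = peptide_mass(mature,
                               n_disulfides = extract_framework(mature)$n_cys %/% 2,
                               amidated = amidation != "none"),
    stringsAsFactors = FALSE)
  list(cdna = cdna, truth = truth)
}

#' Generator configuration
#'
#' Defaults describe a venom-gland cDNA library: three transcript categories
#' in proportions 0.54 / 0.26 / 0.20 (toxin-like, cellular, no-match), 13
#' toxin families seeded from the bundled exemplars, strong copy-number skew
#' (Zipf weights) so that most toxin transcripts fall into multi-member
#' contigs, sparse point mutations ("natural mutants" differing by a few
#' residues), rare cysteine-loss / premature-stop / stop-readthrough events,
#' and occasional 5'/3' fragmentation. See the package vignette for the
#' rationale behind each default.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_transcripts Total number of transcripts to emit.
#' @param category_proportions Named numeric vector (`toxin`, `cellular`,
#'   `no_match`) summing to 1.
#' @param families Data frame describing the toxin families: `family`,
#'   `exemplar_mature`, `with_propeptide`, `amidation`. Default: the bundled
#'   exemplar set via [default_families()].
#' @param genes_per_family Range (min, max) of distinct paralogous genes per
#'   family.
#' @param exemplar_divergence Per-site divergence of a family seed from its
#'   exemplar (emulates cross-species homology levels).
#' @param gene_divergence Per-site divergence between paralogous genes of
#'   one family.
#' @param n_cellular_genes,n_no_match_genes Distinct genes in the other two
#'   categories.
#' @param cellular_divergence Per-site divergence of a cellular gene from
#'   its housekeeping exemplar.
#' @param copy_zipf_exponent Exponent of the Zipf copy-number weights.
#' @param mutation_rates List with `point` (per-nt substitution rate per
#'   copy), `cys_loss`, `stop_gain`, `stop_readthrough` (per-copy event
#'   probabilities).
#' @param fragmentation_prob Per-copy probability of 5' or 3' truncation.
#' @param transcriptome_prob Per-toxin-copy probability of being emitted as
#'   a short transcriptome-assembly fragment instead of a library clone.
#' @param n_fractions Number of chromatographic fractions for the emitted
#'   peak lists.
#' @param noise_peaks_per_fraction Range of uniform-noise peaks added per
#'   fraction.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1,
                             n_transcripts = 1000,
                             category_proportions = c(toxin = 0.54,
                                                      cellular = 0.26,
                                                      no_match = 0.20),
                             families = default_families(),
                             genes_per_family = c(1, 6),
                             exemplar_divergence = 0.10,
                             gene_divergence = 0.04,
                             n_cellular_genes = 60,
                             n_no_match_genes = 30,
                             cellular_divergence = 0.20,
                             copy_zipf_exponent = 1.2,
                             mutation_rates = list(point = 0.001,
                                                   cys_loss = 0.02,
                                                   stop_gain = 0.005,
                                                   stop_readthrough = 0.005),
                             fragmentation_prob = 0.05,
                             transcriptome_prob = 0.05,
                             n_fractions = 36,
                             noise_peaks_per_fraction = c(2, 5)) {
  if (abs(sum(category_proportions) - 1) > 1e-9) {
    stop("category_proportions must sum to 1")
  }
  rates <- unlist(mutation_rates)
  if (any(rates < 0 | rates > 1)) stop("mutation rates must be in [0,1]")
  structure(as.list(environment()), class = "generator_config")
}

#' Default toxin family settings
#'
#' One row per bundled toxin exemplar: its mature sequence, cysteine
#' scaffold, whether precursors of that family carry a propeptide, and the
#' family's amidation signal. The thirteen scaffolds cover the frameworks
#' recurrent in spider venom peptides (2-10 cysteines, including juxtaposed
#' pairs and a triplet).
#'
#' @param refs Reference set; defaults to the bundled one.
#' @return Data frame `family`, `exemplar_id`, `exemplar_mature`,
#'   `with_propeptide`, `amidation`.
#' @export
default_families <- function(refs = load_reference_set()) {
  tox <- refs[refs$category == "toxin" &
                grepl("^TOXFAM_", refs$id), , drop = FALSE]
  tox <- tox[order(tox$id), , drop = FALSE]
  settings <- data.frame(
    family = LETTERS[1:13],
    with_propeptide = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                        TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    amidation = c("none", "none", "none", "none", "none", "none", "none",
                  "none", "G", "GK", "G", "GK", "GR"),
    stringsAsFactors = FALSE)
  stopifnot(nrow(tox) == nrow(settings))
  data.frame(family = settings$family, exemplar_id = tox$id,
             exemplar_mature = tox$seq,
             with_propeptide = settings$with_propeptide,
             amidation = settings$amidation, stringsAsFactors = FALSE)
}

# highest global identity of cand against a set of sequences
.max_identity <- function(cand, others) {
  if (!length(others)) return(0)
  subst <- get_subst_matrix("BLOSUM62")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(others), Biostrings::AAString(cand),
    type = "global", substitutionMatrix = subst,
    gapOpening = 11, gapExtension = 1)
  max(Biostrings::pid(aln))
}

# mutate `base` at `rate` until the result is below `limit` percent identity
# to every sequence in `others` (capped attempts, best candidate kept)
draw_separated <- function(base, rate, others, limit = 22,
                           max_tries = 200) {
  if (rate <= 0) return(base)
  best <- NULL
  best_mx <- Inf
  for (try in seq_len(max_tries)) {
    cand <- mutate_protein(base, rate)
    mx <- .max_identity(cand, others)
    if (mx < best_mx) {
      best <- cand
      best_mx <- mx
    }
    if (best_mx < limit) break
  }
  best
}

zipf_weights <- function(n, exponent) {
  w <- seq_len(n)^(-exponent)
  w / sum(w)
}

apply_point_mutations <- function(seq, rate) {
  if (rate <= 0) return(seq)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(res)) < rate)
  for (i in hit) res[i] <- .sample1(setdiff(c("A", "C", "G", "T"), res[i]))
  paste(res, collapse = "")
}

#' Generate a synthetic venom-gland library
#'
#' Emits a transcript table, a per-transcript ground-truth manifest and
#' per-fraction MALDI-style peak lists, fully determined by the seed in the
#' configuration.
#'
#' @param config A [generator_config()].
#' @return List with `ests` (an EST table as from [est_records()], mixed
#'   sources), `manifest` (one row per transcript: category, family, gene,
#'   planted segmentation, amidation, framework, mature mass, anomalies) and
#'   `peaklists` (named list of peak-list data frames).
#' @export
generate_library <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  props <- config$category_proportions[c("toxin", "cellular", "no_match")]
  n_cat <- stats::setNames(as.vector(stats::rmultinom(1, config$n_transcripts,
                                                      props)), names(props))
  refs <- load_reference_set()
  housekeeping <- refs$seq[refs$category == "cellular"]

  ## ---- gene pools ---------------------------------------------------------
  fam <- config$families
  toxin_genes <- list()
  other_matures <- list()  # accepted matures, keyed by family
  for (f in seq_len(nrow(fam))) {
    others <- unlist(other_matures[setdiff(names(other_matures),
                                           fam$family[f])])
    # families are planted as separable groups: every realized mature must
    # stay clearly below the relaxed linkage threshold (25%) against all
    # matures of the other families
    seed_mature <- draw_separated(fam$exemplar_mature[f],
                                  config$exemplar_divergence, others)
    other_matures[[fam$family[f]]] <- seed_mature
    signal <- draw_signal_peptide()
    pro <- if (fam$with_propeptide[f]) draw_propeptide() else ""
    tail <- if (fam$amidation[f] == "none") "" else fam$amidation[f]
    n_genes <- sample(config$genes_per_family[1]:config$genes_per_family[2], 1)
    for (g in seq_len(n_genes)) {
      mat <- if (g == 1) seed_mature else
        draw_separated(seed_mature, config$gene_divergence, others)
      other_matures[[fam$family[f]]] <-
        c(other_matures[[fam$family[f]]], mat)
      protein <- paste0(signal, pro, mat, tail)
      cds <- paste0(reverse_translate(protein), "TGA")
      cdna <- paste0(draw_utr5(), cds, draw_utr3(),
                     strrep("A", sample(15:30, 1)))
      toxin_genes[[length(toxin_genes) + 1L]] <- list(
        family = fam$family[f], gene = sprintf("%s_g%d", fam$family[f], g),
        cdna = cdna, signal = signal, pro = pro, mature = mat, tail = tail,
        amidation = fam$amidation[f])
    }
  }

  cellular_genes <- lapply(seq_len(config$n_cellular_genes), function(g) {
    ex <- .sample1(housekeeping)
    protein <- paste0("M", mutate_protein(substring(ex, 2),
                                          config$cellular_divergence))
    cds <- paste0(reverse_translate(protein), "TGA")
    list(gene = sprintf("HK_g%d", g),
         cdna = paste0(draw_utr5(), cds, draw_utr3(),
                       strrep("A", sample(15:30, 1))))
  })
  no_match_genes <- lapply(seq_len(config$n_no_match_genes), function(g) {
    ex <- .sample1(housekeeping)
    cds0 <- reverse_translate(ex)
    codons <- substring(cds0, seq(1, nchar(cds0) - 2, 3),
                        seq(3, nchar(cds0), 3))
    interior <- sample(codons[-1])  # composition-preserving codon shuffle
    cds <- paste0("ATG", paste(interior, collapse = ""), "TGA")
    list(gene = sprintf("NM_g%d", g),
         cdna = paste0(draw_utr5(), cds, draw_utr3(),
                       strrep("A", sample(15:30, 1))))
  })

  ## ---- copies with per-copy events ---------------------------------------
  rows <- list()
  emit <- function(row) rows[[length(rows) + 1L]] <<- row

  make_copies <- function(genes, n_copies, category, min_one_per = NULL) {
    if (n_copies == 0 || !length(genes)) return(invisible())
    w <- zipf_weights(length(genes), config$copy_zipf_exponent)
    w <- w[sample.int(length(w))]  # abundance rank not tied to gene order
    counts <- as.vector(stats::rmultinom(1, n_copies, w))
    if (!is.null(min_one_per)) {
      # every family is represented at least once (the library is sequenced
      # to saturation of the families actually present)
      groups <- vapply(genes, `[[`, character(1), min_one_per)
      for (f in unique(groups)) {
        sel <- which(groups == f)
        if (sum(counts[sel]) == 0 && sum(counts) > 1) {
          donor <- which.max(counts)
          counts[donor] <- counts[donor] - 1L
          counts[sel[1]] <- 1L
        }
      }
    }
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      for (cp in seq_len(counts[gi])) {
        emit(make_one_copy(g, category, config))
      }
    }
  }
  make_copies(toxin_genes, n_cat[["toxin"]], "toxin", min_one_per = "family")
  make_copies(cellular_genes, n_cat[["cellular"]], "cellular")
  make_copies(no_match_genes, n_cat[["no_match"]], "no_match")

  manifest <- do.call(rbind, rows)
  manifest <- manifest[sample.int(nrow(manifest)), , drop = FALSE]
  manifest$id <- sprintf("EST_%04d", seq_len(nrow(manifest)))
  rownames(manifest) <- NULL

  ests <- do.call(rbind, lapply(split(manifest, manifest$source), function(m)
    est_records(data.frame(id = m$id, seq = m$seq), source = m$source[1])))
  ests <- ests[match(manifest$id, ests$id), , drop = FALSE]
  rownames(ests) <- NULL
  manifest$seq <- NULL

  ## ---- peak lists ---------------------------------------------------------
  tox_m <- manifest[manifest$category == "toxin" & !is.na(manifest$mature) &
                      manifest$anomalies == "", , drop = FALSE]
  masses <- sort(unique(round(tox_m$mature_mass, 4)))
  masses <- masses[masses >= 1000 & masses <= 10000]
  peaklists <- list()
  if (length(masses)) {
    frac_of <- sample.int(config$n_fractions, length(masses), replace = TRUE)
    for (f in seq_len(config$n_fractions)) {
      m <- masses[frac_of == f]
      mz <- m + PROTON_MASS
      if (length(m)) {
        dbl <- stats::runif(length(m)) < 0.3
        mz <- c(mz, m[dbl] / 2 + PROTON_MASS)
      }
      n_noise <- sample(config$noise_peaks_per_fraction[1]:
                          config$noise_peaks_per_fraction[2], 1)
      mz <- c(mz, stats::runif(n_noise, 1000, 10000))
      pk <- data.frame(mz = mz,
                       intensity = round(stats::runif(length(mz), 5, 100), 1))
      pk <- pk[order(pk$mz), , drop = FALSE]
      rownames(pk) <- NULL
      peaklists[[sprintf("F%02d", f)]] <- pk
    }
  }
  list(ests = ests, manifest = manifest, peaklists = peaklists,
       config = config)
}

# one transcript copy: nt-level noise, rare targeted events, fragmentation
make_one_copy <- function(g, category, config) {
  rates <- config$mutation_rates
  cdna <- g$cdna
  anomalies <- character(0)
  source <- "library"

  cdna <- apply_point_mutations(cdna, rates$point)

  if (category == "toxin") {
    prot_len <- nchar(paste0(g$signal, g$pro, g$mature, g$tail))
    # the 5' UTR contains no ATG by construction, so the first ATG of the
    # unmutated gene locates the CDS
    cds_at <- regexpr("ATG", g$cdna, fixed = TRUE)

    if (stats::runif(1) < rates$cys_loss && grepl("C", g$mature)) {
      # mutate one cysteine codon non-synonymously
      res <- strsplit(g$mature, "", fixed = TRUE)[[1]]
      ci <- .sample1(which(res == "C"))
      aa_pos <- nchar(g$signal) + nchar(g$pro) + ci
      nt_pos <- cds_at + 3L * (aa_pos - 1L)
      new_codon <- .sample1(.rev_codon[[.sample1(setdiff(.MATURE_POOL, "C"))]])
      substr(cdna, nt_pos, nt_pos + 2L) <- new_codon
      anomalies <- c(anomalies, "cys_mutation")
    }
    if (stats::runif(1) < rates$stop_gain) {
      res_n <- nchar(g$mature)
      ci <- sample(2:(res_n - 1), 1)
      aa_pos <- nchar(g$signal) + nchar(g$pro) + ci
      nt_pos <- cds_at + 3L * (aa_pos - 1L)
      substr(cdna, nt_pos, nt_pos + 2L) <- .sample1(c("TAA", "TAG", "TGA"))
      anomalies <- c(anomalies, "premature_stop")
    }
    if (stats::runif(1) < rates$stop_readthrough) {
      stop_pos <- cds_at + 3L * prot_len
      substr(cdna, stop_pos, stop_pos + 2L) <- "CGA"  # TGA -> CGA
      anomalies <- c(anomalies, "stop_readthrough")
    }
  }

  if (category == "toxin" && stats::runif(1) < config$transcriptome_prob) {
    source <- "transcriptome"
    len <- sample(150:450, 1)
    if (len < nchar(cdna)) {
      if (stats::runif(1) < 0.5) {
        cdna <- substring(cdna, nchar(cdna) - len + 1L)
        anomalies <- c(anomalies, "fragment_5p")
      } else {
        cdna <- substr(cdna, 1L, len)
        anomalies <- c(anomalies, "fragment_3p")
      }
    }
  } else if (stats::runif(1) < config$fragmentation_prob) {
    if (stats::runif(1) < 0.5) {
      cut <- sample.int(floor(nchar(cdna) * 0.6), 1)
      cdna <- substring(cdna, cut + 1L)
      anomalies <- c(anomalies, "fragment_5p")
    } else {
      keep <- floor(nchar(cdna) * stats::runif(1, 0.4, 0.9))
      cdna <- substr(cdna, 1L, keep)
      anomalies <- c(anomalies, "fragment_3p")
    }
  }

  if (category != "toxin") {
    return(data.frame(seq = cdna, source = source, category = category,
                      family = NA_character_, gene = g$gene,
                      anomalies = paste(anomalies, collapse = ";"),
                      signal = NA_character_, propeptide = NA_character_,
                      mature = NA_character_, amidated = NA,
                      notation = NA_character_, mature_mass = NA_real_,
                      protein = NA_character_, stringsAsFactors = FALSE))
  }

  truth <- toxin_copy_truth(g, cdna, anomalies)
  anomalies <- union(anomalies, truth$extra_anomalies)
  data.frame(seq = cdna, source = source, category = "toxin",
             family = g$family, gene = g$gene,
             anomalies = paste(anomalies, collapse = ";"),
             signal = truth$signal, propeptide = truth$pro,
             mature = truth$mature, amidated = truth$amidated,
             notation = truth$notation, mature_mass = truth$mass,
             protein = truth$protein, stringsAsFactors = FALSE)
}

# ground truth of a (possibly mutated, unfragmented-coordinates) toxin copy:
# re-translate the planted spans from the mutated cDNA so that nt-level
# noise is reflected in the manifest
toxin_copy_truth <- function(g, cdna, anomalies) {
  sig_n <- nchar(g$signal); pro_n <- nchar(g$pro)
  mat_n <- nchar(g$mature); tail_n <- nchar(g$tail)
  prot_len <- sig_n + pro_n + mat_n + tail_n
  cds_at <- regexpr("ATG", g$cdna, fixed = TRUE)  # coordinates pre-fragmentation
  frag <- any(anomalies %in% c("fragment_5p", "fragment_3p"))
  if (frag) {
    # the planted peptides may be partly missing from the fragment; record
    # the planted truth of the unfragmented gene and let anomalies mark it
    return(list(signal = g$signal, pro = g$pro, mature = g$mature,
                amidated = g$amidation != "none",
                notation = extract_framework(g$mature)$notation,
                mass = peptide_mass(g$mature,
                                    extract_framework(g$mature)$n_cys %/% 2,
                                    g$amidation != "none"),
                protein = paste0(g$signal, g$pro, g$mature, g$tail),
                extra_anomalies = character(0)))
  }
  aa_full <- translate_frame(substring(cdna, cds_at), 1)
  stop_at <- regexpr("*", aa_full, fixed = TRUE)
  protein <- if (stop_at > 0) substr(aa_full, 1, stop_at - 1) else aa_full
  signal <- substr(protein, 1, sig_n)
  pro <- substr(protein, sig_n + 1, sig_n + pro_n)
  mature <- substr(protein, sig_n + pro_n + 1, sig_n + pro_n + mat_n)
  amidated <- g$amidation != "none"
  extra <- character(0)
  if (nchar(protein) > prot_len) {
    # stop readthrough (planted, or the stop codon hit by a point
    # mutation): the mature extends to the next in-frame stop and the
    # amidation signal is no longer terminal
    ami <- detect_amidation(substring(protein, sig_n + pro_n + 1))
    mature <- ami$trimmed_mature
    amidated <- ami$amidated
    extra <- "stop_readthrough"
  } else if (nchar(protein) < prot_len) {
    # premature stop (planted, or a sense codon mutated to a stop)
    ami <- detect_amidation(substring(protein, sig_n + pro_n + 1))
    mature <- ami$trimmed_mature
    amidated <- ami$amidated
    extra <- "premature_stop"
  }
  mass <- tryCatch(
    peptide_mass(mature, extract_framework(mature)$n_cys %/% 2, amidated),
    error = function(e) NA_real_)
  list(signal = signal, pro = pro, mature = mature, amidated = amidated,
       notation = extract_framework(mature)$notation, mass = mass,
       protein = protein, extra_anomalies = extra)
}
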