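# End-to-end orchestration: QC -> annotate -> cluster -> segment ->
# framework -> family -> mass, with a summary bundle, TSV/JSON outputs and
# arithmetic consistency checks.

#' Pipeline configuration
#'
#' All stage parameters with their package defaults. The effective
#' configuration is serialized into the run summary so that a run can be
#' reproduced exactly.
#'
#' @param qc_min_len Minimum EST insert length (strictly greater passes).
#' @param evalue_cutoff Annotation e-value cutoff.
#' @param min_orf_aa Minimum ORF length (aa).
#' @param cluster_min_overlap_nt,cluster_min_identity_pct Contig linkage
#'   thresholds.
#' @param max_pro_len,pqm_acidic Propeptide-scan parameters.
#' @param family_identity_pct,family_relaxed_pct,family_framework_max_dist
#'   Family linkage thresholds.
#' @param mass_tolerance_da Peak-match tolerance.
#' @param mass_scale `"average"` or `"monoisotopic"`.
#' @param name_prefix Toxin-name stem.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic; the seed matters when the inputs are generated).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(qc_min_len = 300, evalue_cutoff = 1e-5,
                            min_orf_aa = 25,
                            cluster_min_overlap_nt = 100,
                            cluster_min_identity_pct = 95,
                            max_pro_len = 40, pqm_acidic = c("E", "D"),
                            family_identity_pct = 40,
                            family_relaxed_pct = 25,
                            family_framework_max_dist = 1,
                            mass_tolerance_da = 2.0,
                            mass_scale = "average",
                            name_prefix = "Tx", seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full toxin-discovery pipeline
#'
#' Stages: EST quality filter; three-way annotation against the reference
#' set; per-category contig clustering; precursor segmentation, naming and
#' anomaly flagging for toxin-like ESTs; cysteine-framework extraction and
#' template assignment; family grouping; theoretical mature masses,
#' molecular-weight histogram and (when peak lists are given) MALDI peak
#' matching. Identity histograms of recovered matures against the bundled
#' toxin references mirror the usual cross-species homology summary.
#'
#' @param ests EST table ([est_records()]) or path to a FASTA file.
#' @param refs Reference set; default the bundled one.
#' @param peaklists Optional named list of peak-list data frames.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for TSV/FASTA/JSON outputs.
#' @param verbose Log stage progress via `message()`.
#' @return A `pipeline_result` list with elements `qc`, `annotations`,
#'   `clusters` (per category), `precursors`, `frameworks`, `families`,
#'   `masses`, `matches`, `summary` and `config`.
#' @export
run_pipeline <- function(ests, refs = load_reference_set(),
                         peaklists = NULL, config = pipeline_config(),
                         out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[venomtx] ", ...)
  if (is.character(ests)) {
    ests <- est_records(read_fasta(ests, "dna"), source = "library")
  }

  say("qc: ", nrow(ests), " ESTs in")
  qc <- qc_filter(ests, qc_min_len = config$qc_min_len)
  hq <- qc$passing
  say("qc: ", nrow(hq), " high-quality (insert > ", config$qc_min_len,
      " nt), ", nrow(qc$failing), " discarded")

  say("annotate: classifying against ", nrow(refs), " reference proteins")
  ann <- classify_ests(hq, refs, evalue_cutoff = config$evalue_cutoff,
                       min_orf_aa = config$min_orf_aa)
  cat_summary <- summarize_categories(ann)

  say("cluster: per-category contig clustering")
  proteins <- stats::setNames(ann$orf_protein, ann$est_id)
  clusters <- lapply(stats::setNames(nm = c("toxin_like", "cellular",
                                            "no_match")), function(cat) {
    sub <- hq[hq$id %in% ann$est_id[ann$category == cat], , drop = FALSE]
    cluster_ests(sub, min_overlap_nt = config$cluster_min_overlap_nt,
                 min_identity_pct = config$cluster_min_identity_pct,
                 proteins = proteins)
  })

  say("precursor: segmenting toxin-like precursors")
  tox_ann <- ann[ann$category == "toxin_like" &
                   !is.na(ann$orf_protein), , drop = FALSE]
  precursors <- NULL
  if (nrow(tox_ann)) {
    est_src <- stats::setNames(hq$source, hq$id)
    # stop anomalies are visible only against the other members of a contig
    memb <- lapply(clusters$toxin_like$clusters, `[[`, "member_est_ids")
    cluster_of <- stats::setNames(rep(names(memb), lengths(memb)),
                                  unlist(memb))
    seg <- do.call(rbind, lapply(seq_len(nrow(tox_ann)), function(i) {
      segment_precursor(tox_ann$orf_protein[i],
                        has_start = isTRUE(tox_ann$orf_has_start[i]),
                        has_stop = isTRUE(tox_ann$orf_has_stop[i]),
                        source = est_src[[tox_ann$est_id[i]]],
                        max_pro_len = config$max_pro_len,
                        acidic = config$pqm_acidic)
    }))
    seg$est_id <- tox_ann$est_id
    clone_no <- seq_len(nrow(seg))
    seg$name <- name_toxin(clone_no,
                           is_partial = seg$completeness != "full_length",
                           from_transcriptome =
                             est_src[seg$est_id] == "transcriptome",
                           prefix = config$name_prefix)
    for (ix in split(seq_len(nrow(seg)), cluster_of[seg$est_id])) {
      sn <- flag_stop_anomalies(seg$full_seq[ix])
      add <- which(nzchar(sn))
      if (length(add)) {
        j <- ix[add]
        seg$notes[j] <- ifelse(nzchar(seg$notes[j]),
                               paste(seg$notes[j], sn[add], sep = ";"),
                               sn[add])
      }
    }
    precursors <- seg
  }

  say("framework: cysteine frameworks and disulfide templates")
  frameworks <- NULL
  families <- NULL
  masses <- NULL
  mw_hist <- NULL
  id_hist <- NULL
  if (!is.null(precursors) && nrow(precursors)) {
    fw <- lapply(precursors$mature, extract_framework)
    frameworks <- data.frame(
      name = precursors$name,
      n_cys = vapply(fw, `[[`, 0L, "n_cys"),
      notation = vapply(fw, `[[`, "", "notation"),
      template_id = vapply(fw, assign_template, ""),
      stringsAsFactors = FALSE)
    frameworks$unpaired_cys <- frameworks$n_cys %% 2L == 1L
    reg <- disulfide_templates()
    pair_str <- vapply(reg, function(t)
      paste(sprintf("C%d-C%d", t$pairs[, 1], t$pairs[, 2]), collapse = ";"),
      character(1))
    names(pair_str) <- vapply(reg, `[[`, character(1), "id")
    frameworks$predicted_pairs <- ifelse(is.na(frameworks$template_id), "",
                                         pair_str[frameworks$template_id])

    say("family: grouping ", nrow(precursors), " precursors")
    families <- assign_families(
      data.frame(name = precursors$name, mature = precursors$mature,
                 notation = frameworks$notation, stringsAsFactors = FALSE),
      identity_threshold_pct = config$family_identity_pct,
      relaxed_threshold_pct = config$family_relaxed_pct,
      framework_max_dist = config$family_framework_max_dist)
    # family labels are positional; map each family to the reference
    # exemplar its members hit most often, without claiming equivalence
    hit_of <- stats::setNames(tox_ann$best_hit_id, tox_ann$est_id)
    fam_hit <- tapply(
      hit_of[precursors$est_id[match(families$name, precursors$name)]],
      families$family_label,
      function(h) {
        h <- h[!is.na(h)]
        if (!length(h)) NA_character_ else
          names(sort(table(h), decreasing = TRUE))[1]
      })
    families$nearest_reference <- unname(fam_hit[families$family_label])

    say("mass: theoretical mature masses")
    masses <- data.frame(
      name = precursors$name, mature = precursors$mature,
      n_disulfides = mapply(default_disulfides, frameworks$n_cys,
                            frameworks$template_id),
      amidated = precursors$amidated, stringsAsFactors = FALSE)
    masses$mass <- vapply(seq_len(nrow(masses)), function(i) {
      tryCatch(peptide_mass(masses$mature[i], masses$n_disulfides[i],
                            masses$amidated[i], scale = config$mass_scale),
               error = function(e) NA_real_)
    }, numeric(1))
    mw_hist <- mw_distribution(masses$mass[!is.na(masses$mass)])
    tox_refs <- refs[refs$category == "toxin", , drop = FALSE]
    uniq_mat <- unique(precursors$mature[nzchar(precursors$mature)])
    id_hist <- identity_histogram(uniq_mat, tox_refs)
  }

  matches <- NULL
  if (!is.null(peaklists) && !is.null(masses)) {
    say("mass: matching ", length(peaklists), " peak lists")
    cand <- stats::na.omit(data.frame(name = masses$name,
                                      mass = masses$mass,
                                      stringsAsFactors = FALSE))
    cand <- cand[!duplicated(round(cand$mass, 4)), , drop = FALSE]
    matches <- lapply(peaklists, match_peaks, candidates = cand,
                      tolerance_da = config$mass_tolerance_da)
  }

  nonredundant <- vapply(clusters, function(cs) {
    length(unique(unlist(lapply(cs$clusters, `[[`, "unique_protein_seqs"))))
  }, 1L)

  summary <- list(
    n_input = nrow(ests), n_high_quality = nrow(hq),
    n_failed_qc = nrow(qc$failing),
    categories = cat_summary,
    clusters = lapply(clusters, function(cs) {
      list(n_clusters = length(cs$clusters), n_singletons = cs$n_singletons,
           n_contigs = cs$n_contigs, bins = cs$bins)
    }),
    nonredundant_proteins = as.list(nonredundant),
    nonredundant_total = sum(nonredundant),
    identity_histogram = id_hist,
    mw_histogram = mw_hist,
    config = unclass(config))

  result <- structure(list(qc = qc, annotations = ann, clusters = clusters,
                           precursors = precursors, frameworks = frameworks,
                           families = families, masses = masses,
                           matches = matches, summary = summary,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write pipeline outputs to a directory
#'
#' Emits the annotation table, per-category cluster reports, precursor /
#' framework / family / mass tables, per-fraction match reports, the mature
#' peptides as protein FASTA and the run summary as JSON.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$annotations, file.path(out_dir, "annotations.tsv"))
  for (cat in names(result$clusters)) {
    cs <- result$clusters[[cat]]
    write_tsv(cs$table, file.path(out_dir, paste0("clusters_", cat, ".tsv")))
    write_tsv(cs$bins, file.path(out_dir, paste0("cluster_bins_", cat,
                                                 ".tsv")))
  }
  if (!is.null(result$precursors)) {
    write_tsv(result$precursors, file.path(out_dir, "precursors.tsv"))
    ok <- nzchar(result$precursors$mature)
    write_fasta(stats::setNames(result$precursors$mature[ok],
                                result$precursors$name[ok]),
                file.path(out_dir, "mature_peptides.fasta"))
  }
  if (!is.null(result$frameworks)) {
    write_tsv(result$frameworks, file.path(out_dir, "frameworks.tsv"))
  }
  if (!is.null(result$families)) {
    write_tsv(result$families, file.path(out_dir, "families.tsv"))
  }
  if (!is.null(result$masses)) {
    write_tsv(result$masses, file.path(out_dir, "masses.tsv"))
  }
  if (!is.null(result$summary$mw_histogram)) {
    write_tsv(result$summary$mw_histogram,
              file.path(out_dir, "mw_histogram.tsv"))
  }
  if (!is.null(result$summary$identity_histogram)) {
    write_tsv(result$summary$identity_histogram,
              file.path(out_dir, "identity_histogram.tsv"))
  }
  if (!is.null(result$matches)) {
    for (f in names(result$matches)) {
      write_tsv(result$matches[[f]],
                file.path(out_dir, paste0("matches_", f, ".tsv")))
    }
  }
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(out_dir)
}

#' Check the arithmetic consistency of a run summary
#'
#' Verifies the conservation identities a correct report must satisfy:
#' category counts sum to the total of high-quality ESTs; per category,
#' singletons plus contigs equal the number of clusters and per-bin EST
#' counts sum to the category total; non-redundant protein counts per
#' category sum to the reported total.
#'
#' @param summary The `summary` element of a `pipeline_result`, or any list
#'   with the same fields.
#' @return List with `pass` (logical) and `violations` (character vector
#'   naming each failed identity).
#' @export
summary_consistency_check <- function(summary) {
  v <- character(0)
  cat_n <- summary$categories$n
  if (length(cat_n) && sum(cat_n) != summary$n_high_quality) {
    v <- c(v, sprintf("category counts (%d) != total high-quality ESTs (%d)",
                      sum(cat_n), summary$n_high_quality))
  }
  for (cat in names(summary$clusters)) {
    cl <- summary$clusters[[cat]]
    if (cl$n_singletons + cl$n_contigs != cl$n_clusters) {
      v <- c(v, sprintf(
        "%s: singletons (%d) + contigs (%d) != clusters (%d)", cat,
        cl$n_singletons, cl$n_contigs, cl$n_clusters))
    }
    cat_total <- summary$categories$n[summary$categories$category == cat]
    if (length(cat_total) && sum(cl$bins$n_ests) != cat_total) {
      v <- c(v, sprintf("%s: per-bin EST counts (%d) != category total (%d)",
                        cat, sum(cl$bins$n_ests), cat_total))
    }
    if (sum(cl$bins$n_clusters) != cl$n_clusters) {
      v <- c(v, sprintf("%s: per-bin cluster counts (%d) != clusters (%d)",
                        cat, sum(cl$bins$n_clusters), cl$n_clusters))
    }
  }
  nr <- unlist(summary$nonredundant_proteins)
  if (length(nr) && !is.null(summary$nonredundant_total) &&
      sum(nr) != summary$nonredundant_total) {
    v <- c(v, sprintf(
      "non-redundant proteins per category (%d) != reported total (%d)",
      sum(nr), summary$nonredundant_total))
  }
  list(pass = length(v) == 0, violations = v)
}
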