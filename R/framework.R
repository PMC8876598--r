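# Cysteine frameworks in adjacency notation and disulfide-connectivity
# templates.

#' Extract the cysteine framework of a mature peptide
#'
#' The framework records the ordered cysteine positions and their adjacency
#' notation: consecutive labels are juxtaposed (`C3C4`) when the two
#' cysteines are sequence-adjacent and dash-separated (`C3-C4`) otherwise.
#'
#' @param mature Mature peptide string.
#' @return List of class `cys_framework` with `positions`, `n_cys` and
#'   `notation` (empty string when the peptide has no cysteine).
#' @examples
#' extract_framework("ACCA")$notation  # "C1C2"
#' @export
extract_framework <- function(mature) {
  res <- strsplit(mature, "", fixed = TRUE)[[1]]
  pos <- which(res == "C")
  structure(list(positions = pos, n_cys = length(pos),
                 notation = notation_from_positions(pos)),
            class = "cys_framework")
}

#' Build adjacency notation from cysteine positions
#' @param positions Strictly increasing 1-based cysteine positions.
#' @return The notation string.
#' @export
notation_from_positions <- function(positions) {
  n <- length(positions)
  if (n == 0) return("")
  parts <- paste0("C", seq_len(n))
  if (n == 1) return(parts)
  seps <- ifelse(diff(positions) == 1, "", "-")
  paste0(paste0(parts[-n], seps, collapse = ""), parts[n])
}

#' Parse adjacency notation into an adjacency signature
#'
#' @param notation A framework notation string such as `"C1-C2-C3C4-C5-C6"`.
#' @return List with `n_cys` and `adjacent` (logical vector of length
#'   `n_cys - 1`: is cysteine i sequence-adjacent to cysteine i+1?).
#' @export
parse_notation <- function(notation) {
  if (!nzchar(notation)) return(list(n_cys = 0L, adjacent = logical(0)))
  toks <- regmatches(notation, gregexpr("C[0-9]+-?", notation))[[1]]
  n <- length(toks)
  idx <- as.integer(sub("^C([0-9]+)-?$", "\\1", toks))
  if (!identical(idx, seq_len(n))) {
    stop("malformed framework notation: ", notation)
  }
  list(n_cys = n, adjacent = !grepl("-$", toks[-n]))
}

#' Bundled disulfide-connectivity templates
#'
#' Templates pair an adjacency notation with a known connectivity: the
#' inhibitor-cystine-knot (ICK) 6-cysteine mode (C1-C4, C2-C5, C3-C6), the
#' Kunitz mode (C1-C6, C2-C4, C3-C5), the disulfide-directed beta-hairpin
#' (DDH) mode (C1-C3, C2-C5, C4-C6), the MIT1-like 10-cysteine mode (C1-C4,
#' C2-C5, C3-C7, C6-C9, C8-C10), a second 10-cysteine mode with a distinct
#' spacing pattern (C1-C7, C2-C8, C3-C6, C4-C10, C5-C9) and an ICK-like
#' 8-cysteine mode (C1-C4, C2-C5, C3-C8, C6-C7).
#'
#' @return A list of templates, each with `id`, `n_cys`, `notation` and
#'   `pairs` (two-column matrix of cysteine indices).
#' @export
disulfide_templates <- function() {
  tmpl <- function(id, notation, pairs) {
    list(id = id, notation = notation,
         n_cys = parse_notation(notation)$n_cys,
         pairs = matrix(pairs, ncol = 2, byrow = TRUE))
  }
  list(
    tmpl("ICK-6", "C1-C2-C3C4-C5-C6", c(1, 4, 2, 5, 3, 6)),
    tmpl("Kunitz-6", "C1-C2-C3-C4-C5-C6", c(1, 6, 2, 4, 3, 5)),
    tmpl("DDH-6", "C1-C2-C3-C4-C5-C6", c(1, 3, 2, 5, 4, 6)),
    tmpl("MIT1-10", "C1-C2-C3C4-C5-C6-C7-C8-C9-C10",
         c(1, 4, 2, 5, 3, 7, 6, 9, 8, 10)),
    tmpl("familyB-10", "C1-C2-C3C4-C5-C6C7-C8-C9-C10",
         c(1, 7, 2, 8, 3, 6, 4, 10, 5, 9)),
    tmpl("ICK-like-8", "C1-C2-C3C4-C5-C6-C7-C8",
         c(1, 4, 2, 5, 3, 8, 6, 7))
  )
}

#' Assign a disulfide template to a framework
#'
#' Assignment keys on the full adjacency notation (two 10-cysteine
#' frameworks with different spacing patterns map to different templates).
#' No match, or an ambiguous notation matched by several templates (the
#' plain 6-cysteine notation is shared by the Kunitz and DDH connectivities,
#' which adjacency alone cannot distinguish), returns `NA`: connectivity is
#' never guessed.
#'
#' @param framework A `cys_framework` (or a notation string).
#' @param registry Template list, by default [disulfide_templates()].
#' @return The matching template id, or `NA`.
#' @export
assign_template <- function(framework, registry = disulfide_templates()) {
  notation <- if (inherits(framework, "cys_framework")) {
    framework$notation
  } else framework
  if (!nzchar(notation)) return(NA_character_)
  hits <- Filter(function(t) identical(t$notation, notation), registry)
  if (length(hits) != 1) return(NA_character_)
  hits[[1]]$id
}

#' Distance between two cysteine frameworks
#'
#' The Levenshtein edit distance between the adjacency signatures (one
#' symbol per inter-cysteine step, adjacent vs non-adjacent) plus the
#' absolute difference in cysteine counts. Zero exactly for identical
#' notations; symmetric; satisfies the triangle inequality.
#'
#' @param a,b `cys_framework` objects or notation strings.
#' @return Non-negative integer distance.
#' @export
framework_distance <- function(a, b) {
  sig <- function(x) {
    p <- parse_notation(if (inherits(x, "cys_framework")) x$notation else x)
    list(n = p$n_cys,
         s = paste(ifelse(p$adjacent, "J", "-"), collapse = ""))
  }
  sa <- sig(a); sb <- sig(b)
  as.integer(utils::adist(sa$s, sb$s)) + abs(sa$n - sb$n)
}
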