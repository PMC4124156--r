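# Ranking of residue-residue couplings into modeling restraints, with the
# exclusion rules used when turning top covarying pairs into distance
# constraints: pairs touching alignment indel columns, intrahelical pairs,
# and pairs whose membrane topology makes a contact geometrically
# impossible are dropped.

#' Top-ranked residue pairs of a coupling matrix
#'
#' @param cm a \code{coupling_matrix}
#' @param k number of pairs to keep (default 50)
#' @param min_separation minimum sequence separation |i - j| (default 0:
#'   neighbouring-residue pairs are kept and typically removed later by the
#'   intrahelical rule)
#' @return data frame of class \code{ranked_pairs}: res_i < res_j,
#'   strength, status (NA until \code{\link{apply_exclusions}}); ordered by
#'   strength descending, ties by (res_i, res_j) ascending
#' @export
select_top_pairs <- function(cm, k = 50L, min_separation = 0L) {
  stopifnot(inherits(cm, "coupling_matrix"))
  if (k < 1L) stop("k must be >= 1")
  if (min_separation < 0L) stop("min_separation must be >= 0")
  L <- length(cm$ref_map)
  iu <- which(upper.tri(cm$strengths), arr.ind = TRUE)
  res_i <- cm$ref_map[iu[, 1L]]
  res_j <- cm$ref_map[iu[, 2L]]
  keep <- abs(res_j - res_i) >= min_separation
  df <- data.frame(res_i = res_i[keep], res_j = res_j[keep],
                   strength = cm$strengths[iu][keep])
  df <- df[order(-df$strength, df$res_i, df$res_j), , drop = FALSE]
  if (k > nrow(df)) {
    warning("k exceeds available pairs; returning all ", nrow(df))
    k <- nrow(df)
  }
  df <- df[seq_len(k), , drop = FALSE]
  df$region_i <- NA_character_
  df$region_j <- NA_character_
  df$status <- NA_character_
  rownames(df) <- NULL
  class(df) <- c("ranked_pairs", "data.frame")
  df
}

#' Apply exclusion rules to ranked residue pairs
#'
#' Statuses are assigned in priority order: \code{indel} (either residue in
#' \code{indel_set}, or the partner residue is missing) beats
#' \code{intrahelical} (both residues in the same helical segment) beats
#' \code{topology_violation} beats \code{retained}. A topology violation is
#' declared when the membrane-depth assignment puts the two residues more
#' than \code{z_threshold} apart, or when both residues lie outside the
#' membrane on opposite sides. If \code{strict_labels} is given (one label
#' per pair, NA meaning "apply the rules"), those labels are honored
#' verbatim; this reproduces published exclusion calls whose quantitative
#' criterion is not part of the published record.
#'
#' @param pairs a \code{ranked_pairs} data frame (res_j may be NA for
#'   pairs whose partner falls in an alignment indel)
#' @param ha a \code{helix_annotation} covering all residues
#' @param indel_set integer residues flagged as alignment indel columns
#' @param depth optional named numeric vector: membrane z (Angstrom) per
#'   residue (cytoplasmic side negative)
#' @param z_threshold maximum compatible |z_i - z_j| (default 12)
#' @param strict_labels optional character vector of printed statuses
#' @return the \code{ranked_pairs} with \code{region_i}, \code{region_j}
#'   and \code{status} filled in
#' @export
apply_exclusions <- function(pairs, ha, indel_set = integer(0), depth = NULL,
                             z_threshold = 12, strict_labels = NULL) {
  stopifnot(inherits(pairs, "ranked_pairs"), inherits(ha, "helix_annotation"))
  n <- nrow(pairs)
  if (!is.null(strict_labels) && length(strict_labels) != n)
    stop("strict_labels must have one entry per pair")
  seg_i <- segment_of(ha, pairs$res_i)
  seg_j <- rep(NA_character_, n)
  has_j <- !is.na(pairs$res_j)
  seg_j[has_j] <- segment_of(ha, pairs$res_j[has_j])
  pairs$region_i <- seg_i
  pairs$region_j <- seg_j
  kind_of <- function(seg) ha$kind[match(seg, ha$name)]
  side_of <- function(seg) ha$side[match(seg, ha$name)]
  status <- character(n)
  for (r in seq_len(n)) {
    if (!is.null(strict_labels) && !is.na(strict_labels[r])) {
      status[r] <- strict_labels[r]
      next
    }
    ri <- pairs$res_i[r]; rj <- pairs$res_j[r]
    if (is.na(rj) || ri %in% indel_set || rj %in% indel_set) {
      status[r] <- "indel"
    } else if (identical(seg_i[r], seg_j[r]) &&
               kind_of(seg_i[r]) %in% c("TM", "surface_helix")) {
      status[r] <- "intrahelical"
    } else {
      viol <- FALSE
      si <- side_of(seg_i[r]); sj <- side_of(seg_j[r])
      if (si != "membrane" && sj != "membrane" && si != sj) viol <- TRUE
      if (!viol && !is.null(depth)) {
        zi <- depth[as.character(ri)]; zj <- depth[as.character(rj)]
        if (is.na(zi) || is.na(zj))
          stop("no depth assignment for residue ",
               if (is.na(zi)) ri else rj)
        if (abs(zi - zj) > z_threshold) viol <- TRUE
      }
      status[r] <- if (viol) "topology_violation" else "retained"
    }
  }
  pairs$status <- status
  pairs
}

#' Distance restraint set from retained pairs
#'
#' @param pairs a \code{ranked_pairs} with statuses assigned
#' @param d_lo,d_hi distance bounds in Angstrom (default 0-8 between
#'   beta carbons, the community default for covariation contacts)
#' @param atom restrained atom, default \code{"CB"}
#' @return object of class \code{restraint_set}
#' @export
restraint_set <- function(pairs, d_lo = 0, d_hi = 8, atom = "CB") {
  stopifnot(inherits(pairs, "ranked_pairs"))
  if (anyNA(pairs$status)) stop("apply_exclusions first")
  keep <- pairs[pairs$status == "retained", , drop = FALSE]
  rownames(keep) <- NULL
  structure(list(pairs = keep, d_lo = d_lo, d_hi = d_hi, atom = atom),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint_set: %d %s-%s restraints, %.1f-%.1f Angstrom\n",
              nrow(x$pairs), x$atom, x$atom, x$d_lo, x$d_hi))
  invisible(x)
}

#' Write restraints in CASP-RR or TSV format
#'
#' CASP-RR records are \code{i j d_lo d_hi p}, 1-based reference residue
#' numbering. The probability column is the pair strength rescaled to
#' (0, 1] by the maximum strength (1 if strengths are absent).
#'
#' @param rs a \code{restraint_set}
#' @param path file path
#' @param format \code{"casp_rr"} or \code{"tsv"}
#' @export
write_restraints <- function(rs, path, format = c("casp_rr", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(rs, "restraint_set"))
  p <- rs$pairs
  if (nrow(p) == 0L) stop("empty restraint set")
  if (any(p$res_i == p$res_j)) stop("restraint with i = j")
  prob <- if (all(is.na(p$strength)) || max(p$strength, na.rm = TRUE) <= 0)
    rep(1, nrow(p)) else pmin(1, p$strength / max(p$strength, na.rm = TRUE))
  if (format == "casp_rr") {
    writeLines(sprintf("%d %d %g %g %.6f", p$res_i, p$res_j, rs$d_lo,
                       rs$d_hi, prob), path)
  } else {
    utils::write.table(cbind(p[, c("res_i", "res_j")],
                             d_lo = rs$d_lo, d_hi = rs$d_hi, prob = prob),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a CASP-RR restraint file
#' @param path file path
#' @return a \code{restraint_set} (statuses all \code{retained})
#' @export
read_restraints <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("res_i", "res_j", "d_lo", "d_hi",
                                         "prob"))
  if (nrow(tab) == 0L) stop("empty restraint file")
  df <- data.frame(res_i = as.integer(tab$res_i),
                   res_j = as.integer(tab$res_j),
                   strength = tab$prob, region_i = NA_character_,
                   region_j = NA_character_, status = "retained")
  class(df) <- c("ranked_pairs", "data.frame")
  structure(list(pairs = df, d_lo = tab$d_lo[1L], d_hi = tab$d_hi[1L],
                 atom = "CB"),
            class = "restraint_set")
}

#' Load a transcribed published pair table
#'
#' Reads a TSV with columns aa_i, res_i, region_i, aa_j, res_j, region_j,
#' d_model, d_ref, status_printed (empty res_j marks pairs whose partner
#' falls in an alignment indel; empty status_printed marks retained pairs)
#' into a \code{ranked_pairs} data frame plus the printed columns. Pairs
#' are ranked by table order (strength is set to a decreasing rank score).
#'
#' @param path TSV path; default: the packaged transcription of the
#'   published top-50 covariation pair table for E. coli YidC
#' @return list with elements \code{pairs} (a \code{ranked_pairs}),
#'   \code{printed_status} (character, NA = retained),
#'   \code{d_model}, \code{d_ref} (numeric, NA for excluded rows)
#' @export
read_pair_table <- function(path = system.file("extdata",
                                               "yidc_top50_pairs.tsv",
                                               package = "covhelix")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  n <- nrow(tab)
  df <- data.frame(res_i = as.integer(tab$res_i),
                   res_j = as.integer(tab$res_j),
                   strength = seq(n, 1) / n,
                   region_i = tab$region_i, region_j = tab$region_j,
                   status = NA_character_)
  class(df) <- c("ranked_pairs", "data.frame")
  printed <- tab$status_printed
  list(pairs = df, printed_status = printed,
       d_model = as.numeric(tab$d_model), d_ref = as.numeric(tab$d_ref),
       aa_i = tab$aa_i, aa_j = tab$aa_j)
}

#' Segment annotation for the conserved TM region of E. coli YidC
#'
#' Helix/loop segmentation (TM2-TM6 region, reference residue numbering)
#' used with the packaged pair table: five TM helices, the cytoplasmic
#' loop between TM2 and TM3 carrying the helical hairpin, and the
#' flanking loops and C-terminus.
#'
#' @return a \code{helix_annotation}
#' @export
yidc_segments <- function() {
  helix_annotation(
    name = c("TM2", "Loop2-3", "TM3", "Loop3-4", "TM4", "Loop4-5", "TM5",
             "Loop5-6", "TM6", "c-term"),
    start = c(350, 372, 420, 441, 463, 481, 497, 510, 514, 533),
    end   = c(371, 419, 440, 462, 480, 496, 509, 513, 532, 548),
    kind  = c("TM", "loop", "TM", "loop", "TM", "loop", "TM", "loop", "TM",
              "loop"),
    side  = c("membrane", "cytoplasmic", "membrane", "periplasmic",
              "membrane", "cytoplasmic", "membrane", "periplasmic",
              "membrane", "cytoplasmic"))
}
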