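#' Aligned multiple sequence alignment container
#'
#' Light container for a protein multiple sequence alignment used by the
#' coupling estimators. Sequences are stored as an n x L character matrix
#' (one row per sequence, one column per alignment column) together with a
#' column-to-reference-residue map.
#'
#' @param ali character matrix (n sequences x L columns) of single upper-case
#'   residues with gaps as "-".
#' @param labels character vector of per-sequence identifiers.
#' @param ref_map integer vector of length L mapping alignment columns to
#'   1-based reference residue numbers; must be strictly increasing.
#' @return An object of class \code{msa}.
#' @export
msa <- function(ali, labels = rownames(ali), ref_map = seq_len(ncol(ali))) {
  if (!is.matrix(ali) || !is.character(ali))
    stop("`ali` must be a character matrix")
  if (ncol(ali) < 2L) stop("alignment needs at least 2 columns")
  if (nrow(ali) < 2L) stop("alignment needs at least 2 sequences")
  if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(ali)))
  if (length(labels) != nrow(ali)) stop("one label per sequence required")
  ref_map <- as.integer(ref_map)
  if (length(ref_map) != ncol(ali)) stop("ref_map must have one entry per column")
  if (any(diff(ref_map) <= 0L)) stop("ref_map must be strictly increasing")
  structure(list(ali = ali, labels = labels, ref_map = ref_map),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (reference %d..%d)\n",
              nrow(x$ali), ncol(x$ali), min(x$ref_map), max(x$ref_map)))
  invisible(x)
}

#' Number of columns / sequences of an alignment
#' @param x an \code{msa}
#' @return integer
#' @export
msa_ncol <- function(x) ncol(x$ali)

#' @rdname msa_ncol
#' @export
msa_nseq <- function(x) nrow(x$ali)

# Normalize one aligned string: uppercase, '.' and unknown gap marks to '-'.
.norm_aligned <- function(s) {
  s <- toupper(s)
  gsub("[.~]", "-", s)
}

.strings_to_ali <- function(seqs, labels) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("format error: sequences have unequal aligned lengths (",
         paste(unique(lens), collapse = ", "), ")")
  ali <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(ali) <- labels
  ali
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA, A3M (lowercase insert states are removed so all
#' rows align on match columns) and Stockholm. Gap characters are
#' normalized to \code{-}.
#'
#' @param path file path.
#' @param format one of \code{"fasta"}, \code{"a3m"}, \code{"stockholm"};
#'   default guesses from the file extension, falling back to fasta.
#' @param ref_start reference residue number of the first alignment column
#'   (the ref map is \code{ref_start + 0:(L-1)}).
#' @return an \code{msa}.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "a3m", "stockholm"),
                     ref_start = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, a3m = "a3m", sto = "stockholm", stk = "stockholm",
                     "fasta")
  }
  if (format == "stockholm") {
    maln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- as.character(maln)
    labels <- names(seqs)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty-input error: no sequences in ", path)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop("format error: no FASTA headers in ", path)
    idx <- cumsum(hdr)
    labels <- sub("^>\\s*", "", lines[hdr])
    labels <- sub("\\s.*$", "", labels)
    seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                   function(x) paste(x, collapse = ""), character(1))
    if (format == "a3m") seqs <- gsub("[a-z]", "", seqs)
  }
  if (length(seqs) == 0L) stop("empty-input error: no sequences in ", path)
  if (length(seqs) < 2L) stop("alignment needs at least 2 sequences")
  seqs <- vapply(seqs, .norm_aligned, character(1), USE.NAMES = FALSE)
  ali <- .strings_to_ali(seqs, labels)
  L <- ncol(ali)
  msa(ali, labels, ref_map = ref_start + seq_len(L) - 1L)
}

#' Write an alignment as FASTA
#' @param x an \code{msa}
#' @param path output file
#' @export
write_msa <- function(x, path) {
  seqs <- apply(x$ali, 1L, paste, collapse = "")
  writeLines(paste0(">", x$labels, "\n", seqs), path)
  invisible(path)
}

# Pairwise identity between two character rows: matches over columns where
# both are non-gap; 0 if no such column.
.pair_identity <- function(a, b) {
  both <- a != "-" & b != "-"
  n <- sum(both)
  if (n == 0L) return(0)
  sum(a[both] == b[both]) / n
}

#' Greedy redundancy filter at a maximum pairwise identity
#'
#' A single pass in input order: a sequence is dropped if its pairwise
#' identity (matches over columns where both sequences are non-gap) with any
#' already-retained sequence exceeds \code{max_identity}. The retained set
#' keeps its original order.
#'
#' @param x an \code{msa}
#' @param max_identity fraction in (0, 1]; default 0.90.
#' @return filtered \code{msa}
#' @export
filter_redundancy <- function(x, max_identity = 0.90) {
  stopifnot(inherits(x, "msa"))
  if (!(max_identity > 0 && max_identity <= 1))
    stop("max_identity must be in (0, 1]")
  keep <- integer(0)
  for (i in seq_len(nrow(x$ali))) {
    red <- FALSE
    for (j in keep) {
      if (.pair_identity(x$ali[i, ], x$ali[j, ]) > max_identity) {
        red <- TRUE
        break
      }
    }
    if (!red) keep <- c(keep, i)
  }
  if (length(keep) < 2L)
    return(structure(list(ali = x$ali[keep, , drop = FALSE],
                          labels = x$labels[keep], ref_map = x$ref_map),
                     class = "msa"))
  msa(x$ali[keep, , drop = FALSE], x$labels[keep], x$ref_map)
}

#' Sequence weights by identity clustering
#'
#' Each sequence gets weight 1/m where m is the number of sequences (itself
#' included) with pairwise identity >= \code{identity}. Off by default in
#' \code{\link{compute_couplings}}.
#'
#' @param x an \code{msa}
#' @param identity clustering identity threshold, default 0.80.
#' @return numeric weight per sequence
#' @export
sequence_weights <- function(x, identity = 0.80) {
  n <- nrow(x$ali)
  m <- rep(1L, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (.pair_identity(x$ali[i, ], x$ali[j, ]) >= identity) {
          m[i] <- m[i] + 1L
          m[j] <- m[j] + 1L
        }
      }
    }
  }
  1 / m
}
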