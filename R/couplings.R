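# Residue-residue coupling strengths from an alignment.
#
# Two estimators: mutual information with average-product correction
# (mi_apc) and a regularized mean-field inverse-covariance coupling norm
# (mf_dca). Both return a symmetric non-negative L x L matrix with zero
# diagonal, indexed by reference residue numbers.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
.ALPHA21 <- c(.AA20, "-")

# Map a character alignment onto integer states 1..21 (21 = gap; every
# non-standard symbol is treated as a gap state).
.ali_states <- function(ali) {
  st <- match(ali, .ALPHA21)
  st[is.na(st)] <- 21L
  dim(st) <- dim(ali)
  st
}

#' Coupling-strength matrix
#'
#' @param strengths symmetric non-negative numeric matrix with zero
#'   diagonal.
#' @param ref_map integer reference residue numbers for the rows/columns.
#' @return object of class \code{coupling_matrix}
#' @export
coupling_matrix <- function(strengths, ref_map = seq_len(ncol(strengths))) {
  if (!is.matrix(strengths) || nrow(strengths) != ncol(strengths))
    stop("strengths must be a square matrix")
  if (any(!is.finite(strengths))) stop("strengths must be finite")
  if (max(abs(strengths - t(strengths))) > 1e-8) stop("strengths must be symmetric")
  if (any(strengths < 0)) stop("strengths must be non-negative")
  strengths <- (strengths + t(strengths)) / 2
  diag(strengths) <- 0
  ref_map <- as.integer(ref_map)
  if (length(ref_map) != ncol(strengths)) stop("ref_map length mismatch")
  if (any(diff(ref_map) <= 0L)) stop("ref_map must be strictly increasing")
  dimnames(strengths) <- list(ref_map, ref_map)
  structure(list(strengths = strengths, ref_map = ref_map),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("coupling_matrix: %d x %d (reference %d..%d), max %.4g\n",
              nrow(x$strengths), ncol(x$strengths),
              min(x$ref_map), max(x$ref_map), max(x$strengths)))
  invisible(x)
}

# Average-product correction. Row/overall means are taken over
# off-diagonal entries; negatives optionally clamped to zero.
.apc <- function(m, clamp = TRUE) {
  L <- nrow(m)
  if (L < 2L) return(m * 0)
  diag(m) <- NA
  rm <- rowMeans(m, na.rm = TRUE)
  om <- mean(m, na.rm = TRUE)
  corr <- if (om > 0) outer(rm, rm) / om else 0
  out <- m - corr
  diag(out) <- 0
  if (clamp) out[out < 0] <- 0
  out
}

# Weighted pair frequency table over 21 states for two state columns.
.pair_freq <- function(si, sj, w) {
  f <- matrix(0, 21L, 21L)
  tab <- tapply(w, list(factor(si, levels = 1:21), factor(sj, levels = 1:21)),
                sum)
  tab[is.na(tab)] <- 0
  f[] <- tab
  f / sum(w)
}

# Plug-in mutual information (nats) between two state columns.
.mi_pair <- function(si, sj, w) {
  f <- .pair_freq(si, sj, w)
  fi <- rowSums(f); fj <- colSums(f)
  nz <- f > 0
  sum(f[nz] * log(f[nz] / (fi[row(f)[nz]] * fj[col(f)[nz]])))
}

.mi_matrix <- function(st, w) {
  L <- ncol(st)
  m <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      m[i, j] <- m[j, i] <- .mi_pair(st[, i], st[, j], w)
    }
  }
  m
}

# Mean-field inverse-covariance couplings. Frequencies over 21 states with
# a small pseudocount; the gap state is the reference state dropped from
# the covariance, so C is 20L x 20L. Ridge-regularized with
# lambda = ridge * mean(diag(C)); couplings are the APC-corrected Frobenius
# norms of the zero-sum-gauge 20 x 20 blocks of -C^-1.
.mf_dca_matrix <- function(st, w, ridge = 0.5, pseudocount = 0.01) {
  L <- ncol(st)
  q <- 20L
  W <- sum(w)
  # single-site frequencies (21 states)
  f1 <- matrix(0, L, 21L)
  for (i in seq_len(L))
    f1[i, ] <- tapply(c(w, 0), factor(c(st[, i], 21L), levels = 1:21), sum,
                      default = 0) / W
  f1 <- (1 - pseudocount) * f1 + pseudocount / 21
  # covariance over the 20 amino-acid states
  idx <- function(i, a) (i - 1L) * q + a
  C <- matrix(0, L * q, L * q)
  for (i in seq_len(L)) {
    for (j in i:L) {
      if (i == j) {
        blk <- diag(f1[i, 1:q]) - tcrossprod(f1[i, 1:q])
      } else {
        fij <- .pair_freq(st[, i], st[, j], w)
        fij <- (1 - pseudocount) * fij + pseudocount / (21 * 21)
        blk <- fij[1:q, 1:q] - tcrossprod(f1[i, 1:q], f1[j, 1:q])
      }
      C[idx(i, 1L):idx(i, q), idx(j, 1L):idx(j, q)] <- blk
      if (i != j)
        C[idx(j, 1L):idx(j, q), idx(i, 1L):idx(i, q)] <- t(blk)
    }
  }
  lambda <- ridge * mean(diag(C))
  J <- -solve(C + diag(lambda, nrow(C)))
  m <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      blk <- J[idx(i, 1L):idx(i, q), idx(j, 1L):idx(j, q)]
      blk <- blk - outer(rowMeans(blk), rep(1, q)) -
        outer(rep(1, q), colMeans(blk)) + mean(blk)
      m[i, j] <- m[j, i] <- sqrt(sum(blk^2))
    }
  }
  m
}

#' Compute residue-residue coupling strengths
#'
#' \code{mi_apc} is plug-in mutual information with average-product
#' correction, negatives clamped to zero. \code{mf_dca} is a regularized
#' mean-field inverse-covariance estimator (gaps as 21st state, gap state
#' as covariance reference, Frobenius norm of the zero-sum-gauge 20 x 20
#' coupling blocks, then APC).
#'
#' Columns in which only a single symbol is observed get zero coupling to
#' every other column.
#'
#' @param x an \code{msa}
#' @param estimator \code{"mf_dca"} (default) or \code{"mi_apc"}
#' @param weight if TRUE, sequences are down-weighted by 80\%-identity
#'   clustering (\code{\link{sequence_weights}}); off by default.
#' @param ridge ridge multiplier for the mean-field estimator; the ridge
#'   added to the covariance is \code{ridge * mean(diag(C))}.
#' @param pseudocount frequency pseudocount for the mean-field estimator.
#' @return a \code{\link{coupling_matrix}}
#' @export
compute_couplings <- function(x, estimator = c("mf_dca", "mi_apc"),
                              weight = FALSE, ridge = 0.5,
                              pseudocount = 0.01) {
  stopifnot(inherits(x, "msa"))
  estimator <- match.arg(estimator)
  if (nrow(x$ali) < 2L || ncol(x$ali) < 2L)
    stop("need at least 2 sequences and 2 columns")
  st <- .ali_states(x$ali)
  w <- if (weight) sequence_weights(x) else rep(1, nrow(x$ali))
  m <- switch(estimator,
              mi_apc = .apc(.mi_matrix(st, w), clamp = TRUE),
              mf_dca = .apc(.mf_dca_matrix(st, w, ridge, pseudocount),
                            clamp = TRUE))
  mono <- apply(st, 2L, function(s) length(unique(s)) == 1L)
  m[mono, ] <- 0
  m[, mono] <- 0
  coupling_matrix(m, x$ref_map)
}

#' Write / read a coupling matrix as TSV
#'
#' The TSV carries a header row and first column of reference residue
#' numbers. Values are written with 17 significant digits so that
#' write-then-read reproduces the written decimal representation exactly.
#'
#' @param cm a \code{coupling_matrix}
#' @param path file path
#' @export
write_couplings <- function(cm, path) {
  stopifnot(inherits(cm, "coupling_matrix"))
  m <- cm$strengths
  txt <- apply(m, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  lines <- c(paste(c("res", cm$ref_map), collapse = "\t"),
             paste(cm$ref_map, txt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_couplings
#' @return \code{read_couplings}: a \code{coupling_matrix}
#' @export
read_couplings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ref <- as.integer(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(m) <- NULL
  hdr <- as.integer(colnames(tab)[-1L])
  if (!identical(hdr, ref)) stop("header/row reference numbers disagree")
  coupling_matrix(m, ref)
}
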