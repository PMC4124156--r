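# Structure-comparison geometry: Cbeta contact distances, Kabsch
# superposition RMSD over residue selections, smoothed C-alpha deviation
# profiles, and alignment-derived cross-species residue mappings.

#' Atomic structure container
#'
#' A minimal per-atom table: chain, residue number, residue name (3-letter),
#' atom name and coordinates. (chain, resno, elety) must be unique.
#'
#' @param atoms data frame with columns chain, resno, resid, elety, x, y, z
#' @return object of class \code{structure_coords}
#' @export
structure_coords <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms))) stop("atoms must have columns: ",
                                         paste(need, collapse = ", "))
  atoms <- as.data.frame(atoms[, need], stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) stop("duplicate (chain, resno, atom) records")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_coords")
}

#' @export
print.structure_coords <- function(x, ...) {
  cat(sprintf("structure_coords: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain,
                                                 x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read a PDB file into a structure
#'
#' ATOM records only; alternate locations resolved by highest occupancy,
#' ties by altloc label order (blank first, then 'A', 'B', ...).
#'
#' @param path PDB file path
#' @param chain optional chain to keep
#' @return a \code{structure_coords}
#' @export
read_structure_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno), ,
           drop = FALSE]
  structure_coords(data.frame(chain = at$chain, resno = at$resno,
                              resid = at$resid, elety = at$elety,
                              x = at$x, y = at$y, z = at$z,
                              stringsAsFactors = FALSE))
}

#' Write a structure as a PDB file
#' @param s a \code{structure_coords}
#' @param path file path
#' @export
write_structure_pdb <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain, eleno = seq_len(nrow(a)))
  invisible(path)
}

# coordinates of one atom; NULL if absent
.atom_xyz <- function(s, resno, elety, chain = NULL) {
  a <- s$atoms
  sel <- a$resno == resno & a$elety == elety
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) return(NULL)
  as.numeric(a[which(sel)[1L], c("x", "y", "z")])
}

.residue_name <- function(s, resno, chain = NULL) {
  a <- s$atoms
  sel <- a$resno == resno
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) return(NULL)
  a$resid[which(sel)[1L]]
}

#' Cbeta-Cbeta distance between two residues
#'
#' Glycine (no Cbeta) falls back to its C-alpha.
#'
#' @param s a \code{structure_coords}
#' @param res_i,res_j residue numbers
#' @param chain optional chain
#' @return distance in Angstrom
#' @export
cb_distance <- function(s, res_i, res_j, chain = NULL) {
  get_cb <- function(r) {
    nm <- .residue_name(s, r, chain)
    if (is.null(nm)) stop("missing residue ", r)
    xyz <- .atom_xyz(s, r, "CB", chain)
    if (is.null(xyz)) {
      if (nm != "GLY") stop("missing atom CB on residue ", r, " (", nm, ")")
      xyz <- .atom_xyz(s, r, "CA", chain)
      if (is.null(xyz)) stop("missing atom CA on glycine ", r)
    }
    xyz
  }
  sqrt(sum((get_cb(res_i) - get_cb(res_j))^2))
}

# Kabsch: proper-rotation least-squares superposition of x onto y
# (n x 3 matrices). Returns rotation R, translations, rmsd, and whether
# the determinant correction (reflection avoidance) triggered.
.kabsch <- function(x, y) {
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2L, mx); yc <- sweep(y, 2L, my)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  Dm <- diag(c(1, 1, d))
  R <- s$u %*% Dm %*% t(s$v) # applied as xc %*% R
  xr <- xc %*% R
  rmsd <- sqrt(mean(rowSums((xr - yc)^2)))
  list(R = R, center_x = mx, center_y = my,
       rmsd = rmsd, reflection_corrected = d < 0)
}

#' Least-squares rigid superposition RMSD (Kabsch)
#'
#' Superposes the mapped atoms of \code{a} onto \code{b} with the optimal
#' proper rotation and reports the residual RMSD.
#'
#' @param a,b \code{structure_coords}
#' @param mapping data frame with columns res_a, res_b (1:1 residue map)
#' @param atoms atom name selection, default \code{"CA"}
#' @param chain_a,chain_b optional chains
#' @return list: rmsd (Angstrom), R (3x3 rotation applied to centered a),
#'   center_a, center_b, reflection_corrected, n (mapped atoms used)
#' @export
superpose_rmsd <- function(a, b, mapping, atoms = "CA", chain_a = NULL,
                           chain_b = NULL) {
  if (nrow(mapping) < 3L) stop("need at least 3 mapped residues")
  xa <- NULL; xb <- NULL
  for (k in seq_len(nrow(mapping))) {
    for (ety in atoms) {
      pa <- .atom_xyz(a, mapping$res_a[k], ety, chain_a)
      pb <- .atom_xyz(b, mapping$res_b[k], ety, chain_b)
      if (is.null(pa) || is.null(pb)) next
      xa <- rbind(xa, pa); xb <- rbind(xb, pb)
    }
  }
  if (is.null(xa) || nrow(xa) < 3L)
    stop("fewer than 3 mapped atom pairs present in both structures")
  fit <- .kabsch(xa, xb)
  list(rmsd = fit$rmsd, R = fit$R, center_a = fit$center_x,
       center_b = fit$center_y,
       reflection_corrected = fit$reflection_corrected, n = nrow(xa))
}

#' Smoothed per-residue C-alpha deviation profile
#'
#' Superposes \code{a} onto \code{b} over the mapped C-alphas (unless
#' \code{superpose = FALSE}, in which case coordinates are taken as
#' already superposed), computes the per-mapped-residue C-alpha distance,
#' and applies a centered moving average of odd width \code{window}
#' (shrinking symmetrically at the edges).
#'
#' @inheritParams superpose_rmsd
#' @param window odd moving-average width; 1 returns raw distances
#' @param superpose superpose before measuring (default TRUE)
#' @return data frame: res_a, res_b, distance, smoothed
#' @export
smoothed_ca_profile <- function(a, b, mapping, window = 5L,
                                superpose = TRUE, chain_a = NULL,
                                chain_b = NULL) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  xa <- NULL; xb <- NULL; ok <- logical(nrow(mapping))
  for (k in seq_len(nrow(mapping))) {
    pa <- .atom_xyz(a, mapping$res_a[k], "CA", chain_a)
    pb <- .atom_xyz(b, mapping$res_b[k], "CA", chain_b)
    if (is.null(pa) || is.null(pb)) next
    xa <- rbind(xa, pa); xb <- rbind(xb, pb); ok[k] <- TRUE
  }
  if (superpose) {
    fit <- .kabsch(xa, xb)
    xa <- sweep(sweep(xa, 2L, fit$center_x) %*% fit$R, 2L,
                -fit$center_y)
  }
  d <- sqrt(rowSums((xa - xb)^2))
  n <- length(d)
  h <- (window - 1L) / 2L
  sm <- vapply(seq_len(n), function(k) {
    lo <- max(1L, k - h); hi <- min(n, k + h)
    mean(d[lo:hi])
  }, numeric(1))
  data.frame(res_a = mapping$res_a[ok], res_b = mapping$res_b[ok],
             distance = d, smoothed = sm)
}

#' Cbeta distance table over residue pairs
#'
#' One \code{\link{cb_distance}} per pair; failures are reported per row
#' (distance NA with the error message) without aborting the rest. The
#' mean over successful rows is attached as attribute \code{"mean"}.
#'
#' @param s a \code{structure_coords}
#' @param pairs data frame with columns res_i, res_j
#' @param chain optional chain
#' @return data frame res_i, res_j, distance, note
#' @export
pair_distance_table <- function(s, pairs, chain = NULL) {
  if (nrow(pairs) == 0L) stop("empty pair list")
  d <- numeric(nrow(pairs)); note <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    r <- tryCatch(cb_distance(s, pairs$res_i[k], pairs$res_j[k], chain),
                  error = function(e) conditionMessage(e))
    if (is.character(r)) {
      d[k] <- NA_real_; note[k] <- r
    } else {
      d[k] <- r; note[k] <- ""
    }
  }
  out <- data.frame(res_i = pairs$res_i, res_j = pairs$res_j, distance = d,
                    note = note, stringsAsFactors = FALSE)
  attr(out, "mean") <- mean(d, na.rm = TRUE)
  out
}

# 3-letter -> 1-letter amino acid code (X for unknowns)
.aa321 <- function(resid) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- map[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Sequence of a structure from its C-alpha records
#' @param s a \code{structure_coords}
#' @param chain optional chain
#' @return list: resno (integer), seq (1-letter character vector)
#' @export
structure_sequence <- function(s, chain = NULL) {
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  ca <- a[a$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  list(resno = ca$resno, seq = .aa321(ca$resid))
}

#' Residue mapping between two structures by global sequence alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11, gap extend 1)
#' of the C-alpha derived sequences; aligned non-gap positions become the
#' mapping. Optional residue-range restrictions (e.g. TM segments) are
#' applied per structure before reporting.
#'
#' @param a,b \code{structure_coords}
#' @param chain_a,chain_b optional chains
#' @param keep_a,keep_b optional integer residue numbers to keep (both
#'   residues of a mapped pair must be in their keep set)
#' @return data frame res_a, res_b
#' @export
align_residue_mapping <- function(a, b, chain_a = NULL, chain_b = NULL,
                                  keep_a = NULL, keep_b = NULL) {
  sa <- structure_sequence(a, chain_a)
  sb <- structure_sequence(b, chain_b)
  al <- Biostrings::pairwiseAlignment(
    paste(sa$seq, collapse = ""), paste(sb$seq, collapse = ""),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::subject(al)), "")[[1L]]
  ia <- 0L; ib <- 0L
  res_a <- integer(0); res_b <- integer(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && pb[k] != "-") {
      res_a <- c(res_a, sa$resno[ia])
      res_b <- c(res_b, sb$resno[ib])
    }
  }
  out <- data.frame(res_a = res_a, res_b = res_b)
  if (!is.null(keep_a)) out <- out[out$res_a %in% keep_a, , drop = FALSE]
  if (!is.null(keep_b)) out <- out[out$res_b %in% keep_b, , drop = FALSE]
  rownames(out) <- NULL
  out
}
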