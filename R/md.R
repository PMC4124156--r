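# Trajectory observables for a protein-bilayer system: leaflet-resolved
# membrane thickness maps, positional-variance flexibility (global motion
# included), geometric hydrogen bonds, height-resolved hydropathy, and
# local spatial smoothing of per-residue energies.

#' Bilayer trajectory container
#'
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom)
#' @param atoms data frame with columns resno, elety, role (one of
#'   \code{"phosphate_head"}, \code{"protein_backbone"},
#'   \code{"protein_other"}, \code{"other"}) and leaflet (\code{"upper"},
#'   \code{"lower"} or \code{"n/a"})
#' @param box optional per-frame box dimensions: matrix n_frames x 3 (or a
#'   length-3 vector recycled); used for minimum-image distances
#' @return object of class \code{bilayer_trajectory}
#' @export
bilayer_trajectory <- function(frames, atoms, box = NULL) {
  if (length(frames) == 0L) stop("no frames")
  n <- nrow(frames[[1L]])
  if (!all(vapply(frames, nrow, integer(1)) == n))
    stop("atom count must be constant across frames")
  if (nrow(atoms) != n) stop("atom metadata does not match frame size")
  if (!all(atoms$role %in% c("phosphate_head", "protein_backbone",
                             "protein_other", "other")))
    stop("unknown atom role")
  ph <- atoms$role == "phosphate_head"
  if (any(!atoms$leaflet[ph] %in% c("upper", "lower")))
    stop("every phosphate_head needs a leaflet")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = length(frames),
                                         ncol = 3L, byrow = TRUE)
    if (nrow(box) != length(frames)) stop("one box per frame required")
  }
  structure(list(frames = frames, atoms = atoms, box = box),
            class = "bilayer_trajectory")
}

#' @export
print.bilayer_trajectory <- function(x, ...) {
  cat(sprintf("bilayer_trajectory: %d frames x %d atoms (%d phosphates)\n",
              length(x$frames), nrow(x$atoms),
              sum(x$atoms$role == "phosphate_head")))
  invisible(x)
}

#' Read a multi-model PDB plus metadata table as a bilayer trajectory
#'
#' @param pdb_path multi-model PDB file
#' @param meta_path TSV with columns resno, elety, role, leaflet in atom
#'   order
#' @param box optional box dimensions (see \code{\link{bilayer_trajectory}})
#' @return a \code{bilayer_trajectory}
#' @export
read_trajectory_pdb <- function(pdb_path, meta_path, box = NULL) {
  pdb <- bio3d::read.pdb(pdb_path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  bilayer_trajectory(frames, meta, box)
}

# minimum-image displacement components given box lengths (NULL = none)
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - round(d / box) * box
}

# pairwise distances between rows of a (m x k) and b (n x k), optionally
# wrapped by the first k box lengths
.cross_dist <- function(a, b, box = NULL) {
  m <- nrow(a); n <- nrow(b); k <- ncol(a)
  out <- matrix(0, m, n)
  for (dim_ in seq_len(k)) {
    d <- outer(a[, dim_], b[, dim_], "-")
    if (!is.null(box)) d <- .min_image(d, box[dim_])
    out <- out + d^2
  }
  sqrt(out)
}

#' Time-averaged leaflet thickness map
#'
#' The membrane plane is binned into \code{bin} x \code{bin} Angstrom
#' cells. Per frame and per cell whose center has a same-leaflet phosphate
#' within \code{bin} Angstrom (in-plane), the thickness sample is the
#' minimum 3D distance from the nearest such phosphate to any phosphate of
#' the opposite leaflet. Samples are averaged over frames; cells without
#' occupancy are reported as NA, never zero.
#'
#' @param traj a \code{bilayer_trajectory}
#' @param bin grid bin size in Angstrom (default 2)
#' @param leaflet reference leaflet whose surface is probed
#' @param project_z if TRUE, use the |z| separation to the opposite
#'   leaflet instead of the 3D minimum distance
#' @return object of class \code{thickness_map}: x, y bin centers,
#'   \code{thickness} (matrix, NA where unoccupied), \code{occupancy}
#' @export
thickness_map <- function(traj, bin = 2, leaflet = c("upper", "lower"),
                          project_z = FALSE) {
  leaflet <- match.arg(leaflet)
  other <- if (leaflet == "upper") "lower" else "upper"
  ph <- traj$atoms$role == "phosphate_head"
  same_idx <- which(ph & traj$atoms$leaflet == leaflet)
  opp_idx <- which(ph & traj$atoms$leaflet == other)
  if (length(same_idx) == 0L || length(opp_idx) == 0L)
    stop("both leaflets must contain phosphate head groups")
  all_xy <- do.call(rbind, lapply(traj$frames, function(f)
    f[c(same_idx, opp_idx), 1:2, drop = FALSE]))
  xr <- range(all_xy[, 1L]); yr <- range(all_xy[, 2L])
  xc <- seq(xr[1L] + bin / 2, xr[2L], by = bin)
  yc <- seq(yr[1L] + bin / 2, yr[2L], by = bin)
  acc <- matrix(0, length(xc), length(yc))
  occ <- matrix(0L, length(xc), length(yc))
  for (fi in seq_along(traj$frames)) {
    f <- traj$frames[[fi]]
    box <- if (is.null(traj$box)) NULL else traj$box[fi, ]
    same <- f[same_idx, , drop = FALSE]
    opp <- f[opp_idx, , drop = FALSE]
    centers <- as.matrix(expand.grid(x = xc, y = yc))
    dxy <- .cross_dist(centers, same[, 1:2, drop = FALSE],
                       if (is.null(box)) NULL else box[1:2])
    nearest <- apply(dxy, 1L, which.min)
    near_d <- dxy[cbind(seq_len(nrow(dxy)), nearest)]
    hit <- near_d <= bin
    if (!any(hit)) next
    if (project_z) {
      th <- vapply(which(hit), function(ci) {
        min(abs(same[nearest[ci], 3L] - opp[, 3L]))
      }, numeric(1))
    } else {
      # in-plane wrap only: the slab separation must not be imaged in z
      d3 <- .cross_dist(same, opp,
                        if (is.null(box)) NULL else c(box[1:2], Inf))
      th <- apply(d3[nearest[hit], , drop = FALSE], 1L, min)
    }
    ij <- cbind(((which(hit) - 1L) %% length(xc)) + 1L,
                ((which(hit) - 1L) %/% length(xc)) + 1L)
    acc[ij] <- acc[ij] + th
    occ[ij] <- occ[ij] + 1L
  }
  thick <- acc / occ
  thick[occ == 0L] <- NA_real_
  structure(list(x = xc, y = yc, bin = bin, leaflet = leaflet,
                 thickness = thick, occupancy = occ),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf(
    "thickness_map (%s leaflet): %d x %d bins of %.1f A, range %.2f-%.2f A\n",
    x$leaflet, length(x$x), length(x$y), x$bin,
    min(x$thickness, na.rm = TRUE), max(x$thickness, na.rm = TRUE)))
  invisible(x)
}

#' Write a thickness map as a TSV grid
#' @param tm a \code{thickness_map}
#' @param path file path
#' @export
write_thickness_map <- function(tm, path) {
  m <- tm$thickness
  dimnames(m) <- list(sprintf("%.2f", tm$x), sprintf("%.2f", tm$y))
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Per-residue positional variance (flexibility)
#'
#' For each selected residue: the mean over its backbone atoms of the
#' time-variance of the atom position about its trajectory-mean position
#' (sum of the three coordinate variances, population normalization).
#' No superposition is applied first, so rigid-body displacements of the
#' helices contribute - this is deliberate and distinguishes the measure
#' from the usual RMSF.
#'
#' @param traj a \code{bilayer_trajectory}
#' @param selection integer residue numbers (default: all residues with
#'   protein_backbone atoms)
#' @param backbone atom names treated as backbone
#' @return data frame: resno, variance (Angstrom^2)
#' @export
positional_variance <- function(traj, selection = NULL,
                                backbone = c("N", "CA", "C", "O")) {
  if (length(traj$frames) < 2L) stop("need at least 2 frames")
  at <- traj$atoms
  bb <- which(at$role == "protein_backbone" & at$elety %in% backbone)
  if (is.null(selection)) selection <- sort(unique(at$resno[bb]))
  out <- data.frame(resno = selection, variance = NA_real_)
  nfr <- length(traj$frames)
  for (k in seq_along(selection)) {
    idx <- bb[at$resno[bb] == selection[k]]
    if (length(idx) == 0L)
      stop("no backbone atoms for residue ", selection[k])
    v <- vapply(idx, function(i) {
      xyz <- t(vapply(traj$frames, function(f) f[i, ], numeric(3)))
      sum(colMeans(xyz^2) - colMeans(xyz)^2)
    }, numeric(1))
    out$variance[k] <- mean(v)
  }
  out
}

#' Geometric hydrogen bond detection in one frame
#'
#' A donor-acceptor pair is reported iff the donor-heavy-atom to acceptor
#' distance is at most \code{max_dist} and the angle at the donor between
#' the D->H and D->A directions (deviation of H-D...A from linearity along
#' the hydrogen-donor axis) is at most \code{max_angle}. Both boundaries
#' are inclusive.
#'
#' @param frame n_atoms x 3 coordinate matrix
#' @param donors data frame with columns d (heavy atom row index) and h
#'   (bonded hydrogen row index)
#' @param acceptors integer acceptor row indices
#' @param max_dist distance cutoff in Angstrom (default 3.8)
#' @param max_angle angle cutoff in degrees (default 20)
#' @return data frame: donor, acceptor, dist, angle
#' @export
hydrogen_bonds <- function(frame, donors, acceptors, max_dist = 3.8,
                           max_angle = 20) {
  if (any(is.na(donors$h))) stop("donor lacking a bonded hydrogen")
  out <- NULL
  for (k in seq_len(nrow(donors))) {
    D <- frame[donors$d[k], ]; H <- frame[donors$h[k], ]
    dh <- H - D
    for (aidx in acceptors) {
      if (aidx == donors$d[k] || aidx == donors$h[k]) next
      A <- frame[aidx, ]
      da <- A - D
      dist <- sqrt(sum(da^2))
      if (dist > max_dist) next
      cosang <- sum(dh * da) / (sqrt(sum(dh^2)) * dist)
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang <= max_angle) {
        out <- rbind(out, data.frame(donor = donors$d[k], acceptor = aidx,
                                     dist = dist, angle = ang))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(donor = integer(0), acceptor = integer(0),
                      dist = numeric(0), angle = numeric(0))
  rownames(out) <- NULL
  out
}

# Kyte-Doolittle hydropathy index by 3-letter residue name
.KD <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
         GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
         LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
         SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

#' Height-resolved hydropathy profile
#'
#' Residues are binned by C-alpha z over \code{n_bins} equal slices of
#' [z_lo, z_hi]; residues below/above the range land in two overflow bins
#' (never dropped). A residue is hydrophobic iff its Kyte-Doolittle index
#' exceeds 0.
#'
#' @param s a \code{structure_coords}
#' @param membrane_z numeric (z_lo, z_hi) membrane slab bounds
#' @param n_bins number of in-slab bins (>= 1)
#' @return data frame: z_lo, z_hi, hydrophobic, hydrophilic (the first and
#'   last rows are the overflow bins with infinite bounds)
#' @export
hydropathy_height_profile <- function(s, membrane_z, n_bins = 10L) {
  if (membrane_z[1L] >= membrane_z[2L]) stop("need z_lo < z_hi")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  ca <- s$atoms[s$atoms$elety == "CA", , drop = FALSE]
  kd <- .KD[toupper(ca$resid)]
  kd[is.na(kd)] <- 0
  phob <- kd > 0
  edges <- seq(membrane_z[1L], membrane_z[2L], length.out = n_bins + 1L)
  idx <- findInterval(ca$z, edges, rightmost.closed = TRUE) # 0..n_bins+1?
  idx[ca$z < membrane_z[1L]] <- 0L
  idx[ca$z > membrane_z[2L]] <- n_bins + 1L
  lo <- c(-Inf, edges[-length(edges)], membrane_z[2L])
  hi <- c(membrane_z[1L], edges[-1L], Inf)
  out <- data.frame(z_lo = lo, z_hi = hi,
                    hydrophobic = 0L, hydrophilic = 0L)
  for (b in 0:(n_bins + 1L)) {
    sel <- idx == b
    out$hydrophobic[b + 1L] <- sum(phob & sel)
    out$hydrophilic[b + 1L] <- sum(!phob & sel)
  }
  out
}

#' Locally averaged per-residue energies
#'
#' Energies are first time-averaged per residue, then for every residue
#' replaced by the mean over all residues whose C-alpha lies within
#' \code{cutoff} Angstrom of its own C-alpha (inclusive; the residue
#' itself is always included).
#'
#' @param energy numeric matrix n_frames x n_residues with column names
#'   giving residue numbers (a single-row matrix is treated as already
#'   time-averaged)
#' @param s a \code{structure_coords} providing C-alpha positions
#' @param cutoff spatial smoothing cutoff in Angstrom (default 10)
#' @return data frame: resno, energy (time average), smoothed
#' @export
local_energy_average <- function(energy, s, cutoff = 10) {
  if (is.null(colnames(energy))) stop("energy needs residue column names")
  resno <- as.integer(colnames(energy))
  tavg <- colMeans(energy)
  ca <- s$atoms[s$atoms$elety == "CA", , drop = FALSE]
  pos <- match(resno, ca$resno)
  if (anyNA(pos))
    stop("residue ", resno[which(is.na(pos))[1L]],
         " missing a C-alpha in the structure")
  miss <- setdiff(ca$resno, resno)
  if (length(miss))
    stop("residue ", miss[1L], " missing from the energy series")
  xyz <- as.matrix(ca[pos, c("x", "y", "z")])
  d <- .cross_dist(xyz, xyz)
  sm <- vapply(seq_along(resno), function(k)
    mean(tavg[d[k, ] <= cutoff]), numeric(1))
  data.frame(resno = resno, energy = unname(tavg), smoothed = sm)
}
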