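# Ideal-helix bundle construction: 2D placement of helix axes from the
# predicted contact graph, azimuthal orientation from lipid/protein
# exposure labels, and backbone + Cbeta coordinates on ideal alpha-helix
# geometry (rise 1.5 A/residue, 100 degrees/residue twist).

.HELIX_RISE <- 1.5
.HELIX_TWIST <- 100 * pi / 180
.CA_RADIUS <- 2.30

# undirected connectivity check; returns list of components (by name)
.components <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- comp[edges[k, 1L]]; b <- comp[edges[k, 2L]]
    if (a != b) comp[comp == b] <- a
  }
  split(nodes, comp)
}

#' Place helix axes in the membrane plane from pairwise contacts
#'
#' Minimizes the stress
#' \code{sum_contacts (|p_a - p_b| - contact_distance)^2 +
#' sum_noncontacts max(0, contact_distance - |p_a - p_b|)^2}
#' by seeded multi-start BFGS (one circular-layout start plus random
#' starts). The result is gauge-fixed: centroid at the origin, the first
#' helix on the +x axis, and the y axis reflected so that the second helix
#' has y <= 0.
#'
#' @param helices character vector of helix names
#' @param contacts two-column matrix or data frame of contacting helix
#'   name pairs (e.g. predictions above a posterior cutoff)
#' @param contact_distance target axis-axis distance in Angstrom
#' @param n_starts number of random restarts
#' @param seed RNG seed for the restarts
#' @return data frame (class \code{helix_placement}): name, x, y; with the
#'   achieved stress in attribute \code{"stress"}
#' @export
place_helices <- function(helices, contacts, contact_distance = 10,
                          n_starts = 8L, seed = 1234L) {
  contacts <- as.matrix(contacts)[, 1:2, drop = FALSE]
  if (!all(contacts %in% helices)) stop("contacts name unknown helices")
  comps <- .components(helices, contacts)
  if (length(comps) > 1L)
    stop("contact graph is disconnected; components: ",
         paste(vapply(comps, paste, character(1), collapse = "+"),
               collapse = " | "))
  n <- length(helices)
  ci <- cbind(match(contacts[, 1L], helices), match(contacts[, 2L], helices))
  pairkey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  is_contact <- matrix(FALSE, n, n)
  is_contact[ci] <- TRUE
  is_contact <- is_contact | t(is_contact)
  noncon <- which(upper.tri(is_contact) & !is_contact, arr.ind = TRUE)
  con <- which(upper.tri(is_contact) & is_contact, arr.ind = TRUE)
  D <- contact_distance
  stress <- function(p) {
    xy <- matrix(p, ncol = 2L)
    s <- 0
    if (nrow(con)) {
      d <- sqrt(rowSums((xy[con[, 1L], , drop = FALSE] -
                           xy[con[, 2L], , drop = FALSE])^2))
      s <- s + sum((d - D)^2)
    }
    if (nrow(noncon)) {
      d <- sqrt(rowSums((xy[noncon[, 1L], , drop = FALSE] -
                           xy[noncon[, 2L], , drop = FALSE])^2))
      s <- s + sum(pmax(0, D - d)^2)
    }
    s
  }
  starts <- list(cbind(1.2 * D * cos(2 * pi * seq_len(n) / n),
                       1.2 * D * sin(2 * pi * seq_len(n) / n)))
  set.seed(seed)
  for (k in seq_len(n_starts))
    starts[[k + 1L]] <- matrix(stats::rnorm(2L * n, sd = D), ncol = 2L)
  best <- NULL; best_val <- Inf
  for (s0 in starts) {
    fit <- stats::optim(as.numeric(s0), stress, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best_val - 1e-9) {
      best_val <- fit$value
      best <- matrix(fit$par, ncol = 2L)
    }
  }
  # gauge fixing
  best <- sweep(best, 2L, colMeans(best))
  if (n >= 1L && sqrt(sum(best[1L, ]^2)) > 1e-9) {
    ang <- atan2(best[1L, 2L], best[1L, 1L])
    R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2L, 2L)
    best <- best %*% t(R)
  }
  if (n >= 2L && best[2L, 2L] > 1e-9) best[, 2L] <- -best[, 2L]
  out <- data.frame(name = helices, x = best[, 1L], y = best[, 2L],
                    stringsAsFactors = FALSE)
  attr(out, "stress") <- best_val
  class(out) <- c("helix_placement", "data.frame")
  out
}

#' Helix rotation phase from lipid/protein exposure labels
#'
#' With residue r's side chain pointing at azimuth
#' \code{phase + handed * twist * (r - start)}, the phase maximizing
#' \code{sum_lipid cos(theta_r) - sum_protein cos(theta_r)} (theta_r the
#' angle between the residue's radial direction and the outward direction
#' away from the bundle centroid) has the closed form
#' \code{phase = psi - Arg(sum_r s_r exp(i * handed * twist * (r - start)))}
#' with s_r = +1 for lipid, -1 for protein, psi the outward azimuth.
#'
#' @param residues integer residue numbers of the helix (N to C)
#' @param labels character vector over residues: \code{"lipid"},
#'   \code{"protein"} or \code{"unknown"}
#' @param origin_xy helix axis position (x, y)
#' @param centroid_xy bundle centroid (x, y), default origin
#' @param twist helical twist per residue in radians
#' @param handed +1 for a helix running cytoplasm->periplasm (+z), -1 for
#'   the opposite direction (azimuth progression reverses)
#' @return phase in radians (in (-pi, pi]); attribute
#'   \code{"degenerate"} is TRUE when the labels carry no net direction
#'   (phase 0 returned with a warning)
#' @export
orient_by_exposure <- function(residues, labels, origin_xy,
                               centroid_xy = c(0, 0),
                               twist = .HELIX_TWIST, handed = 1) {
  if (length(labels) != length(residues))
    stop("one label per residue required")
  s <- ifelse(labels == "lipid", 1, ifelse(labels == "protein", -1, 0))
  if (all(s == 0)) stop("no labelled residues on the helix")
  out_dir <- origin_xy - centroid_xy
  if (sqrt(sum(out_dir^2)) < 1e-9) out_dir <- c(1, 0)
  psi <- atan2(out_dir[2L], out_dir[1L])
  delta <- handed * twist * (residues - residues[1L])
  vsum <- sum(s * exp(1i * delta))
  if (Mod(vsum) < 1e-9) {
    warning("exposure labels are azimuthally uniform; phase is degenerate")
    return(structure(0, degenerate = TRUE))
  }
  ph <- (psi - Arg(vsum) + pi) %% (2 * pi) - pi
  structure(ph, degenerate = FALSE)
}

# Canonical ideal helix along +z for n residues, phase 0: returns a list of
# per-residue backbone atoms (N, CA, C, O, CB). Cylindrical placements for
# N and C approximate standard alpha-helix internal geometry; CB is rebuilt
# from N, CA, C with the standard tetrahedral construction.
.ideal_helix_atoms <- function(n, rise = .HELIX_RISE, twist = .HELIX_TWIST) {
  k <- seq_len(n) - 1L
  th <- k * twist
  z <- k * rise
  cyl <- function(r, dth, dz) cbind(r * cos(th + dth), r * sin(th + dth),
                                    z + dz)
  CA <- cyl(.CA_RADIUS, 0, 0)
  N <- cyl(1.60, -28 * pi / 180, -0.90)
  C <- cyl(1.65, 27 * pi / 180, 0.45)
  O <- C + matrix(rep(c(0, 0, 1.23), each = n), ncol = 3L)
  b <- CA - N
  c_ <- C - CA
  a <- cbind(b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L],
             b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L],
             b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  CB <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * c_ + CA
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

#' Build an ideal-helix bundle model
#'
#' Each TM segment becomes an ideal alpha helix (1.5 A/residue rise,
#' 100 degrees/residue twist, backbone N/CA/C/O plus tetrahedral Cbeta)
#' with its axis perpendicular to the membrane plane at the placed (x, y)
#' position, running +z (cytoplasm at -z) when its N terminus is
#' cytoplasmic and -z otherwise, rotated about its axis by the given
#' phase. The bundle is centered so the membrane mid-plane is z = 0.
#'
#' @param placement a \code{helix_placement} (name, x, y)
#' @param phases named numeric vector of phases (radians) per helix
#' @param ha a \code{helix_annotation} giving each helix's residue range
#' @param n_term_side named character vector per helix:
#'   \code{"cytoplasmic"} or \code{"periplasmic"} N-terminus
#' @return object of class \code{bundle_model}: \code{helices} (data frame
#'   with name, x, y, phase, dir, start, end) and \code{atoms} (data frame
#'   chain, resno, resid, elety, x, y, z)
#' @export
build_ideal_bundle <- function(placement, phases, ha, n_term_side) {
  stopifnot(inherits(placement, "helix_placement"))
  miss <- setdiff(placement$name, names(phases))
  if (length(miss)) stop("missing phase for helix: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(placement$name, names(n_term_side))
  if (length(miss)) stop("missing topology for helix: ",
                         paste(miss, collapse = ", "))
  atoms <- NULL
  hinfo <- placement
  hinfo$phase <- as.numeric(phases[placement$name])
  hinfo$dir <- ifelse(n_term_side[placement$name] == "cytoplasmic", 1, -1)
  hinfo$start <- NA_integer_; hinfo$end <- NA_integer_
  for (r in seq_len(nrow(placement))) {
    nm <- placement$name[r]
    res <- segment_residues(ha, nm)
    n <- length(res)
    hinfo$start[r] <- res[1L]; hinfo$end[r] <- res[n]
    at <- .ideal_helix_atoms(n)
    dir <- hinfo$dir[r]
    for (ety in names(at)) {
      xyz <- at[[ety]]
      if (dir < 0) { # proper rotation about x: (x, -y, -z)
        xyz[, 2L] <- -xyz[, 2L]
        xyz[, 3L] <- -xyz[, 3L]
      }
      at[[ety]] <- xyz
    }
    # rotate about z so residue 1's CB azimuth equals the phase, then
    # center the helix on the membrane mid-plane and translate to (x, y)
    cb1 <- at$CB[1L, ]
    rot <- hinfo$phase[r] - atan2(cb1[2L], cb1[1L])
    Rz <- matrix(c(cos(rot), sin(rot), 0, -sin(rot), cos(rot), 0, 0, 0, 1),
                 3L, 3L)
    zmid <- mean(range(at$CA[, 3L]))
    for (ety in names(at)) {
      xyz <- at[[ety]] %*% t(Rz)
      xyz[, 3L] <- xyz[, 3L] - zmid
      xyz[, 1L] <- xyz[, 1L] + placement$x[r]
      xyz[, 2L] <- xyz[, 2L] + placement$y[r]
      atoms <- rbind(atoms,
                     data.frame(chain = "A", resno = res, resid = "ALA",
                                elety = ety, x = xyz[, 1L], y = xyz[, 2L],
                                z = xyz[, 3L], helix = nm,
                                stringsAsFactors = FALSE))
    }
  }
  atoms <- atoms[order(atoms$resno,
                       match(atoms$elety, c("N", "CA", "C", "O", "CB"))), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(helices = hinfo, atoms = atoms), class = "bundle_model")
}

#' @export
print.bundle_model <- function(x, ...) {
  cat(sprintf("bundle_model: %d helices, %d atoms\n", nrow(x$helices),
              nrow(x$atoms)))
  invisible(x)
}

#' Convert a bundle model to a structure
#' @param bundle a \code{bundle_model}
#' @return a \code{\link{structure_coords}} object
#' @export
bundle_as_structure <- function(bundle) {
  structure_coords(bundle$atoms[, c("chain", "resno", "resid", "elety",
                                    "x", "y", "z")])
}

#' Write a bundle model as a single-model PDB file
#' @param bundle a \code{bundle_model}
#' @param path file path
#' @export
write_bundle_pdb <- function(bundle, path) {
  write_structure_pdb(bundle_as_structure(bundle), path)
}
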