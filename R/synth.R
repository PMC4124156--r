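# Seeded generators for every input the pipeline consumes: coupling
# matrices with planted periodic helix-interaction stripes, labelled
# helix-pair datasets for calibration, ideal helical bundles, and
# two-leaflet phosphate bilayers with a planted thinning depression.
# Every generator is a pure function of its parameter record (seed
# included): the same record reproduces the output bit-exactly.

#' Planted helix-interaction topology
#'
#' Parameter record for \code{\link{gen_coupling_matrix}}: a helix/loop
#' segmentation, the truly interacting helix pairs with orientation and
#' register, and the gamma strength models for planted (foreground) and
#' background cells. The defaults (background gamma(shape 1, scale 0.05),
#' foreground gamma(shape 4, scale 0.25) added on top at signal 1) put
#' planted-pair posteriors above the upper decision threshold and
#' background pairs below the lower one under the default detector.
#'
#' @param ha a \code{helix_annotation}
#' @param pairs data frame: helix_a, helix_b, orientation
#'   (\code{"parallel"}/\code{"antiparallel"}), register (integer offset of
#'   the stripe from the submatrix diagonal; 0 = in-register)
#' @param signal foreground multiplier; 0 plants nothing
#' @param periodicity stripe bump spacing in residues
#' @param fg_shape,fg_scale,bg_shape,bg_scale gamma parameters
#' @param seed RNG seed
#' @return object of class \code{planted_topology}
#' @export
planted_topology <- function(ha, pairs, signal = 1, periodicity = 3.5,
                             fg_shape = 4, fg_scale = 0.25,
                             bg_shape = 1, bg_scale = 0.05, seed = 1234L) {
  stopifnot(inherits(ha, "helix_annotation"))
  hel <- helices_of(ha)$name
  if (nrow(pairs) > 0L &&
      !all(c(pairs$helix_a, pairs$helix_b) %in% hel))
    stop("planted pairs must reference annotated helices")
  structure(list(ha = ha, pairs = pairs, signal = signal,
                 periodicity = periodicity,
                 fg = c(shape = fg_shape, scale = fg_scale),
                 bg = c(shape = bg_shape, scale = bg_scale),
                 seed = as.integer(seed)),
            class = "planted_topology")
}

# Residue index pairs of a periodic interface stripe inside an na x nb
# inter-helix block. Interface-facing positions recur every `periodicity`
# residues on each helix (positions whose distance to the periodic lattice
# is < periodicity / 4); a cell is planted when both residues face the
# interface and it lies within `band` residues of the register diagonal,
# giving the coherent diagonal (parallel) or anti-diagonal (antiparallel)
# stripe of periodicity-spaced contacts seen for real helix interfaces.
.stripe_cells <- function(na, nb, orientation, register, periodicity,
                          band = 1L) {
  facing <- function(n) {
    u <- seq_len(n) - 1L
    r <- u %% periodicity
    which(pmin(r, periodicity - r) < periodicity / 4)
  }
  fa <- facing(na)
  fb <- facing(nb)
  cells <- as.matrix(expand.grid(i = fa, j = fb))
  diag_off <- if (orientation == "parallel")
    cells[, 2L] - cells[, 1L] - register
  else
    cells[, 2L] - (nb - cells[, 1L] + 1L) - register
  cells <- cells[abs(diag_off) <= band, , drop = FALSE]
  if (nrow(cells) == 0L) NULL else cells
}

#' Synthetic coupling matrix with planted helix-pair stripes
#'
#' Background strengths are iid gamma draws; each planted pair receives a
#' periodic stripe of additional foreground gamma draws along its
#' register/orientation inside the inter-helix block. The matrix is
#' symmetric with zero diagonal.
#'
#' @param pt a \code{planted_topology}
#' @return a \code{coupling_matrix} covering the annotated residue range
#' @export
gen_coupling_matrix <- function(pt) {
  stopifnot(inherits(pt, "planted_topology"))
  ha <- pt$ha
  ref <- seq(min(ha$start), max(ha$end))
  L <- length(ref)
  set.seed(pt$seed)
  m <- matrix(0, L, L)
  iu <- upper.tri(m)
  m[iu] <- stats::rgamma(sum(iu), shape = pt$bg[["shape"]],
                         scale = pt$bg[["scale"]])
  if (pt$signal > 0 && nrow(pt$pairs) > 0L) {
    for (r in seq_len(nrow(pt$pairs))) {
      ra <- match(segment_residues(ha, pt$pairs$helix_a[r]), ref)
      rb <- match(segment_residues(ha, pt$pairs$helix_b[r]), ref)
      cells <- .stripe_cells(length(ra), length(rb),
                             pt$pairs$orientation[r],
                             pt$pairs$register[r], pt$periodicity)
      if (is.null(cells)) next
      fg <- pt$signal * stats::rgamma(nrow(cells),
                                      shape = pt$fg[["shape"]],
                                      scale = pt$fg[["scale"]])
      ii <- pmin(ra[cells[, 1L]], rb[cells[, 2L]])
      jj <- pmax(ra[cells[, 1L]], rb[cells[, 2L]])
      m[cbind(ii, jj)] <- m[cbind(ii, jj)] + fg
    }
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  coupling_matrix(m, ref)
}

#' Default synthetic membrane-protein annotation
#'
#' \code{n_helices} TM helices of \code{helix_len} residues separated by
#' loops of \code{loop_len} residues, loop sides alternating between the
#' cytoplasmic and periplasmic surface.
#'
#' @param n_helices number of TM helices
#' @param helix_len residues per helix
#' @param loop_len residues per loop
#' @return a \code{helix_annotation}
#' @export
gen_annotation <- function(n_helices = 7L, helix_len = 18L, loop_len = 4L) {
  name <- character(0); start <- integer(0); end <- integer(0)
  kind <- character(0); side <- character(0)
  pos <- 1L
  for (h in seq_len(n_helices)) {
    name <- c(name, paste0("H", h))
    start <- c(start, pos); end <- c(end, pos + helix_len - 1L)
    kind <- c(kind, "TM"); side <- c(side, "membrane")
    pos <- pos + helix_len
    if (h < n_helices) {
      name <- c(name, paste0("L", h))
      start <- c(start, pos); end <- c(end, pos + loop_len - 1L)
      kind <- c(kind, "loop")
      side <- c(side, if (h %% 2L == 1L) "cytoplasmic" else "periplasmic")
      pos <- pos + loop_len
    }
  }
  helix_annotation(name, start, end, kind, side)
}

#' Labelled helix-pair dataset for training and calibration
#'
#' Simulates \code{n_proteins} synthetic membrane proteins (random helix
#' counts, planted interactions), returning every unordered helix pair as
#' a labelled example. Used to fit strength distributions, optimize and
#' calibrate the detector end to end without any external dataset.
#'
#' @param n_proteins number of proteins
#' @param seed RNG seed
#' @param n_helices helices per protein (single value or range)
#' @param p_interact probability that a candidate pair is planted
#' @param signal foreground multiplier passed to the topology record
#' @param helix_len residues per helix
#' @return list of entries: cm (coupling matrix), ha (annotation), pairs
#'   (all unordered helix pairs with is_interacting labels)
#' @export
gen_labelled_helix_pairs <- function(n_proteins, seed = 1234L,
                                     n_helices = c(4L, 7L),
                                     p_interact = 0.3, signal = 1,
                                     helix_len = 18L) {
  if (n_proteins == 0L) return(list())
  set.seed(seed)
  out <- vector("list", n_proteins)
  for (p in seq_len(n_proteins)) {
    nh <- if (length(n_helices) > 1L)
      sample(seq(n_helices[1L], n_helices[2L]), 1L) else n_helices
    ha <- gen_annotation(nh, helix_len = helix_len)
    hel <- helices_of(ha)$name
    combos <- utils::combn(hel, 2L)
    planted <- stats::runif(ncol(combos)) < p_interact
    pairs <- data.frame(
      helix_a = combos[1L, planted], helix_b = combos[2L, planted],
      orientation = sample(c("parallel", "antiparallel"),
                           sum(planted), replace = TRUE),
      register = sample(-2:2, sum(planted), replace = TRUE),
      stringsAsFactors = FALSE)
    pt <- planted_topology(ha, pairs, signal = signal,
                           seed = sample.int(2^31 - 1L, 1L))
    cm <- gen_coupling_matrix(pt)
    lab <- data.frame(helix_a = combos[1L, ], helix_b = combos[2L, ],
                      is_interacting = planted, stringsAsFactors = FALSE)
    out[[p]] <- list(cm = cm, ha = ha, pairs = lab)
  }
  out
}

#' Synthetic two-leaflet phosphate bilayer trajectory
#'
#' Phosphate head groups on a square in-plane grid form two flat slabs at
#' z = +/- slab_sep / 2. An optional Gaussian depression thins the bilayer
#' symmetrically: each leaflet is displaced toward the mid-plane by
#' \code{depth / 2 * exp(-r^2 / (2 sigma^2))} around the given center, so
#' the planted total thinning at the center equals \code{depth}. Per-frame
#' isotropic Gaussian jitter is added to every phosphate.
#'
#' @param n_frames number of frames
#' @param slab_sep unperturbed slab separation in Angstrom (default 38)
#' @param depression NULL or list(depth, sigma, center = c(x, y))
#' @param jitter per-coordinate Gaussian jitter sd in Angstrom
#' @param seed RNG seed
#' @param extent in-plane half-width of the patch (Angstrom)
#' @param spacing in-plane phosphate grid spacing (Angstrom)
#' @return a \code{bilayer_trajectory}
#' @export
gen_bilayer_trajectory <- function(n_frames, slab_sep = 38,
                                   depression = NULL, jitter = 0,
                                   seed = 1234L, extent = 50,
                                   spacing = 8) {
  g <- seq(-extent, extent, by = spacing)
  xy <- as.matrix(expand.grid(x = g, y = g))
  n_side <- nrow(xy)
  zup <- rep(slab_sep / 2, n_side)
  zlo <- rep(-slab_sep / 2, n_side)
  if (!is.null(depression)) {
    r2 <- (xy[, 1L] - depression$center[1L])^2 +
      (xy[, 2L] - depression$center[2L])^2
    dz <- depression$depth / 2 * exp(-r2 / (2 * depression$sigma^2))
    zup <- zup - dz
    zlo <- zlo + dz
  }
  base <- rbind(cbind(xy, zup), cbind(xy, zlo))
  atoms <- data.frame(resno = seq_len(2L * n_side), elety = "P",
                      role = "phosphate_head",
                      leaflet = rep(c("upper", "lower"), each = n_side),
                      stringsAsFactors = FALSE)
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    base + if (jitter > 0)
      matrix(stats::rnorm(length(base), sd = jitter), nrow(base)) else 0
  })
  bilayer_trajectory(frames, atoms)
}

#' Ideal toy helix bundle
#'
#' Builds \code{n_helices} ideal helices via the bundle-construction
#' primitives, arranged on a regular polygon with side length
#' \code{contact_distance} (a single helix sits at the origin), all phases
#' pointing outward from the bundle center.
#'
#' @param n_helices number of helices
#' @param arrangement \code{"polygon"} or \code{"line"}
#' @param seed placement RNG seed (the polygon itself is deterministic)
#' @param helix_len residues per helix
#' @param contact_distance adjacent axis-axis distance in Angstrom
#' @return list: bundle (a \code{bundle_model}), structure
#'   (a \code{structure_coords}), ha (the annotation used)
#' @export
gen_toy_bundle <- function(n_helices, arrangement = c("polygon", "line"),
                           seed = 1234L, helix_len = 18L,
                           contact_distance = 10) {
  arrangement <- match.arg(arrangement)
  ha <- gen_annotation(n_helices, helix_len = helix_len)
  hel <- helices_of(ha)$name
  if (arrangement == "polygon" && n_helices > 1L) {
    rad <- if (n_helices == 2L) contact_distance / 2 else
      contact_distance / (2 * sin(pi / n_helices))
    ang <- -2 * pi * (seq_len(n_helices) - 1L) / n_helices
    xy <- cbind(rad * cos(ang), rad * sin(ang))
  } else if (arrangement == "line") {
    xy <- cbind((seq_len(n_helices) - 1L) * contact_distance, 0)
  } else {
    xy <- matrix(0, 1L, 2L)
  }
  xy <- sweep(xy, 2L, colMeans(xy))
  placement <- data.frame(name = hel, x = xy[, 1L], y = xy[, 2L],
                          stringsAsFactors = FALSE)
  class(placement) <- c("helix_placement", "data.frame")
  phases <- stats::setNames(atan2(xy[, 2L], xy[, 1L]), hel)
  phases[!is.finite(phases)] <- 0
  side <- rep(c("cytoplasmic", "periplasmic"),
              length.out = n_helices)
  bundle <- build_ideal_bundle(placement, phases, ha,
                               stats::setNames(side, hel))
  list(bundle = bundle, structure = bundle_as_structure(bundle), ha = ha)
}
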