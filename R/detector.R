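# Helix-helix interaction detector.
#
# A square weighted pattern that encodes the ~3.5-residue periodicity of a
# helical interface is slid over the inter-helix block of the coupling
# matrix. At each pattern position Bayes' rule converts the per-cell
# coupling strengths into a raw interaction probability via weighted
# log-likelihood ratios under gamma strength models for interacting and
# non-interacting residue pairs; evidence is aggregated over positions and
# the raw score is mapped to a posterior by a fitted monotone calibration
# curve.

#' Periodicity-aware square pattern template
#'
#' The parallel grid carries cosine ridges along diagonals: writing a
#' cell's offset from the pattern center in diagonal coordinates
#' (\code{o = u - v} selecting the diagonal, \code{s = (u + v) / 2} the
#' position along it), the weight is
#' \code{max(0, cos(2*pi*d(o)/periodicity)) *
#' max(0, cos(2*pi*d(s)/periodicity))} with \code{d(.)} the distance to
#' the nearest multiple of the periodicity. Ridges therefore sit on the
#' main diagonal and on diagonals every ~3.5 cells to either side, with
#' bumps recurring every ~3.5 cells along each ridge (the helical-turn
#' spacing). Weights are scaled so the absolute weights sum to 1. The
#' antiparallel grid is the parallel grid with row order reversed, turning
#' the ridges onto the anti-diagonals.
#'
#' @param size odd pattern side length (cells); default 17 (289 cells).
#' @param periodicity residues per helical turn; default 3.5.
#' @return object of class \code{pattern_template} with elements
#'   \code{size}, \code{periodicity}, \code{parallel}, \code{antiparallel}.
#' @export
build_pattern_template <- function(size = 17L, periodicity = 3.5) {
  size <- as.integer(size)
  if (size %% 2L == 0L || size < 3L) stop("size must be odd and >= 3")
  if (!(periodicity > 2)) stop("periodicity must exceed 2")
  h <- (size - 1L) / 2L
  off <- seq(-h, h)
  dmod <- function(u) {
    r <- abs(u) %% periodicity
    pmin(r, periodicity - r)
  }
  # diagonal coordinates: o = u - v indexes the ridge diagonal (ridges
  # recur every `periodicity` in offset), s = (u + v) / 2 the position
  # along it (interface bumps recur every `periodicity` along the ridge)
  o <- outer(off, off, "-")
  s <- outer(off, off, "+") / 2
  w <- pmax(cos(2 * pi * dmod(o) / periodicity), 0) *
    pmax(cos(2 * pi * dmod(s) / periodicity), 0)
  w <- w / sum(abs(w))
  structure(list(size = size, periodicity = periodicity,
                 parallel = w, antiparallel = w[size:1, , drop = FALSE]),
            class = "pattern_template")
}

#' @export
print.pattern_template <- function(x, ...) {
  cat(sprintf("pattern_template: %d x %d cells, periodicity %.2f\n",
              x$size, x$size, x$periodicity))
  invisible(x)
}

#' Gamma strength models for interacting and background residue pairs
#'
#' Fits two-parameter gamma densities by maximum likelihood to the coupling
#' strengths observed at interacting (foreground) and non-interacting
#' (background) residue pairs, and stores the prior probability of a
#' helix-helix interaction. Strengths are floored at \code{eps} before
#' fitting and evaluation (exact zeros arise from clamping and padding).
#'
#' @param strength numeric coupling strengths
#' @param is_interacting logical labels, same length
#' @param prior prior interaction probability in (0, 1)
#' @param eps positive floor applied to strengths
#' @return object of class \code{strength_dists} with gamma parameters
#'   \code{fg}, \code{bg} (shape, rate), \code{prior} and \code{eps}
#' @export
fit_strength_distributions <- function(strength, is_interacting, prior = 0.5,
                                       eps = 1e-6) {
  if (!(prior > 0 && prior < 1)) stop("prior must be in (0, 1)")
  if (!any(is_interacting) || !all(is.finite(strength)))
    stop("both classes must be non-empty and strengths finite")
  if (all(is_interacting)) stop("both classes must be non-empty")
  fitg <- function(x, what) {
    x <- pmax(x, eps)
    if (stats::sd(x) < 1e-12)
      stop("fit error: zero-variance ", what, " strengths")
    fit <- MASS::fitdistr(x, "gamma",
                          start = list(shape = max(mean(x)^2 / stats::var(x),
                                                   1e-3),
                                       rate = max(mean(x) / stats::var(x),
                                                  1e-3)),
                          lower = c(1e-6, 1e-6))
    fit$estimate
  }
  structure(list(fg = fitg(strength[is_interacting], "interacting"),
                 bg = fitg(strength[!is_interacting], "background"),
                 prior = prior, eps = eps),
            class = "strength_dists")
}

#' Construct strength models from known gamma parameters
#' @param fg_shape,fg_rate,bg_shape,bg_rate gamma parameters
#' @param prior prior interaction probability
#' @param eps strength floor
#' @return a \code{strength_dists}
#' @export
strength_dists <- function(fg_shape, fg_rate, bg_shape, bg_rate,
                           prior = 0.5, eps = 1e-6) {
  if (!(prior > 0 && prior < 1)) stop("prior must be in (0, 1)")
  structure(list(fg = c(shape = fg_shape, rate = fg_rate),
                 bg = c(shape = bg_shape, rate = bg_rate),
                 prior = prior, eps = eps),
            class = "strength_dists")
}

# Per-strength log-likelihood ratio log fg(s) - log bg(s).
.llr <- function(s, dists) {
  s <- pmax(s, dists$eps)
  stats::dgamma(s, dists$fg[["shape"]], dists$fg[["rate"]], log = TRUE) -
    stats::dgamma(s, dists$bg[["shape"]], dists$bg[["rate"]], log = TRUE)
}

#' Raw interaction probability of one pattern window
#'
#' Bayes' rule with per-cell weighted log-likelihood ratios:
#' \code{logit(p) = logit(prior) + sum(w * (log fg(s) - log bg(s)))}.
#'
#' @param window size x size matrix of coupling strengths
#' @param template a \code{pattern_template}
#' @param dists a \code{strength_dists}
#' @param orientation \code{"parallel"} or \code{"antiparallel"}
#' @return probability in [0, 1]
#' @export
raw_window_probability <- function(window, template, dists,
                                   orientation = c("parallel",
                                                   "antiparallel")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(window) || any(dim(window) != template$size))
    stop("window shape must equal the template size")
  if (any(!is.finite(window))) stop("non-finite strengths in window")
  w <- template[[orientation]]
  z <- stats::qlogis(dists$prior) + sum(w * .llr(window, dists))
  stats::plogis(z)
}

#' Scan one helix pair for an interaction
#'
#' Extracts the inter-helix submatrix (rows: first helix N->C, columns:
#' second helix N->C), evaluates \code{\link{raw_window_probability}} with
#' the window centered at every submatrix position for both orientations
#' (overhanging cells are zero-padded), and aggregates over positions.
#'
#' @param cm a \code{coupling_matrix}
#' @param ha a \code{helix_annotation}
#' @param pair character vector of two distinct helix names
#' @param template a \code{pattern_template}
#' @param dists a \code{strength_dists}
#' @param aggregate \code{"max"} (default: a contact at some register) or
#'   \code{"logsumexp"} (soft aggregation of the position logits)
#' @return object of class \code{helix_pair_prediction}: helix_a, helix_b,
#'   orientation, best_offset (residue pair at the best window center),
#'   raw_score, posterior (NA until calibrated)
#' @export
scan_helix_pair <- function(cm, ha, pair, template, dists,
                            aggregate = c("max", "logsumexp")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(cm, "coupling_matrix"), inherits(ha, "helix_annotation"))
  if (length(pair) != 2L || pair[1L] == pair[2L])
    stop("pair must name two distinct helices")
  res_a <- segment_residues(ha, pair[1L])
  res_b <- segment_residues(ha, pair[2L])
  if (length(res_a) < 3L || length(res_b) < 3L)
    stop("helices must have at least 3 residues")
  ia <- match(res_a, cm$ref_map)
  ib <- match(res_b, cm$ref_map)
  if (anyNA(ia) || anyNA(ib))
    stop("helix residues missing from the coupling matrix")
  S <- cm$strengths[ia, ib, drop = FALSE]
  size <- template$size
  h <- (size - 1L) / 2L
  na <- nrow(S); nb <- ncol(S)
  P <- matrix(0, na + 2L * h, nb + 2L * h)
  P[(h + 1L):(h + na), (h + 1L):(h + nb)] <- S
  LP <- .llr(P, dists)
  # padded zeros contribute the (constant) background-typical evidence of a
  # zero strength, matching raw_window_probability on an explicit window
  z0 <- stats::qlogis(dists$prior)
  zs <- array(NA_real_, c(na, nb, 2L),
              dimnames = list(NULL, NULL, c("parallel", "antiparallel")))
  for (oi in c("parallel", "antiparallel")) {
    w <- template[[oi]]
    for (i in seq_len(na)) {
      rows <- i:(i + 2L * h)
      for (j in seq_len(nb)) {
        zs[i, j, oi] <- z0 + sum(w * LP[rows, j:(j + 2L * h)])
      }
    }
  }
  # ties resolved toward the earlier orientation, then smaller (i, j)
  best_flat <- which(zs == max(zs), arr.ind = TRUE)[1L, ]
  best_pos <- best_flat[1:2]
  best_orient <- c("parallel", "antiparallel")[best_flat[3L]]
  raw <- if (aggregate == "max") {
    stats::plogis(max(zs))
  } else {
    m <- max(zs)
    stats::plogis(m + log(mean(exp(zs - m))))
  }
  structure(list(helix_a = pair[1L], helix_b = pair[2L],
                 orientation = best_orient,
                 best_offset = c(res_a[best_pos[1L]], res_b[best_pos[2L]]),
                 raw_score = raw, posterior = NA_real_),
            class = "helix_pair_prediction")
}

#' @export
print.helix_pair_prediction <- function(x, ...) {
  cat(sprintf("%s--%s (%s) raw %.3f posterior %s at offset (%d, %d)\n",
              x$helix_a, x$helix_b, x$orientation, x$raw_score,
              ifelse(is.na(x$posterior), "NA", sprintf("%.3f", x$posterior)),
              x$best_offset[1L], x$best_offset[2L]))
  invisible(x)
}

#' Fit a monotone four-parameter calibration curve
#'
#' \code{cal(r) = a + (b - a) * plogis(c * (logit(r) - d))} fitted by
#' Bernoulli maximum likelihood on the unbinned labels, with
#' \code{0 <= a <= b <= 1} and \code{c > 0} enforced by reparameterization.
#' Binning (default 60 predictions per bin, ordered by raw score) is used
#' only for the reliability diagnostic returned alongside the fit.
#'
#' @param raw_score raw probabilities in (0, 1)
#' @param is_interacting logical labels
#' @param bin_size predictions per diagnostic bin
#' @param source_weight weight used when averaging several calibrations
#'   (defaults to the number of observations)
#' @return object of class \code{calibration_model} with \code{params}
#'   (a, b, c, d), \code{bin_size}, \code{source_weight} and the binned
#'   diagnostic table \code{reliability}
#' @export
fit_calibration <- function(raw_score, is_interacting, bin_size = 60L,
                            source_weight = length(raw_score)) {
  y <- as.integer(is_interacting)
  n <- length(raw_score)
  if (n < 2L * bin_size)
    stop("need at least 2 * bin_size predictions to calibrate")
  if (length(unique(y)) < 2L)
    stop("fit error: calibration labels are all one class")
  r <- pmin(pmax(raw_score, 1e-9), 1 - 1e-9)
  lr <- stats::qlogis(r)
  unpack <- function(th) {
    a <- stats::plogis(th[1L])
    b <- a + (1 - a) * stats::plogis(th[2L])
    c(a = a, b = b, c = exp(th[3L]), d = th[4L])
  }
  nll <- function(th) {
    p <- unpack(th)
    cal <- p[1L] + (p[2L] - p[1L]) * stats::plogis(p[3L] * (lr - p[4L]))
    cal <- pmin(pmax(cal, 1e-12), 1 - 1e-12)
    -sum(y * log(cal) + (1 - y) * log(1 - cal))
  }
  # data-driven multi-start: the transition location d and slope c are
  # poorly identified from a fixed origin when the raw scores concentrate
  # away from logit 0
  s_lr <- max(stats::sd(lr), 1e-3)
  starts <- expand.grid(d0 = stats::quantile(lr, c(0.25, 0.5, 0.75)),
                        c0 = c(1 / s_lr, 4 / s_lr, 1))
  fit <- NULL
  for (k in seq_len(nrow(starts))) {
    cand <- stats::optim(c(stats::qlogis(0.05), stats::qlogis(0.9473),
                           log(starts$c0[k]), starts$d0[k]),
                         nll, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12))
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  params <- unpack(fit$par)
  names(params) <- c("a", "b", "c", "d")
  ord <- order(r)
  bins <- split(ord, ceiling(seq_along(ord) / bin_size))
  reliability <- data.frame(
    raw_mean = vapply(bins, function(i) mean(r[i]), numeric(1)),
    empirical = vapply(bins, function(i) mean(y[i]), numeric(1)),
    n = vapply(bins, length, integer(1)))
  structure(list(params = params, bin_size = as.integer(bin_size),
                 source_weight = source_weight, reliability = reliability,
                 convergence = fit$convergence),
            class = "calibration_model")
}

#' Evaluate a calibration curve
#' @param model a \code{calibration_model} (or the function returned by
#'   \code{\link{combine_calibrations}})
#' @param raw raw probabilities
#' @return calibrated probabilities in [0, 1]
#' @export
calibrate <- function(model, raw) {
  if (is.function(model)) return(model(raw))
  p <- model$params
  r <- pmin(pmax(raw, 1e-9), 1 - 1e-9)
  unname(p[["a"]] + (p[["b"]] - p[["a"]]) *
           stats::plogis(p[["c"]] * (stats::qlogis(r) - p[["d"]])))
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "calibration_model: a=%.3f b=%.3f c=%.3f d=%.3f (weight %g)\n",
    x$params[["a"]], x$params[["b"]], x$params[["c"]], x$params[["d"]],
    x$source_weight))
  invisible(x)
}

#' Size-weighted average of calibration curves
#'
#' Returns \code{r -> sum(w_i * cal_i(r)) / sum(w_i)} with weights taken
#' from each model's \code{source_weight}.
#'
#' @param models list of \code{calibration_model}s
#' @return a function of the raw score
#' @export
combine_calibrations <- function(models) {
  if (length(models) == 0L) stop("need at least one calibration model")
  w <- vapply(models, function(m) m$source_weight, numeric(1))
  if (any(w <= 0)) stop("source weights must be positive")
  function(raw) {
    vals <- vapply(models, function(m) calibrate(m, raw),
                   numeric(length(raw)))
    if (length(raw) == 1L) vals <- matrix(vals, nrow = 1L)
    as.numeric(vals %*% w / sum(w))
  }
}

#' Predict all unordered helix pairs
#'
#' Runs \code{\link{scan_helix_pair}} on every unordered pair of helical
#' segments and calibrates the raw scores. The result is sorted by
#' posterior (descending), ties broken by (helix_a, helix_b) names.
#'
#' @inheritParams scan_helix_pair
#' @param calibration a \code{calibration_model}, a combined calibration
#'   function, or NULL (posteriors equal raw scores)
#' @return data frame of class \code{helix_pair_predictions}: helix_a,
#'   helix_b, orientation, best_offset_i, best_offset_j, raw_score,
#'   posterior
#' @export
predict_all_pairs <- function(cm, ha, template, dists, calibration = NULL,
                              aggregate = "max") {
  hel <- helices_of(ha)
  if (nrow(hel) < 2L) stop("need at least 2 helices")
  combos <- utils::combn(hel$name, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    p <- scan_helix_pair(cm, ha, combos[, k], template, dists,
                         aggregate = aggregate)
    data.frame(helix_a = p$helix_a, helix_b = p$helix_b,
               orientation = p$orientation,
               best_offset_i = p$best_offset[1L],
               best_offset_j = p$best_offset[2L],
               raw_score = p$raw_score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$posterior <- if (is.null(calibration)) out$raw_score else
    calibrate(calibration, out$raw_score)
  out <- out[order(-out$posterior, out$helix_a, out$helix_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("helix_pair_predictions", "data.frame")
  out
}

#' Write helix-pair predictions as TSV
#' @param pred a \code{helix_pair_predictions} data frame
#' @param path file path
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(as.data.frame(unclass(pred)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
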