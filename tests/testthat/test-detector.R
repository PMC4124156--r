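test_that("default pattern template has 289 cells with periodic ridges", {
  tp <- build_pattern_template()
  expect_equal(length(tp$parallel), 289L)
  expect_equal(sum(abs(tp$parallel)), 1)
  # ridge bumps along the main diagonal recur every 3-4 cells (the
  # incommensurate 3.5-residue period alternates between the two)
  dw <- diag(tp$parallel)
  pos <- which(dw > 0)
  cluster_id <- cumsum(c(1L, diff(pos) > 1L))
  centers <- vapply(split(pos, cluster_id), mean, numeric(1))
  expect_true(all(round(diff(centers)) %in% c(3L, 4L)))
  expect_gte(length(centers), 4L)
  # antiparallel grid is exactly the row-reversed parallel grid
  expect_identical(tp$antiparallel, tp$parallel[tp$size:1, ])
  expect_error(build_pattern_template(size = 16L), "odd")
})

test_that("gamma strength models are recovered from samples", {
  set.seed(88)
  fg <- rgamma(1e4, shape = 4, scale = 0.1)
  bg <- rgamma(1e4, shape = 1, scale = 0.05)
  d <- fit_strength_distributions(c(fg, bg),
                                  rep(c(TRUE, FALSE), each = 1e4),
                                  prior = 0.4)
  expect_lt(abs(d$fg[["shape"]] - 4) / 4, 0.1)
  expect_lt(abs(1 / d$fg[["rate"]] - 0.1) / 0.1, 0.1)
  expect_lt(abs(d$bg[["shape"]] - 1), 0.1)
  expect_lt(abs(1 / d$bg[["rate"]] - 0.05) / 0.05, 0.1)
  expect_equal(d$prior, 0.4)
  expect_error(fit_strength_distributions(rep(c(0.2, 0.5), c(50, 50)),
                                          rep(c(TRUE, FALSE), each = 50)),
               "zero-variance")
})

test_that("window probability equals the prior under identical models", {
  tp <- build_pattern_template(5L)
  d <- strength_dists(2, 10, 2, 10, prior = 0.37)
  w <- matrix(runif(25), 5L)
  expect_equal(raw_window_probability(w, tp, d, "parallel"), 0.37)
  expect_equal(raw_window_probability(w, tp, d, "antiparallel"), 0.37)
})

test_that("window probability matches a longhand Bayes oracle", {
  tp <- build_pattern_template(3L, periodicity = 2.5)
  d <- strength_dists(4, 8, 1.2, 15, prior = 0.2, eps = 1e-6)
  set.seed(9)
  win <- matrix(rgamma(9, 2, 10), 3L)
  # independent longhand computation over the 9 cells:
  # p = pi * prod(fg^w) / (pi * prod(fg^w) + (1 - pi) * prod(bg^w))
  w <- tp$parallel
  fg <- dgamma(pmax(win, 1e-6), 4, 8)
  bg <- dgamma(pmax(win, 1e-6), 1.2, 15)
  num <- 0.2 * prod(fg^w)
  den <- num + 0.8 * prod(bg^w)
  expect_equal(raw_window_probability(win, tp, d, "parallel"), num / den,
               tolerance = 1e-12)
  expect_error(raw_window_probability(matrix(NA_real_, 3, 3), tp, d),
               "finite")
  expect_error(raw_window_probability(matrix(1, 5, 5), tp, d), "shape")
})

test_that("a window saturated at the foreground mode is near-certain", {
  tp <- build_pattern_template(17L)
  d <- strength_dists(4, 4, 1, 20, prior = 0.3)
  mode_fg <- (4 - 1) / 4
  win <- matrix(mode_fg, 17L, 17L)
  expect_gt(raw_window_probability(win, tp, d, "parallel"), 0.99)
})

test_that("a planted anti-diagonal stripe is found at the right register", {
  ha <- helix_annotation(c("A", "B"), c(1L, 25L), c(20L, 44L),
                         c("TM", "TM"), c("membrane", "membrane"))
  L <- 44L
  m <- matrix(0.01, L, L)
  # periodic anti-diagonal stripe centered on the block center (10, 34):
  # interface bumps every ~3.5 residues along the anti-diagonal
  for (k in round(seq(-7, 7, by = 3.5))) {
    i <- 10L + k; j <- 34L - k
    m[i, j] <- m[j, i] <- 1
  }
  diag(m) <- 0
  cm <- coupling_matrix((m + t(m)) / 2)
  tp <- build_pattern_template()
  d <- default_test_dists()
  p <- scan_helix_pair(cm, ha, c("A", "B"), tp, d)
  expect_equal(p$orientation, "antiparallel")
  # the best window center lies on the planted anti-diagonal register
  expect_equal(sum(p$best_offset), 44)
  expect_true(abs(p$best_offset[1L] - 10L) <= 4L)
})

test_that("scanning an all-zero matrix reduces to the zero-window value", {
  ha <- helix_annotation(c("A", "B"), c(1L, 25L), c(20L, 44L),
                         c("TM", "TM"), c("membrane", "membrane"))
  cm <- coupling_matrix(matrix(0, 44L, 44L))
  tp <- build_pattern_template()
  d <- default_test_dists()
  p <- scan_helix_pair(cm, ha, c("A", "B"), tp, d)
  zero_win <- raw_window_probability(matrix(0, 17L, 17L), tp, d, "parallel")
  expect_equal(p$raw_score, zero_win)
  expect_lte(p$raw_score, d$prior)
})

test_that("the raw score only depends on the inter-helix submatrix", {
  ha <- gen_annotation(4L)
  truth <- data.frame(helix_a = "H1", helix_b = "H2",
                      orientation = "parallel", register = 0L)
  cm <- gen_coupling_matrix(planted_topology(ha, truth, seed = 3L))
  tp <- build_pattern_template()
  d <- default_test_dists()
  base <- scan_helix_pair(cm, ha, c("H1", "H2"), tp, d)
  # perturb couplings between H3 and H4 only
  r3 <- match(segment_residues(ha, "H3"), cm$ref_map)
  r4 <- match(segment_residues(ha, "H4"), cm$ref_map)
  cm$strengths[r3, r4] <- cm$strengths[r3, r4] + 5
  cm$strengths[r4, r3] <- t(cm$strengths[r3, r4])
  pert <- scan_helix_pair(cm, ha, c("H1", "H2"), tp, d)
  expect_identical(pert$raw_score, base$raw_score)
})

test_that("raising a coupling under a positive template weight never
           lowers the raw score", {
  ha <- gen_annotation(3L)
  truth <- data.frame(helix_a = "H1", helix_b = "H2",
                      orientation = "parallel", register = 0L)
  cm <- gen_coupling_matrix(planted_topology(ha, truth, seed = 5L))
  tp <- build_pattern_template()
  d <- default_test_dists() # fg stochastically larger, increasing LLR
  base <- scan_helix_pair(cm, ha, c("H1", "H2"), tp, d)
  # the best-offset center cell has the template's maximal weight
  i <- match(base$best_offset[1L], cm$ref_map)
  j <- match(base$best_offset[2L], cm$ref_map)
  for (bump in c(0.1, 0.5, 2)) {
    cm2 <- cm
    cm2$strengths[i, j] <- cm2$strengths[i, j] + bump
    cm2$strengths[j, i] <- cm2$strengths[i, j]
    p2 <- scan_helix_pair(cm2, ha, c("H1", "H2"), tp, d)
    expect_gte(p2$raw_score, base$raw_score)
  }
})

test_that("calibration recovers planted curve parameters", {
  set.seed(5)
  n <- 5000L
  r <- plogis(rnorm(n, 0, 2))
  truth <- c(a = 0.02, b = 0.95, c = 1.5, d = 0)
  cal_true <- truth[["a"]] + (truth[["b"]] - truth[["a"]]) *
    plogis(truth[["c"]] * (qlogis(r) - truth[["d"]]))
  y <- runif(n) < cal_true
  fit <- fit_calibration(r, y, bin_size = 60L)
  expect_lt(abs(fit$params[["a"]] - truth[["a"]]), 0.05)
  expect_lt(abs(fit$params[["b"]] - truth[["b"]]), 0.05)
  expect_lt(abs(fit$params[["c"]] - truth[["c"]]) / truth[["c"]], 0.15)
  expect_lt(abs(fit$params[["d"]] - truth[["d"]]), 0.15)
})

test_that("perfectly calibrated scores give a near-identity curve", {
  set.seed(6)
  r <- runif(4000, 0.02, 0.98)
  y <- runif(4000) < r
  fit <- fit_calibration(r, y)
  grid <- seq(0.1, 0.9, length.out = 50)
  expect_lt(max(abs(calibrate(fit, grid) - grid)), 0.05)
})

test_that("fitted calibration curves are monotone and bounded", {
  set.seed(7)
  r <- plogis(rnorm(3000, 0, 1.5))
  y <- runif(3000) < plogis(2 * qlogis(r))
  fit <- fit_calibration(r, y)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 1000)
  vals <- calibrate(fit, grid)
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(fit_calibration(r[1:200], rep(TRUE, 200)), "one class")
  expect_error(fit_calibration(r[1:100], y[1:100]), "bin_size")
})

test_that("calibration averaging is weighted by dataset size", {
  const_model <- function(level, weight) {
    structure(list(params = c(a = level, b = level, c = 1, d = 0),
                   bin_size = 60L, source_weight = weight),
              class = "calibration_model")
  }
  m2 <- const_model(0.2, 204)
  m3 <- const_model(0.8, 85)
  comb <- combine_calibrations(list(m2, m3))
  expect_equal(comb(c(0.1, 0.5, 0.9)),
               rep((204 * 0.2 + 85 * 0.8) / 289, 3), tolerance = 1e-12)
  one <- combine_calibrations(list(m2))
  expect_equal(one(0.4), calibrate(m2, 0.4))
  twin <- combine_calibrations(list(m3, m3))
  expect_equal(twin(0.4), calibrate(m3, 0.4))
  expect_error(combine_calibrations(list()), "at least one")
})

test_that("seven helices give 21 ranked pair predictions", {
  truth <- seven_helix_truth()
  cm <- gen_coupling_matrix(planted_topology(truth$ha, truth$pairs,
                                             seed = 17L))
  tp <- build_pattern_template()
  d <- default_test_dists()
  pred <- predict_all_pairs(cm, truth$ha, tp, d)
  expect_equal(nrow(pred), 21L)
  expect_true(all(pred$posterior >= 0 & pred$posterior <= 1))
  expect_true(all(diff(pred$posterior) <= 1e-12))
  planted <- pair_key(truth$pairs$helix_a, truth$pairs$helix_b)
  expect_setequal(pair_key(pred$helix_a, pred$helix_b)[1:7], planted)
})

test_that("relabeling helices permutes but never changes scores", {
  truth <- seven_helix_truth()
  cm <- gen_coupling_matrix(planted_topology(truth$ha, truth$pairs,
                                             seed = 19L))
  tp <- build_pattern_template()
  d <- default_test_dists()
  base <- predict_all_pairs(cm, truth$ha, tp, d)
  relabel <- truth$ha
  relabel$name <- sub("^H", "helix", relabel$name)
  ren <- predict_all_pairs(cm, relabel, tp, d)
  key0 <- pair_key(base$helix_a, base$helix_b)
  key1 <- gsub("helix", "H", pair_key(ren$helix_a, ren$helix_b))
  expect_equal(stats::setNames(ren$raw_score, key1)[key0],
               stats::setNames(base$raw_score, key0),
               ignore_attr = TRUE)
})

test_that("posterior histograms are bimodal on planted systems", {
  truth <- seven_helix_truth()
  tp <- build_pattern_template()
  train <- gen_labelled_helix_pairs(15L, seed = 210L)
  tr <- training_strengths(train)
  d <- fit_strength_distributions(tr$strength, tr$label, prior = 0.3)
  calset <- gen_labelled_helix_pairs(25L, seed = 211L)
  sc <- detector_scores(calset, tp, d)
  cal <- fit_calibration(sc$raw, sc$label)
  planted <- pair_key(truth$pairs$helix_a, truth$pairs$helix_b)
  for (seed in 1:5) {
    cm <- gen_coupling_matrix(planted_topology(truth$ha, truth$pairs,
                                               seed = 300L + seed))
    pred <- predict_all_pairs(cm, truth$ha, tp, d, calibration = cal)
    is_planted <- pair_key(pred$helix_a, pred$helix_b) %in% planted
    expect_true(all(pred$posterior[is_planted] > 0.5))
    expect_true(all(pred$posterior[!is_planted] < 0.2))
  }
})
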