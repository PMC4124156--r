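flat_bilayer <- function(sep, n_frames = 1L, jitter = 0, seed = 1L) {
  gen_bilayer_trajectory(n_frames, slab_sep = sep, depression = NULL,
                         jitter = jitter, seed = seed, extent = 30,
                         spacing = 6)
}

test_that("flat slabs give a uniform thickness map", {
  tm <- thickness_map(flat_bilayer(38), bin = 2)
  vals <- tm$thickness[tm$occupancy > 0]
  expect_gt(length(vals), 100L)
  expect_true(all(abs(vals - 38) <= 1e-6))
  expect_true(all(is.na(tm$thickness[tm$occupancy == 0L])))
})

test_that("thickness averages across frames", {
  t30 <- flat_bilayer(30)
  t40 <- flat_bilayer(40)
  traj <- bilayer_trajectory(c(t30$frames, t40$frames), t30$atoms)
  tm <- thickness_map(traj, bin = 2)
  vals <- tm$thickness[tm$occupancy > 0]
  expect_true(all(abs(vals - 35) <= 1e-6))
})

test_that("a planted depression is recovered at depth and position", {
  traj <- gen_bilayer_trajectory(5L, slab_sep = 38,
                                 depression = list(depth = 8, sigma = 10,
                                                   center = c(0, 0)),
                                 jitter = 0.3, seed = 77L)
  for (leaflet in c("upper", "lower")) {
    tm <- thickness_map(traj, bin = 2, leaflet = leaflet)
    expect_lt(abs(min(tm$thickness, na.rm = TRUE) - 30), 1)
    idx <- which(tm$thickness == min(tm$thickness, na.rm = TRUE),
                 arr.ind = TRUE)
    expect_lt(abs(tm$x[idx[1L, 1L]]), 8)
    expect_lt(abs(tm$y[idx[1L, 2L]]), 8)
  }
})

test_that("thickness maps shift with rigid in-plane translation", {
  traj <- gen_bilayer_trajectory(2L, slab_sep = 36,
                                 depression = list(depth = 6, sigma = 8,
                                                   center = c(0, 0)),
                                 jitter = 0, seed = 5L)
  shifted <- traj
  shifted$frames <- lapply(traj$frames, function(f) {
    f[, 1L] <- f[, 1L] + 11
    f[, 2L] <- f[, 2L] + 7
    f
  })
  tm0 <- thickness_map(traj, bin = 2)
  tm1 <- thickness_map(shifted, bin = 2)
  v0 <- sort(tm0$thickness[tm0$occupancy > 0])
  v1 <- sort(tm1$thickness[tm1$occupancy > 0])
  expect_equal(v1, v0, tolerance = 1e-9)
  expect_equal(min(tm1$x) - min(tm0$x), 11, tolerance = 1e-9)
})

protein_traj <- function(frames) {
  n <- nrow(frames[[1L]])
  atoms <- data.frame(resno = rep(seq_len(n / 4), each = 4L),
                      elety = rep(c("N", "CA", "C", "O"), n / 4),
                      role = "protein_backbone", leaflet = "n/a",
                      stringsAsFactors = FALSE)
  bilayer_trajectory(frames, atoms)
}

test_that("static trajectories have zero positional variance", {
  base <- matrix(rnorm(8 * 3), 8L)
  traj <- protein_traj(list(base, base, base))
  pv <- positional_variance(traj)
  expect_equal(pv$variance, c(0, 0))
  expect_error(positional_variance(protein_traj(list(base))), "2 frames")
})

test_that("isotropic jitter gives variance 3 sigma^2", {
  set.seed(9)
  base <- matrix(rnorm(8 * 3, sd = 4), 8L)
  sigma <- 0.5
  frames <- lapply(seq_len(1e4), function(i)
    base + matrix(rnorm(24, sd = sigma), 8L))
  pv <- positional_variance(protein_traj(frames))
  expect_true(all(abs(pv$variance - 3 * sigma^2) / (3 * sigma^2) < 0.05))
})

test_that("rigid drift inflates every residue's variance", {
  set.seed(10)
  base <- matrix(rnorm(8 * 3), 8L)
  frames <- lapply(1:50, function(i)
    base + matrix(rnorm(24, sd = 0.2), 8L))
  pv0 <- positional_variance(protein_traj(frames))
  drifted <- lapply(seq_along(frames), function(i)
    frames[[i]] + 0.1 * i) # growing rigid displacement
  pv1 <- positional_variance(protein_traj(drifted))
  expect_true(all(pv1$variance > pv0$variance))
})

test_that("hydrogen bond geometry thresholds are inclusive", {
  # D at origin, H toward A, A at 2.9 A and 5 degrees off the D-H axis
  mk_frame <- function(dist, ang_deg) {
    ang <- ang_deg * pi / 180
    rbind(c(0, 0, 0),                                   # donor heavy
          c(1, 0, 0),                                   # hydrogen
          c(dist * cos(ang), dist * sin(ang), 0))       # acceptor
  }
  donors <- data.frame(d = 1L, h = 2L)
  hb <- hydrogen_bonds(mk_frame(2.9, 5), donors, acceptors = 3L)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$angle, 5, tolerance = 1e-9)
  expect_equal(nrow(hydrogen_bonds(mk_frame(4.0, 5), donors, 3L)), 0L)
  expect_equal(nrow(hydrogen_bonds(mk_frame(3.0, 25), donors, 3L)), 0L)
  # boundaries count as bonded
  expect_equal(nrow(hydrogen_bonds(mk_frame(3.8, 20), donors, 3L)), 1L)
  expect_error(hydrogen_bonds(mk_frame(2.9, 5),
                              data.frame(d = 1L, h = NA_integer_), 3L),
               "hydrogen")
})

test_that("hydrogen bonds match an all-pairs brute-force oracle", {
  set.seed(12)
  frame <- matrix(runif(50 * 3, 0, 12), 50L)
  donors <- data.frame(d = seq(1L, 19L, 2L), h = seq(2L, 20L, 2L))
  acceptors <- 21:50
  got <- hydrogen_bonds(frame, donors, acceptors)
  oracle <- 0L
  for (k in seq_len(nrow(donors))) {
    for (a in acceptors) {
      da <- frame[a, ] - frame[donors$d[k], ]
      dh <- frame[donors$h[k], ] - frame[donors$d[k], ]
      dist <- sqrt(sum(da^2))
      cosang <- sum(dh * da) / (sqrt(sum(dh^2)) * dist)
      ang <- acos(min(max(cosang, -1), 1)) * 180 / pi
      if (dist <= 3.8 && ang <= 20) oracle <- oracle + 1L
    }
  }
  expect_equal(nrow(got), oracle)
  # monotone in both cutoffs
  wider <- hydrogen_bonds(frame, donors, acceptors, max_dist = 5,
                          max_angle = 40)
  expect_gte(nrow(wider), nrow(got))
})

test_that("hydropathy profiles bin and conserve residues", {
  helix <- gen_toy_bundle(1L, helix_len = 20L)$structure
  helix$atoms$resid <- "LEU"
  prof <- hydropathy_height_profile(helix, membrane_z = c(-15, 15),
                                    n_bins = 6L)
  expect_equal(sum(prof$hydrophilic), 0L)
  expect_equal(sum(prof$hydrophobic), 20L)
  # mixed sequence against a manual binning oracle
  s <- toy_structure(chain = "A", resno = 1:6,
                     resid = c("LEU", "ASP", "ILE", "LYS", "GLY", "PHE"),
                     elety = "CA",
                     x = 0, y = 0, z = c(-20, -10, -10, 2, 10, 30))
  prof2 <- hydropathy_height_profile(s, membrane_z = c(-15, 15),
                                     n_bins = 3L)
  expect_equal(sum(prof2$hydrophobic) + sum(prof2$hydrophilic), 6L)
  expect_equal(prof2$hydrophobic[1L], 1L)  # LEU below the slab
  expect_equal(prof2$hydrophilic[2L], 1L)  # ASP in the lowest slab bin
  expect_equal(prof2$hydrophobic[2L], 1L)  # ILE beside it
  expect_equal(prof2$hydrophobic[5L], 1L)  # PHE above the slab
  expect_equal(prof2$hydrophilic[4L], 1L)  # GLY (index -0.4) top bin
})

test_that("local energy averaging matches a double-loop oracle", {
  set.seed(14)
  n <- 20L
  s <- toy_structure(chain = "A", resno = 1:n, resid = "ALA", elety = "CA",
                     x = runif(n, 0, 25), y = runif(n, 0, 25),
                     z = runif(n, 0, 25))
  energy <- matrix(rnorm(5L * n), 5L, n, dimnames = list(NULL, 1:n))
  got <- local_energy_average(energy, s, cutoff = 10)
  xyz <- as.matrix(s$atoms[s$atoms$elety == "CA", c("x", "y", "z")])
  tavg <- colMeans(energy)
  for (k in 1:n) {
    nb <- which(sqrt(colSums((t(xyz) - xyz[k, ])^2)) <= 10)
    expect_equal(got$smoothed[k], mean(tavg[nb]))
  }
  # an infinite cutoff preserves the global mean at every residue
  all_avg <- local_energy_average(energy, s, cutoff = Inf)
  expect_true(all(abs(all_avg$smoothed - mean(tavg)) < 1e-12))
  # isolated residue keeps its own time average
  s2 <- s
  s2$atoms$x[1L] <- 1e4
  iso <- local_energy_average(energy, s2, cutoff = 10)
  expect_equal(iso$smoothed[1L], tavg[[1L]])
  expect_error(local_energy_average(energy[, -3L, drop = FALSE], s),
               "missing")
})
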