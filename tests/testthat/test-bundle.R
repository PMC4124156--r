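test_that("two helices with one contact sit at the contact distance", {
  pl <- place_helices(c("A", "B"), cbind("A", "B"), contact_distance = 10)
  d <- sqrt(diff(pl$x)^2 + diff(pl$y)^2)
  expect_equal(d, 10, tolerance = 1e-4)
  # gauge: centered, first helix on +x
  expect_equal(mean(pl$x), 0, tolerance = 1e-8)
  expect_equal(pl$y[1L], 0, tolerance = 1e-6)
  expect_gt(pl$x[1L], 0)
})

test_that("a pentagon contact ring places helices on a regular pentagon", {
  hel <- paste0("H", 1:5)
  ring <- cbind(hel, hel[c(2:5, 1L)])
  pl <- place_helices(hel, ring, contact_distance = 10)
  xy <- cbind(pl$x, pl$y)
  side <- sqrt(rowSums((xy - xy[c(2:5, 1L), ])^2))
  expect_true(all(abs(side - 10) / 10 < 0.05))
  rad <- sqrt(rowSums(xy^2))
  expect_true(all(abs(rad - 10 / (2 * sin(pi / 5))) / rad < 0.05))
  # cyclic (ring) order preserved around the center
  ang <- atan2(pl$y, pl$x)
  ord <- order(ang)
  start <- which(ord == 1L)
  cyc <- ord[c(start:5, seq_len(start - 1L))]
  expect_true(identical(cyc, c(1L, 2L, 3L, 4L, 5L)) ||
                identical(cyc, c(1L, 5L, 4L, 3L, 2L)))
})

test_that("placement stress matches a brute-force grid search", {
  hel <- c("A", "B", "C")
  contacts <- rbind(c("A", "B"), c("B", "C"))
  pl <- place_helices(hel, contacts, contact_distance = 10)
  stress <- attr(pl, "stress")
  # oracle: helix A at origin, B on +x, C free on a 0.5 A grid
  D <- 10
  obj <- function(xb, xc, yc) {
    pa <- c(0, 0); pb <- c(xb, 0); pc <- c(xc, yc)
    dab <- sqrt(sum((pa - pb)^2)); dbc <- sqrt(sum((pb - pc)^2))
    dac <- sqrt(sum((pa - pc)^2))
    (dab - D)^2 + (dbc - D)^2 + max(0, D - dac)^2
  }
  grid <- expand.grid(xb = seq(5, 15, 0.5), xc = seq(-10, 30, 0.5),
                      yc = seq(0, 20, 0.5))
  oracle <- min(mapply(obj, grid$xb, grid$xc, grid$yc))
  expect_lte(stress, oracle + 1e-6)
  expect_lt(oracle - stress, 0.1)
})

test_that("placement is invariant under contact reordering", {
  hel <- paste0("H", 1:5)
  ring <- cbind(hel, hel[c(2:5, 1L)])
  pl1 <- place_helices(hel, ring, contact_distance = 10)
  pl2 <- place_helices(hel, ring[c(3, 1, 5, 2, 4), c(2, 1)],
                       contact_distance = 10)
  expect_equal(pl1$x, pl2$x, tolerance = 1e-3)
  expect_equal(pl1$y, pl2$y, tolerance = 1e-3)
})

test_that("disconnected contact graphs are refused with components", {
  expect_error(place_helices(c("A", "B", "C", "D"), cbind("A", "B")),
               "disconnected")
})

test_that("exposure phase maximization matches a brute-force scan", {
  set.seed(31)
  residues <- 1:18
  for (rep in 1:5) {
    labels <- sample(c("lipid", "protein", "unknown"), 18, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    if (all(labels == "unknown")) labels[1L] <- "lipid"
    origin <- c(8, 3)
    ph <- orient_by_exposure(residues, labels, origin)
    # independent 0.1-degree brute-force scan of the objective
    twist <- 100 * pi / 180
    psi <- atan2(origin[2L], origin[1L])
    s <- ifelse(labels == "lipid", 1, ifelse(labels == "protein", -1, 0))
    objective <- function(phi) {
      th <- phi + twist * (residues - 1)
      sum(s * cos(th - psi))
    }
    grid <- seq(-pi, pi, by = 0.1 * pi / 180)
    best <- grid[which.max(vapply(grid, objective, numeric(1)))]
    delta <- abs(((ph - best + pi) %% (2 * pi)) - pi)
    expect_lt(delta, 0.005)
  }
})

test_that("a single lipid residue points its side chain outward", {
  ph <- orient_by_exposure(1L, "lipid", origin_xy = c(0, 7),
                           centroid_xy = c(0, 0))
  expect_equal(as.numeric(ph), pi / 2, tolerance = 1e-9)
})

test_that("azimuthally balanced labels are flagged as degenerate", {
  # two lipid residues ~180 degrees apart (100 deg/residue, offsets 0/9)
  labels <- rep("unknown", 10)
  labels[c(1, 10)] <- "lipid" # offsets 0 and 900 deg = 180 (mod 360)
  expect_warning(ph <- orient_by_exposure(1:10, labels, c(5, 0)),
                 "degenerate")
  expect_equal(as.numeric(ph), 0)
  expect_error(orient_by_exposure(1:5, rep("unknown", 5), c(1, 0)),
               "labelled")
})

test_that("ideal bundles have ideal helix geometry", {
  toy <- gen_toy_bundle(3L, helix_len = 18L)
  at <- toy$structure$atoms
  for (h in unique(toy$bundle$atoms$helix)) {
    res <- segment_residues(toy$ha, h)
    ca <- at[at$elety == "CA" & at$resno %in% res, ]
    ca <- ca[order(ca$resno), ]
    step <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
    expect_true(all(abs(step - 3.8) <= 0.1))
    # 18 residues: axial extent 17 * 1.5 = 25.5 within 2%
    expect_lt(abs(diff(range(ca$z)) - 25.5) / 25.5, 0.02)
    # rise per residue 1.5 within 5%
    rise <- abs(diff(ca$z))
    expect_true(all(abs(rise - 1.5) / 1.5 < 0.05))
  }
})

test_that("bundle topology alternates helix direction", {
  toy <- gen_toy_bundle(2L)
  expect_equal(toy$bundle$helices$dir, c(1, -1))
  at <- toy$structure$atoms
  for (r in seq_len(2L)) {
    h <- toy$bundle$helices$name[r]
    res <- segment_residues(toy$ha, h)
    ca <- at[at$elety == "CA" & at$resno %in% res, ]
    ca <- ca[order(ca$resno), ]
    expect_equal(sign(ca$z[nrow(ca)] - ca$z[1L]),
                 toy$bundle$helices$dir[r])
  }
})

test_that("bundle PDB files round-trip coordinates", {
  toy <- gen_toy_bundle(2L, helix_len = 10L)
  path <- tempfile(fileext = ".pdb")
  write_bundle_pdb(toy$bundle, path)
  back <- read_structure_pdb(path)
  a0 <- toy$structure$atoms
  a1 <- back$atoms
  key0 <- paste(a0$resno, a0$elety)
  key1 <- paste(a1$resno, a1$elety)
  expect_setequal(key1, key0)
  m <- match(key0, key1)
  expect_true(max(abs(a0$x - a1$x[m])) <= 1e-3)
  expect_true(max(abs(a0$y - a1$y[m])) <= 1e-3)
  expect_true(max(abs(a0$z - a1$z[m])) <= 1e-3)
})

test_that("missing phases or topology are reported", {
  toy <- gen_toy_bundle(2L)
  pl <- toy$bundle$helices[, c("name", "x", "y")]
  class(pl) <- c("helix_placement", "data.frame")
  expect_error(build_ideal_bundle(pl, c(H1 = 0), toy$ha,
                                  c(H1 = "cytoplasmic",
                                    H2 = "periplasmic")),
               "phase")
  expect_error(build_ideal_bundle(pl, c(H1 = 0, H2 = 0), toy$ha,
                                  c(H1 = "cytoplasmic")),
               "topology")
})

test_that("contact-derived bundles keep planted pairs within reach", {
  # pentagon of 5 helices from planted predictions: retained contact
  # residues end up closer than 13 A between beta carbons
  toy <- gen_toy_bundle(5L, helix_len = 18L)
  s <- toy$structure
  hel <- helices_of(toy$ha)
  for (k in seq_len(5L)) {
    a <- hel[k, ]; b <- hel[(k %% 5L) + 1L, ]
    mid_a <- (a$start + a$end) %/% 2
    mid_b <- (b$start + b$end) %/% 2
    # facing residues: minimum over a one-turn window on both helices
    best <- Inf
    for (i in (mid_a - 2L):(mid_a + 2L)) {
      for (j in (mid_b - 2L):(mid_b + 2L)) {
        best <- min(best, cb_distance(s, i, j))
      }
    }
    expect_lt(best, 13)
  }
})
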