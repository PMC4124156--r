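# Shared fixtures and independent oracles used across the suite.

# unordered pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# write a temporary FASTA alignment and return its path
write_temp_fasta <- function(seqs, labels = paste0("s", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", labels, "\n", seqs), path)
  path
}

# default 7-helix annotation and its planted interaction set (a ring plus
# two cross contacts: 7 truly interacting pairs out of 21)
seven_helix_truth <- function() {
  list(ha = gen_annotation(7L),
       pairs = data.frame(
         helix_a = c("H1", "H2", "H3", "H4", "H5", "H1", "H2"),
         helix_b = c("H2", "H3", "H4", "H5", "H6", "H6", "H7"),
         orientation = rep(c("antiparallel", "parallel"), length.out = 7),
         register = 0L, stringsAsFactors = FALSE))
}

# pool per-cell strengths of every helix-pair block with its label
training_strengths <- function(dataset) {
  s <- c(); y <- logical(0)
  for (e in dataset) {
    for (k in seq_len(nrow(e$pairs))) {
      ra <- match(segment_residues(e$ha, e$pairs$helix_a[k]), e$cm$ref_map)
      rb <- match(segment_residues(e$ha, e$pairs$helix_b[k]), e$cm$ref_map)
      blk <- e$cm$strengths[ra, rb]
      s <- c(s, as.numeric(blk))
      y <- c(y, rep(e$pairs$is_interacting[k], length(blk)))
    }
  }
  list(strength = s, label = y)
}

# raw scores + labels for a labelled dataset under a fitted detector
detector_scores <- function(dataset, template, dists) {
  raw <- c(); y <- logical(0)
  for (e in dataset) {
    pred <- predict_all_pairs(e$cm, e$ha, template, dists)
    lab <- stats::setNames(e$pairs$is_interacting,
                           pair_key(e$pairs$helix_a, e$pairs$helix_b))
    raw <- c(raw, pred$raw_score)
    y <- c(y, lab[pair_key(pred$helix_a, pred$helix_b)])
  }
  list(raw = raw, label = unname(y))
}

# well-separated strength models matching the generator defaults
default_test_dists <- function(prior = 0.3) {
  strength_dists(fg_shape = 4, fg_rate = 4, bg_shape = 1, bg_rate = 20,
                 prior = prior)
}

# Independent quaternion (QCP-style) superposition RMSD oracle: the
# minimal RMSD is sqrt((Ga + Gb - 2 * lambda_max) / n) with lambda_max the
# largest eigenvalue of the 4x4 quaternion key matrix. No SVD involved.
qcp_rmsd <- function(x, y) {
  xc <- sweep(x, 2L, colMeans(x))
  yc <- sweep(y, 2L, colMeans(y))
  G <- sum(xc^2) + sum(yc^2)
  M <- crossprod(xc, yc)
  S <- matrix(c(
    M[1,1]+M[2,2]+M[3,3], M[2,3]-M[3,2], M[3,1]-M[1,3], M[1,2]-M[2,1],
    M[2,3]-M[3,2], M[1,1]-M[2,2]-M[3,3], M[1,2]+M[2,1], M[1,3]+M[3,1],
    M[3,1]-M[1,3], M[1,2]+M[2,1], -M[1,1]+M[2,2]-M[3,3], M[2,3]+M[3,2],
    M[1,2]-M[2,1], M[1,3]+M[3,1], M[2,3]+M[3,2], -M[1,1]-M[2,2]+M[3,3]),
    4L, 4L, byrow = TRUE)
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (G - 2 * lam) / nrow(x)))
}

# tiny hand-built structure from an atom table
toy_structure <- function(...) {
  structure_coords(data.frame(...))
}
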