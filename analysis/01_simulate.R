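#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Everything downstream runs on seeded synthetic data shaped like the real
# inputs: a coupling matrix for a 7-helix membrane protein with 7 planted
# helix-helix interactions, labelled helix-pair datasets for training and
# calibration, and a two-leaflet phosphate bilayer trajectory with a
# planted 8 A thinning depression. Outputs land under results/.

library(covhelix)

dir.create("results", showWarnings = FALSE)
seed <- 1L

ha <- gen_annotation(7L)
truth <- data.frame(
  helix_a = c("H1", "H2", "H3", "H4", "H5", "H1", "H2"),
  helix_b = c("H2", "H3", "H4", "H5", "H6", "H6", "H7"),
  orientation = rep(c("antiparallel", "parallel"), length.out = 7),
  register = 0L, stringsAsFactors = FALSE)

cm <- gen_coupling_matrix(planted_topology(ha, truth, seed = seed))
write_couplings(cm, "results/sim_couplings.tsv")
write_segments(ha, "results/sim_segments.tsv")
write.table(truth, "results/sim_truth_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("coupling matrix: %d x %d, planted pairs: %d\n",
            nrow(cm$strengths), ncol(cm$strengths), nrow(truth)))

traj <- gen_bilayer_trajectory(5L, slab_sep = 38,
                               depression = list(depth = 8, sigma = 10,
                                                 center = c(0, 0)),
                               jitter = 0.3, seed = seed)
# the trajectory is regenerated downstream from its seed; nothing to store
cat(sprintf("bilayer: %d frames x %d phosphates, planted thinning 8 A\n",
            length(traj$frames), nrow(traj$atoms)))
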