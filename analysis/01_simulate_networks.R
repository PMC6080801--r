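#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study networks.
#
# Emits, as nodes/edges CSV pairs under results/samples/:
#   - plexus-stage networks grown at the best-fit creation parameters
#     (lambda = 0.25, delta = 1, 320 nodes), the early-plexus stand-ins;
#   - jittered triangular-lattice meshes, a growth-model-independent
#     planar control;
#   - flux-pruned trees, the near-mature stand-ins.
# Every later stage reads its inputs from these files, so the whole
# pipeline runs from the same on-disk layout as digitized data.

library(ductnet)

out_dir <- "results/samples"
n_rep <- 5L

configs <- c(
  lapply(seq_len(n_rep), function(s)
    list(generator = "plexus", name = sprintf("plexus_%02d", s),
         n_nodes = 320L, seed = s)),
  lapply(seq_len(n_rep), function(s)
    list(generator = "lattice_mesh", name = sprintf("mesh_%02d", s),
         n_nodes = 320L, noise = 0.08, dilution = 0.15, seed = s)),
  lapply(seq_len(n_rep), function(s)
    list(generator = "tree", name = sprintf("tree_%02d", s),
         n_nodes = 320L, seed = s))
)

manifest <- emit_sample_set(out_dir, configs)
print(manifest)
cat("\nwrote", nrow(manifest), "samples to", out_dir, "\n")
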