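#!/usr/bin/env Rscript
# Stage 2: per-sample network statistics and group comparisons.
#
# Reads the samples written by 01_simulate_networks.R, computes the full
# statistic vector for each (counts, total length, degree, clustering,
# polygon counts, cost, performance, distances to the exit, dimension),
# and compares the plexus-stage group against the pruned-tree group with
# pooled two-sample t tests under a Bonferroni-adjusted threshold --
# the same contrasts used to characterize developmental stages.

library(ductnet)

manifest <- read.csv("results/samples/manifest.csv")
summaries <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
  net <- read_network(file.path("results/samples", manifest$nodes_file[i]),
                      file.path("results/samples", manifest$edges_file[i]),
                      root_id = manifest$root_id[i],
                      name = manifest$name[i])
  cbind(generator = manifest$generator[i], summarize_network(net))
}))
write.csv(summaries, "results/network_summaries.csv", row.names = FALSE)
print(summaries[, c("name", "n_nodes", "n_edges", "mean_degree",
                    "n_triangles", "cost", "performance", "root_ratio",
                    "dimension")], digits = 3)

plexus <- summaries[summaries$generator == "plexus", ]
trees <- summaries[summaries$generator == "tree", ]
cmp <- compare_groups(plexus, trees, alpha = 0.05)
write.csv(cmp, "results/plexus_vs_tree_comparison.csv", row.names = FALSE)
cat("\nplexus vs flux-pruned tree (pooled t tests, Bonferroni alpha =",
    format(cmp$bonferroni_alpha[1], digits = 3), "):\n")
print(cmp, digits = 3)

cat("\nkey contrasts: trees lose their polygons, drop in cost toward 1,",
    "\nand pull the mean exit distance toward the all-pair mean",
    "(root_ratio down).\n")
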