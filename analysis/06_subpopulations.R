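#!/usr/bin/env Rscript
# Kernel-density subpopulation analyses of the controllers: 1D KDE of
# hub clustering coefficients (is there more than one kind of hub?) and
# 2D KDE of hub.BN in the degree x BN-score plane (do the top
# controllers split into groups, and which sit isolated?).

library(follinet)

net <- build_network(read_interaction_table("results/database.tsv"))
ctrl <- find_controllers(net)
cent <- all_centralities(net)
cc <- clustering_coefficient(net)$per_node

k1 <- find_subpopulations(kde_estimate(unname(cc[ctrl$hubs])))
cat("-- 1D KDE: hub clustering coefficients --\n")
print(k1)

pts <- cbind(degree = cent$gamma[match(ctrl$hub_bn, cent$node)],
             bn_score = cent$bn_score[match(ctrl$hub_bn, cent$node)])
rownames(pts) <- ctrl$hub_bn
k2 <- find_subpopulations(kde_estimate(pts))
cat("\n-- 2D KDE: hub.BN, degree x BN score --\n")
print(k2)
if (length(k2$isolated)) {
  cat("Isolated hub.BN (extreme degree/BN controllers):",
      paste(rownames(pts)[k2$isolated], collapse = ", "), "\n")
}

jsonlite::write_json(
  list(hub_clustering_1d = list(n_subpopulations = length(k1$subpopulations),
                                n_isolated = length(k1$isolated)),
       hub_bn_2d = list(n_subpopulations = length(k2$subpopulations),
                        n_isolated = length(k2$isolated),
                        isolated = rownames(pts)[k2$isolated])),
  "results/kde_subpopulations.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
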