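#!/usr/bin/env Rscript
# Stratify the network into input / processing / output layers by the
# in/out degree ratio and cross-tabulate the layers against the
# controller classes; check the stratification against the generator's
# ground-truth layers.

library(follinet)

net <- build_network(read_interaction_table("results/database.tsv"))
ctrl <- find_controllers(net)

st <- stratify_network(net, ctrl)
write.table(st$assignments, "results/strata.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(as.data.frame(st$composition), "results/strata_composition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Layer x controller-class composition:\n")
print(st$composition)

truth <- read.delim("results/true_layers.tsv")
m <- merge(st$assignments, truth, by = "node")
planted <- m$layer.y == "input" & !is.na(m$layer.x)
rate <- mean(as.character(m$layer.x[planted]) == "input")
cat(sprintf("\nPlanted signal sources recovered in the input layer: %.1f%%\n",
            100 * rate))
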