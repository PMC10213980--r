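#!/usr/bin/env Rscript
# Build per-cohort soft-thresholded networks, the consensus topological
# overlap, and the reference-cohort module assignment with eigengene-trait
# correlations.

library(coexmeta)

fx <- load_inputs("results/fixture")
dir.create("results/network", showWarnings = FALSE, recursive = TRUE)
norm <- lapply(fx$expression, median_normalize, log2 = TRUE)

# scale-free topology scan on the reference cohort: the default power 4
# should sit on the high-R^2 plateau
scan <- soft_threshold_scan(norm[[1]], powers = c(1:10, 12, 14))
write.table(scan, "results/network/soft_threshold_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("scale-free fit at power 4:", round(scan$sft_r2[scan$power == 4], 3),
    "(power 1:", round(scan$sft_r2[scan$power == 1], 3), ")\n")

toms <- lapply(norm, function(x)
  topological_overlap(adjacency_from_expression(x, beta = 4)))
cons <- consensus_overlap(toms)

asg <- cut_modules(build_dendrogram(cons), min_size = 30, cut_height = 0.99,
                   X = norm[[1]])
asg <- merge_modules(norm[[1]], asg, merge_threshold = 0.25)
sizes <- table(asg$labels[asg$labels > 0])
cat("detected", length(sizes), "modules of sizes",
    paste(sizes, collapse = ", "), "with",
    sum(asg$labels == 0), "unassigned features\n")
write.table(data.frame(feature_id = names(asg$labels), module = asg$labels),
            "results/network/module_assignment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

me <- module_eigengenes(norm[[1]], asg)
mt <- module_trait_table(me, fx$traits[[1]],
                         trait_cols = c("group", "CAPS_total"))
write.table(mt, "results/network/module_trait.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("modules correlated with severity at p < 0.01:",
    paste(unique(mt$module[mt$flagged]), collapse = ", "), "\n")
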