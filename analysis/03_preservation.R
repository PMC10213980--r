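#!/usr/bin/env Rscript
# Permutation module-preservation of reference-cohort modules in each test
# cohort: 300 permutations, Z_summary > 10 = high, 5-10 = moderate.

library(coexmeta)

fx <- load_inputs("results/fixture")
dir.create("results/preservation", showWarnings = FALSE, recursive = TRUE)
norm <- lapply(fx$expression, median_normalize, log2 = TRUE)
labels <- read.delim("results/network/module_assignment.tsv")
asg <- structure(list(labels = setNames(as.integer(labels$module),
                                        labels$feature_id)),
                 class = "module_assignment")

for (cn in names(norm)[-1]) {
  pr <- preservation_zsummary(asg, norm[[1]], norm[[cn]],
                              n_permutations = 300,
                              seed = 7 + match(cn, names(norm)))
  write.table(pr, sprintf("results/preservation/preservation_%s.tsv", cn),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(cn, ": ", paste(sprintf("module %d Z=%.1f (%s)", pr$module,
                              pr$Z_summary, pr$class), collapse = "; "),
      "\n", sep = "")
}
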