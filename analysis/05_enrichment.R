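#!/usr/bin/env Rscript
# Over-representation of the persistent set in the pathway collection,
# sign-consistency activation scores, and pathway-score/severity
# correlations.

library(coexmeta)

fx <- load_inputs("results/fixture")
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
norm <- lapply(fx$expression, median_normalize, log2 = TRUE)
pers <- read.delim("results/diffmeta/persistent_set.tsv")
meta <- read.delim("results/diffmeta/meta.tsv")

universe <- feature_ids(fx$expression[[1]])
enr <- hypergeometric_enrichment(pers$feature_id, fx$pathways, universe,
                                 method = "bonferroni", min_overlap = 3)
write.table(enr, "results/enrichment/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("sets enriched at Bonferroni q < 0.05:",
    paste(enr$set[enr$q < 0.05], collapse = ", "), "\n")

act <- activation_scores(fx$pathways,
                         setNames(ifelse(meta$pooled_d >= 0, 1, -1),
                                  meta$feature_id))
write.table(act, "results/enrichment/activation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (nrow(act)) cat(sprintf("activation z for %s: %.2f\n", act$set,
                           act$activation_z))

scores <- do.call(rbind, lapply(names(fx$pathways$sets), function(nm) {
  sc <- tryCatch(pathway_sample_scores(norm[[1]], fx$pathways$sets[[nm]]),
                 error = function(e) NULL)
  if (is.null(sc)) return(NULL)
  matrix(sc, nrow = 1, dimnames = list(nm, names(sc)))
}))
ptc <- pathway_trait_correlation(scores, fx$traits[[1]],
                                 trait_cols = "CAPS_total")
write.table(ptc, "results/enrichment/pathway_trait.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- ptc[ptc$p < 0.01, ]
if (nrow(sig))
  cat("pathway scores correlated with CAPS total (p < 0.01):",
      paste(sprintf("%s (r=%.2f)", sig$set, sig$r), collapse = ", "), "\n")
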