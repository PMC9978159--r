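#!/usr/bin/env Rscript

# Community diversity: inverse Simpson per sample (alpha), Bray-Curtis
# dissimilarities with a one-factor PERMANOVA over starter mixtures
# (beta), and a scaled PCA of the relative-abundance profiles.

suppressMessages(library(strainasv))

tab <- read_asv_table("results/sim/null_community")  # 12-taxon community
rel <- relative_abundances(tab)

alpha <- data.frame(sample = rownames(rel),
                    inverse_simpson = inverse_simpson(rel))
utils::write.table(alpha, "results/alpha_diversity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("inverse Simpson: median %.2f (range %.2f-%.2f) over %d taxa",
                stats::median(alpha$inverse_simpson),
                min(alpha$inverse_simpson), max(alpha$inverse_simpson),
                ncol(rel)))

D <- bray_curtis_matrix(tab$counts)
write_tsv_matrix(D, "results/bray_curtis.tsv")

pm <- permanova(D, tab$sample_meta$starter, n_perm = 999L, seed = 1L)
print(pm)
jsonlite::write_json(unclass(pm), "results/permanova.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
# starter labels are arbitrary in this community: p should be unremarkable
message(if (pm$p_value < 0.05)
  "starter effect flagged (unexpected under this design)" else
  "no starter effect, as expected for exchangeable abundances")

pc <- pca_scaled(rel)
write_tsv_matrix(pc$scores[, 1:2], "results/pca_scores.tsv")
message(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * pc$proportion[1L], 100 * pc$proportion[2L]))
message("wrote results/alpha_diversity.tsv, bray_curtis.tsv, permanova.json, pca_scores.tsv")
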