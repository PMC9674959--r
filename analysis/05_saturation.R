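#!/usr/bin/env Rscript
# Stage 5 -- saturation predictions for every possible missense variant.
#
# Applies the final classifier to all 19 x L substitutions, maps LOF
# probabilities to the normalized 0-1 functional score (cutoff at 0.5),
# and summarizes per residue and globally.

suppressPackageStartupMessages(library(octnvep))

st <- readRDS("results/study/study.rds")
final <- read_model_json("results/final_model.json")

all_var <- enumerate_missense(st$seq)
Xall <- cbind(sequence_features(all_var, st$seq, st$topo),
              structure_features(all_var, st$structure))
xs <- scale_features(Xall[, final$scaling$features, drop = FALSE],
                     final$scaling)
p <- predict(final, xs, type = "response")
tab <- saturation_table(all_var, p, final$cutoff)
write.table(tab, "results/saturation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ss <- saturation_summary(tab)
write.table(ss$per_residue, "results/saturation_per_residue.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(round(saturation_matrix(tab), 4),
            "results/saturation_heatmap.tsv", sep = "\t", quote = FALSE,
            col.names = NA)

cat(sprintf("Scored %d possible missense variants (%d residues x 19)\n",
            ss$n_total, length(st$seq)))
cat(sprintf("  predicted severe LOF (score < 0.5): %d (%.1f%%)\n",
            ss$n_lof, 100 * ss$frac_lof))
tol <- ss$per_residue[order(-ss$per_residue$mean), ]
cat("  most substitution-tolerant residues:",
    paste(head(tol$pos, 5), collapse = ", "), "\n")
cat("  least tolerant residues:",
    paste(head(tol$pos[order(tol$mean)], 5), collapse = ", "), "\n")
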