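#!/usr/bin/env Rscript
# Stage 3 -- build the four feature sets for the characterized variants.
#
# Sequence features come from the amino-acid change and its topological
# context, structure features from the coordinate model (contact number,
# burial, pLDDT, centroid-axis distance), prediction features from the
# external-style score tables. The combined set is their union. Matrices
# are written raw (unscaled); 0-1 scaling is always fitted on training
# rows inside the evaluation protocol, never here.

suppressPackageStartupMessages(library(octnvep))

st <- readRDS("results/study/study.rds")
v <- st$variants

sets <- list(
  sequence   = assemble_features(v, st$seq, st$topo,
                                 feature_set = "sequence"),
  structure  = assemble_features(v, structure = st$structure,
                                 feature_set = "structure"),
  prediction = assemble_features(v, score_tables = st$score_tables,
                                 feature_set = "prediction"),
  all        = assemble_features(v, st$seq, st$topo, st$structure,
                                 st$score_tables, feature_set = "all")
)
saveRDS(sets, "results/feature_sets.rds")
write.table(data.frame(variant = rownames(sets$all), sets$all,
                       check.names = FALSE),
            "results/features_all.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (nm in names(sets)) {
  cat(sprintf("  %-10s %3d features x %d variants\n", nm,
              ncol(sets[[nm]]), nrow(sets[[nm]])))
}
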