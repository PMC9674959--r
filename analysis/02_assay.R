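#!/usr/bin/env Rscript
# Stage 2 -- uptake assay pipeline and cohort summaries.
#
# Normalizes the raw replicate wells to %WT function, calls LOF at the 20%
# threshold with Bonferroni-corrected significance, and reproduces the
# study-level summaries: per-region characterization density, function by
# ancestry group (ANOVA + Tukey), and function by subcellular localization
# (Welch ANOVA + Games-Howell).

suppressPackageStartupMessages(library(octnvep))

st <- readRDS("results/study/study.rds")
assay <- read_assay_tsv("results/study/assay.tsv")

chr <- characterize_assay(assay)
chr$localization <- st$characterized$localization[
  match(chr$label, st$characterized$label)]
chr$group <- st$characterized$group[match(chr$label, st$characterized$label)]
write.table(chr, "results/characterized.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Characterized %d variants: function %.1f .. %.1f %%WT\n",
            nrow(chr), min(chr$function_pct), max(chr$function_pct)))
cat(sprintf("  LOF (<20%%): %d (%.1f%%); significant vs WT at alpha=%.1e: %d\n",
            sum(chr$lof), 100 * mean(chr$lof), 0.05 / nrow(chr),
            sum(chr$significant, na.rm = TRUE)))

dens <- region_density(st$variants, st$topo)
write.table(dens$regions, "results/region_density.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("  overall characterization density: %.2f (per-region %.2f .. %.2f)\n",
            dens$overall, min(dens$regions$density),
            max(dens$regions$density)))

gs <- group_summary(chr$function_pct, chr$group)
write.table(gs$groups, "results/group_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("  group ANOVA F = %.2f, p = %.3g; smallest Tukey p = %.3f\n",
            gs$anova$F, gs$anova$p, min(gs$tukey$p_adj)))

ls <- localization_summary(chr$function_pct, chr$localization)
write.table(ls$games_howell, "results/localization_posthoc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
med <- setNames(ls$classes$median, ls$classes$class)
cat(sprintf("  localization medians: membrane %.1f / mixed %.1f / intracellular %.1f %%WT (Welch p = %.2g)\n",
            med["membrane"], med["mixed"], med["intracellular"],
            ls$welch_anova$p))
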