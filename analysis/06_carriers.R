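#!/usr/bin/env Rscript
# Stage 6 -- minimum carrier-frequency estimates per population.
#
# Pools the population allele frequencies of the assay-LOF variants and
# converts them to expected heterozygous-carrier frequencies (2q(1-q)),
# reported as 1:N. Variants without an observed frequency in a population
# contribute zero, making each estimate a minimum.

suppressPackageStartupMessages(library(octnvep))

chr <- read.delim("results/characterized.tsv")
afs <- read.delim("results/study/allele_frequencies.tsv")
lof <- chr$label[chr$lof]

rows <- lapply(sort(unique(afs$population)), function(pop) {
  cf <- carrier_frequency(lof, afs, pop)
  data.frame(population = pop, n_lof_with_af = cf$n_variants_with_af,
             q = cf$q, carrier_freq = cf$carrier_freq,
             ratio = ifelse(is.na(cf$ratio), "-", cf$ratio))
})
out <- do.call(rbind, rows)
write.table(out, "results/carrier_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Minimum carrier-frequency estimates from", length(lof),
    "LOF variants:\n")
for (i in seq_len(nrow(out))) {
  cat(sprintf("  %-10s q = %.2e  carrier %s\n", out$population[i],
              out$q[i], out$ratio[i]))
}
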