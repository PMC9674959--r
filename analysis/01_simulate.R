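#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic characterization study.
#
# Produces a complete in-silico analogue of a 150-variant transporter
# characterization campaign (sequence, topology, raw uptake wells,
# localization labels, ancestry groups, allele frequencies, external-style
# predictor scores) with known ground truth, and writes every file the
# downstream stages consume under results/study/.

suppressPackageStartupMessages(library(octnvep))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

dir.create("results", showWarnings = FALSE)
st <- simulate_study(study_config(), seed = seed)
write_study(st, "results/study")
saveRDS(st, "results/study/study.rds")  # full object for later stages

truth <- truth_report(st)
cat("Simulated study (seed ", seed, "):\n", sep = "")
cat("  protein length:", length(st$seq), "residues,",
    nrow(st$topo), "topological regions\n")
cat("  variants:", nrow(st$variants),
    sprintf("(true LOF prevalence %.1f%%)\n",
            100 * mean(st$variants$true_lof)))
cat("  nonzero true coefficients:",
    paste(names(truth$beta), collapse = ", "), "\n")
cat("  wrote", length(list.files("results/study")),
    "files under results/study/\n")
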