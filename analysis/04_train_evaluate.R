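#!/usr/bin/env Rscript
# Stage 4 -- model selection, evaluation, and the final classifiers.
#
# Evaluates the (model type x feature set) grid with repeated random
# subsampling (stratified splits, scaling and penalty tuning inside each
# training fold, cutoff maximizing sensitivity+specificity on training
# scores), then evaluates the final LOF classifier (70/30 splits, 100
# iterations), the quantitative-function regression model, the two
# localization classifiers, and the LASSO feature-importance profile.

suppressPackageStartupMessages(library(octnvep))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
grid_iter <- 25   # per grid cell; the headline report uses 100

st <- readRDS("results/study/study.rds")
sets <- readRDS("results/feature_sets.rds")
chr <- read.delim("results/characterized.tsv")
y <- chr$lof[match(rownames(sets$all), chr$label)]

cat("== model-selection grid (", grid_iter, "iterations/cell ) ==\n")
ms <- model_selection(sets, y, iterations = grid_iter,
                      test_fraction = 0.2, seed = derive_seed(seed, 41L))
print(ms$grid, digits = 3)
write.table(ms$grid, "results/model_selection.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\n== final LOF classifier: 100 x 70/30 subsampling ==\n")
rep <- repeated_evaluation(sets$all, y, iterations = 100,
                           test_fraction = 0.3,
                           seed = derive_seed(seed, 42L))
print(rep)
write.table(cbind(iteration = seq_len(nrow(rep$metrics)), rep$metrics),
            "results/classifier_folds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  list(aggregate = rep$aggregate, split = as.list(rep$split),
       iterations = rep$iterations, seed = rep$seed),
  "results/classifier_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

fi <- feature_importance(rep)
write.table(fi, "results/feature_importance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ntop features by |median coefficient|:\n")
print(head(fi[, c("feature", "median", "iqr", "frac_nonzero")], 8),
      digits = 2, row.names = FALSE)

cat("\n== quantitative-function regression (100 x 110/40 splits) ==\n")
fn <- chr$function_pct[match(rownames(sets$all), chr$label)]
reg <- repeated_evaluation(sets$all, fn, iterations = 100,
                           test_fraction = 40 / 150,
                           seed = derive_seed(seed, 43L),
                           fitter = penalized_fitter("regression"),
                           task = "regression", lof_labels = y)
print(reg)

cat("\n== localization classifiers (membrane / intracellular) ==\n")
loc <- chr$localization[match(rownames(sets$all), chr$label)]
locs <- fit_localization_models(sets$all, loc, iterations = 50,
                                test_fraction = 0.3,
                                seed = derive_seed(seed, 44L))
for (nm in names(locs)) {
  agg <- locs[[nm]]$aggregate
  cat(sprintf("  %-14s AUC %.3f +/- %.3f, accuracy %.3f\n", nm,
              agg$mean[agg$metric == "auc"], agg$sd[agg$metric == "auc"],
              agg$mean[agg$metric == "accuracy"]))
}

# final model on all 150 variants over the saturation-safe feature set
# (features computable for every possible variant: sequence + structure)
truth <- truth_report(st)
Xsat <- sets$all[, truth$feature_names, drop = FALSE]
sc <- fit_feature_scaling(Xsat)
xs <- scale_features(Xsat, sc)
tuned <- tune_lambda(xs, y, seed = derive_seed(seed, 45L))
cut <- select_cutoff(predict(
  fit_penalized_logistic(xs, y, tuned$lambda), xs), y)
final <- fit_penalized_logistic(xs, y, tuned$lambda, cutoff = cut,
                                scaling = sc)
write_model_json(final, "results/final_model.json", seed = seed)
cat(sprintf("\nfinal model: lambda = %.4g, cutoff = %.3f, %d nonzero coefficients\n",
            final$lambda, cut, sum(final$coefficients != 0)))
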