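# shared fixtures and independent oracles used across test files

fixture_seq <- function() {
  read_protein_fasta(system.file("extdata", "octn2_synthetic.fasta",
                                 package = "octnvep"))
}

fixture_topo <- function() {
  read_topology(system.file("extdata", "octn2_topology_synthetic.tsv",
                            package = "octnvep"))
}

# small, fast study profile for unit tests (full defaults are exercised in
# the acceptance tests)
smoke_study <- function(seed = 1, ...) {
  simulate_study(study_config(L = 60, n_variants = 40, ...), seed = seed)
}

# Monte-Carlo permutation two-sample test (independent oracle for the
# t-test's p-value on exchangeable data)
permutation_p <- function(a, b, nperm = 1e5, seed = 99) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- replicate(nperm, {
    idx <- sample(length(pool), na)
    abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
  })
  mean(hits)
}

# trapezoidal area under the empirical ROC curve (oracle for the
# rank-statistic AUC)
trapezoid_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# dense-grid brute force for the sensitivity+specificity cutoff
brute_force_cutoff <- function(scores, labels, grid_n = 4001) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  grid <- c(-Inf, seq(min(scores) - 0.05, max(scores) + 0.05,
                      length.out = grid_n), u - 1e-9, u + 1e-9, Inf)
  j <- vapply(grid, function(ct) {
    pred <- scores > ct
    sum(pred & labels) / sum(labels) + sum(!pred & !labels) / sum(!labels)
  }, numeric(1))
  max(j)
}
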