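test_that("rank-statistic AUC equals the trapezoidal ROC area", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + labels
    if (i %% 3 == 0) scores <- round(scores, 1)  # force ties
    expect_equal(auc_score(scores, labels), trapezoid_auc(scores, labels))
  }
  # invariance under strictly monotone transforms
  labels <- rbinom(60, 1, 0.3)
  scores <- runif(60)
  expect_equal(auc_score(plogis(5 * scores - 2), labels),
               auc_score(scores, labels))
  skip_if_not_installed("pROC")
  expect_equal(auc_score(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))))
})

test_that("cutoff selection equals dense-grid brute force on random instances", {
  set.seed(52)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    scores <- runif(n)
    if (i %% 4 == 0) scores <- round(scores, 1)
    ct <- select_cutoff(scores, labels)
    j <- function(cut) {
      pred <- scores > cut
      sum(pred & labels) / sum(labels) + sum(!pred & !labels) / sum(!labels)
    }
    expect_equal(j(ct), brute_force_cutoff(scores, labels), tolerance = 1e-9)
  }
})

test_that("cutoff selection handles separation and ties as specified", {
  # perfectly separated: cutoff strictly between the class ranges, J = 2
  scores <- c(0.1, 0.2, 0.3, 0.8, 0.85, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1)
  ct <- select_cutoff(scores, labels)
  expect_gt(ct, 0.3); expect_lt(ct, 0.8)
  m <- compute_metrics(scores, labels, ct)
  expect_equal(m$sensitivity + m$specificity, 2)
  # all scores identical: best J is 1, smallest candidate wins
  expect_identical(select_cutoff(rep(0.5, 6), labels), -Inf)
  expect_error(select_cutoff(1:4, rep(1, 4)), "both classes")
})

test_that("the metric suite matches its confusion-matrix definitions", {
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3)
  labels <- c(1, 1, 1, 0, 0, 0)
  m <- compute_metrics(scores, labels, 0.5)
  for (v in c("auc", "accuracy", "sensitivity", "specificity", "ppv",
              "npv")) expect_equal(m[[v]], 1)
  expect_equal(m$mcc, 1)

  # hand-checked mixed case: cutoff 0.5 -> TP=2 FN=1 TN=2 FP=1
  m2 <- compute_metrics(c(0.9, 0.8, 0.2, 0.6, 0.4, 0.1),
                        c(1, 1, 1, 0, 0, 0), 0.5)
  expect_equal(m2$sensitivity, 2 / 3)
  expect_equal(m2$specificity, 2 / 3)
  expect_equal(m2$ppv, 2 / 3)
  expect_equal(m2$npv, 2 / 3)
  expect_equal(m2$accuracy, 4 / 6)
  expect_equal(m2$mcc, (2 * 2 - 1 * 1) / sqrt(3 * 3 * 3 * 3))

  # scores independent of labels: AUC near 1/2, MCC near 0 at large n
  set.seed(53)
  lab <- rbinom(4000, 1, 0.5)
  sc <- runif(4000)
  m3 <- compute_metrics(sc, lab, 0.5)
  expect_lt(abs(m3$auc - 0.5), 0.03)
  expect_lt(abs(m3$mcc), 0.05)

  # zero-denominator metrics are NA, not 0: cutoff above all scores
  m4 <- compute_metrics(c(0.1, 0.2, 0.3, 0.4), c(1, 1, 0, 0), 0.9)
  expect_true(is.na(m4$ppv))
  expect_equal(m4$npv, 0.5)

  # MCC is symmetric under simultaneous label-and-prediction swap
  sc5 <- c(0.9, 0.3, 0.6, 0.2, 0.7, 0.4)
  lb5 <- c(1, 0, 0, 0, 1, 1)
  m5a <- compute_metrics(sc5, lb5, 0.5)
  m5b <- compute_metrics(1 - sc5, 1 - lb5, 0.5 - 1e-12)
  expect_equal(m5a$mcc, m5b$mcc)
})

test_that("R-squared identities hold", {
  y <- c(3, 7, 1, 9, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(rep(mean(y), 5), y), 0)
  expect_lt(r_squared(y + 10, y), 0)  # worse than the mean predictor
  expect_error(r_squared(y, rep(2, 5)), "constant")
})

test_that("lambda tuning returns the requested grid point and breaks ties sparser", {
  d <- smoke_study(seed = 9)
  sc <- fit_feature_scaling(d$features)
  xs <- scale_features(d$features, sc)
  y <- d$characterized$lof
  one <- tune_lambda(xs, y, grid = 0.037, nfolds = 3, nrepeats = 1,
                     seed = 5)
  expect_equal(one$lambda, 0.037)
  # with all-equal cv scores (grid so large every fit is null) the larger
  # lambda wins
  big <- tune_lambda(xs, y, grid = c(5, 10, 20), nfolds = 3, nrepeats = 1,
                     seed = 5)
  expect_equal(big$lambda, 20)
})

test_that("repeated evaluation is bit-reproducible and respects split sizes", {
  st <- smoke_study(seed = 12)
  X <- st$features; y <- st$characterized$lof
  r1 <- repeated_evaluation(X, y, iterations = 2, test_fraction = 0.3,
                            seed = 77)
  r2 <- repeated_evaluation(X, y, iterations = 2, test_fraction = 0.3,
                            seed = 77)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$coefficients, r2$coefficients)
  expect_identical(r1$cutoffs, r2$cutoffs)
  expect_equal(sum(r1$split), nrow(X))
  expect_equal(unname(r1$split["test"]), round(0.3 * 20) + round(0.3 * 20))
  # aggregate mean lies within the per-fold range
  for (i in seq_len(nrow(r1$aggregate))) {
    v <- r1$metrics[[r1$aggregate$metric[i]]]
    v <- v[!is.na(v)]
    expect_gte(r1$aggregate$mean[i], min(v) - 1e-12)
    expect_lte(r1$aggregate$mean[i], max(v) + 1e-12)
  }
})

test_that("a one-cell model-selection grid reduces to repeated evaluation", {
  st <- smoke_study(seed = 13)
  y <- st$characterized$lof
  fsets <- list(sequence = st$features)
  ms <- model_selection(fsets, y, model_types = "penalized",
                        iterations = 2, test_fraction = 0.3, seed = 31)
  direct <- repeated_evaluation(st$features, y, iterations = 2,
                                test_fraction = 0.3, seed = 31)
  expect_equal(ms$grid$mean_auc,
               direct$aggregate$mean[direct$aggregate$metric == "auc"])
  # unavailable cells are marked, not dropped
  ms2 <- model_selection(list(sequence = st$features, structure = NULL), y,
                         model_types = "penalized", iterations = 2,
                         test_fraction = 0.3, seed = 31)
  expect_true(any(!ms2$grid$available))
  expect_equal(nrow(ms2$grid), 2L)
})

test_that("tree-ensemble fitters run through the generic contract", {
  st <- smoke_study(seed = 14)
  y <- st$characterized$lof
  rf <- repeated_evaluation(st$features, y, iterations = 1,
                            test_fraction = 0.3, seed = 3,
                            fitter = random_forest_fitter())
  gb <- repeated_evaluation(st$features, y, iterations = 1,
                            test_fraction = 0.3, seed = 3,
                            fitter = gradient_boosting_fitter())
  expect_true(rf$metrics$auc >= 0 && rf$metrics$auc <= 1)
  expect_true(gb$metrics$auc >= 0 && gb$metrics$auc <= 1)
  expect_null(rf$coefficients)
})

test_that("feature importance summarizes per-fold coefficient distributions", {
  st <- smoke_study(seed = 15)
  rep <- repeated_evaluation(st$features, st$characterized$lof,
                             iterations = 4, test_fraction = 0.3, seed = 8)
  fi <- feature_importance(rep)
  expect_setequal(fi$feature, colnames(rep$coefficients))
  zeroed <- fi[fi$frac_nonzero == 0, ]
  expect_true(all(zeroed$median == 0 & zeroed$iqr == 0))
  # invariant to fold order
  rep2 <- rep
  rep2$coefficients <- rep$coefficients[4:1, ]
  expect_equal(feature_importance(rep2), fi)
  expect_error(feature_importance(list(coefficients = NULL)),
               "no per-fold coefficients")
})

test_that("localization models are one-vs-rest and independent of each other", {
  st <- smoke_study(seed = 16)
  loc <- st$variants$localization
  # ensure all three classes exist in the smoke study
  skip_if(length(unique(loc)) < 3)
  fits <- fit_localization_models(st$features, loc, iterations = 2,
                                  test_fraction = 0.3, seed = 6)
  expect_s3_class(fits$membrane, "evaluation_report")
  expect_s3_class(fits$intracellular, "evaluation_report")
  # permuting mixed <-> intracellular changes model A's negative set but
  # not its positives: the membrane indicator is untouched
  swapped <- loc
  swapped[loc == "mixed"] <- "intracellular"
  swapped[loc == "intracellular"] <- "mixed"
  expect_identical(swapped == "membrane", loc == "membrane")
  expect_false(identical(swapped == "intracellular",
                         loc == "intracellular"))
  expect_error(fit_localization_models(st$features,
                                       rep("membrane", nrow(st$features))),
               "degenerate")
})
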