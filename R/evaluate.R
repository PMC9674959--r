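#' Rank-statistic AUC (Mann-Whitney with midrank ties)
#'
#' Area under the ROC curve computed from the rank statistic: the
#' probability that a random positive scores above a random negative,
#' counting ties as 1/2 (midranks). Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels 0/1 or logical labels (positive = 1).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select a binarizing cutoff maximizing sensitivity + specificity
#'
#' Evaluates sensitivity + specificity at every midpoint between adjacent
#' sorted unique scores (plus -Inf/+Inf sentinels) and returns the
#' maximizing cutoff; a prediction is positive when its score is strictly
#' above the cutoff. Ties are broken toward the smallest such cutoff.
#'
#' @param scores numeric scores (e.g. LOF probabilities).
#' @param labels 0/1 or logical labels (positive = LOF).
#' @return the selected cutoff.
#' @export
select_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to select a cutoff", call. = FALSE)
  }
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  j <- vapply(cand, function(ct) {
    pred <- scores > ct
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    sens + spec
  }, numeric(1))
  cand[which.max(j)]  # which.max returns the first (smallest) maximizer
}

#' Confusion-matrix metric suite at a cutoff
#'
#' Computes the standard binary-classification metrics with LOF as the
#' positive class (predicted positive when score > cutoff): sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN),
#' accuracy, Matthews correlation coefficient, and the rank-statistic AUC
#' (cutoff-free). A metric with a zero denominator is reported as `NA`,
#' never as 0.
#'
#' @param scores numeric scores.
#' @param labels 0/1 or logical labels (positive = LOF).
#' @param cutoff decision cutoff.
#' @return named list of class `metric_set`.
#' @export
compute_metrics <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to compute metrics", call. = FALSE)
  }
  pred <- scores > cutoff
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  mcc_den <- sqrt(prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))))
  structure(list(
    auc = auc_score(scores, labels),
    accuracy = (tp + tn) / length(labels),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    mcc = if (mcc_den == 0) NA_real_ else
      (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  ), class = "metric_set")
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`: the proportion of
#' variance in measured function explained by predicted function.
#'
#' @param pred predicted values.
#' @param y observed values (non-constant).
#' @return R-squared (can be negative for a worse-than-mean predictor).
#' @export
r_squared <- function(pred, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant y", call. = FALSE)
  1 - sum((y - pred)^2) / ss_tot
}

# stratified split indices: TRUE = test row
stratified_split <- function(labels, test_fraction, strata = NULL) {
  n <- length(labels)
  if (is.null(strata)) strata <- rep(1L, n)
  test <- logical(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    k <- max(1L, round(length(idx) * test_fraction))
    k <- min(k, length(idx) - 1L)
    test[sample(idx, k)] <- TRUE
  }
  test
}

# stratified fold assignment for inner cross-validation
stratified_folds <- function(y, nfolds) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  folds
}

#' Tune the L1 penalty by repeated stratified cross-validation
#'
#' Selects the penalty maximizing the mean cross-validated AUC
#' (classification) or R^2 (regression) over `nfolds x nrepeats` folds,
#' fitting the full coefficient path per fold with warm starts. Exact ties
#' are broken toward the larger penalty (sparser model).
#'
#' @param x scaled feature matrix.
#' @param y labels (0/1) or numeric response.
#' @param grid optional decreasing lambda grid (default 50 log-spaced).
#' @param nfolds,nrepeats inner cross-validation shape.
#' @param seed RNG seed for fold assignment.
#' @param family `"binomial"` or `"gaussian"`.
#' @return list with `lambda` (selected), `grid`, `cv_score` (mean per
#'   grid value).
#' @export
tune_lambda <- function(x, y, grid = NULL, nfolds = 5, nrepeats = 5,
                        seed = 1, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (is.null(grid)) grid <- lambda_grid(x, y, family, 50, 1e-3)
  grid <- sort(grid, decreasing = TRUE)
  set.seed(seed)
  scores <- matrix(NA_real_, nrow = nfolds * nrepeats, ncol = length(grid))
  row <- 0L
  for (rep in seq_len(nrepeats)) {
    folds <- if (family == "binomial") stratified_folds(y, nfolds)
             else rep_len(seq_len(nfolds), length(y))[sample(length(y))]
    for (f in seq_len(nfolds)) {
      row <- row + 1L
      tr <- folds != f
      if (family == "binomial" &&
          (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)) {
        next
      }
      fit <- lasso_path(x[tr, , drop = FALSE], y[tr], family, lambda = grid)
      eta <- sweep(x[!tr, , drop = FALSE] %*% fit$beta, 2, fit$intercept,
                   "+")
      scores[row, ] <- vapply(seq_along(grid), function(l) {
        if (family == "binomial") auc_score(eta[, l], y[!tr])
        else r_squared(eta[, l], y[!tr])
      }, numeric(1))
    }
  }
  mean_score <- colMeans(scores, na.rm = TRUE)
  if (all(is.nan(mean_score))) {
    stop("all inner folds degenerate: cannot tune lambda", call. = FALSE)
  }
  best <- which.max(mean_score)  # grid is decreasing: first max = largest
  list(lambda = grid[best], grid = grid, cv_score = mean_score)
}

# ---- generic fit/predict contract for the model-selection grid ----------

#' Model fitters for the model-selection grid
#'
#' Each fitter is a list with elements `fit(x, y, seed)` returning an
#' opaque model and `predict(model, x)` returning scores (LOF
#' probabilities for classification, predicted function for regression).
#' The penalized fitter tunes its penalty internally by cross-validation;
#' the tree ensembles (random forest, gradient boosting) run with fixed,
#' documented default hyperparameters and delegated implementations.
#'
#' @param task `"classification"` or `"regression"`.
#' @param nfolds,nrepeats,grid inner tuning shape for the penalized
#'   fitter.
#' @return a fitter list.
#' @name model_fitters
NULL

#' @rdname model_fitters
#' @export
penalized_fitter <- function(task = "classification", nfolds = 5,
                             nrepeats = 5, grid = NULL) {
  family <- if (task == "classification") "binomial" else "gaussian"
  list(
    name = "penalized",
    fit = function(x, y, seed) {
      tuned <- tune_lambda(x, y, grid = grid, nfolds = nfolds,
                           nrepeats = nrepeats, seed = seed,
                           family = family)
      if (family == "binomial") {
        fit_penalized_logistic(x, y, tuned$lambda)
      } else {
        fit_penalized_linear(x, y, tuned$lambda)
      }
    },
    predict = function(model, x) predict(model, x, type = "response"),
    coefs = function(model) model$coefficients
  )
}

#' @rdname model_fitters
#' @param ntree random-forest tree count.
#' @export
random_forest_fitter <- function(task = "classification", ntree = 500) {
  list(
    name = "random_forest",
    fit = function(x, y, seed) {
      set.seed(seed)
      if (task == "classification") {
        randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                   ntree = ntree)
      } else {
        randomForest::randomForest(x, y, ntree = ntree)
      }
    },
    predict = function(model, x) {
      if (model$type == "classification") {
        unname(stats::predict(model, x, type = "prob")[, "1"])
      } else {
        unname(stats::predict(model, x))
      }
    },
    coefs = function(model) NULL
  )
}

#' @rdname model_fitters
#' @param nrounds,eta,max_depth gradient-boosting defaults.
#' @export
gradient_boosting_fitter <- function(task = "classification",
                                     nrounds = 100, eta = 0.1,
                                     max_depth = 3) {
  list(
    name = "gradient_boosting",
    fit = function(x, y, seed) {
      set.seed(seed)
      yy <- if (task == "classification") factor(y, levels = c(0, 1))
            else as.numeric(y)
      xgboost::xgboost(as.matrix(x), yy, nrounds = nrounds,
                       learning_rate = eta, max_depth = max_depth,
                       nthreads = 1, verbosity = 0)
    },
    predict = function(model, x) {
      if (task == "classification") {
        as.numeric(stats::predict(model, as.matrix(x), type = "response"))
      } else {
        as.numeric(stats::predict(model, as.matrix(x)))
      }
    },
    coefs = function(model) NULL
  )
}

#' Repeated random-subsampling evaluation
#'
#' The study's resampling protocol: for each iteration, a stratified
#' random train/test split at `test_fraction`; feature scaling fitted on
#' the training rows only; the model fitted on the training rows (the
#' penalized fitter tunes its penalty by inner cross-validation); the
#' binarizing cutoff selected on training scores by maximizing
#' sensitivity + specificity; and the metric suite computed on the test
#' rows at that cutoff. Bit-reproducible given the seed.
#'
#' @param x raw (unscaled) feature matrix with variant rownames.
#' @param y 0/1 or logical labels (classification) or numeric response
#'   (regression).
#' @param iterations number of random subsampling iterations.
#' @param test_fraction held-out fraction per iteration.
#' @param seed master seed; per-iteration seeds derive from it.
#' @param fitter a fitter contract from [model_fitters]; defaults to the
#'   tuned penalized model.
#' @param task `"classification"` or `"regression"`.
#' @param lof_labels optional stratification labels for regression splits.
#' @return object of class `evaluation_report`: `metrics` (per-fold
#'   data.frame), `coefficients` (iterations x features matrix or NULL),
#'   `cutoffs`, `aggregate` (mean and sd per metric), `split` sizes,
#'   `seed`.
#' @export
repeated_evaluation <- function(x, y, iterations = 100, test_fraction = 0.3,
                                seed = 1, fitter = NULL,
                                task = c("classification", "regression"),
                                lof_labels = NULL) {
  task <- match.arg(task)
  stopifnot(iterations >= 1, test_fraction > 0, test_fraction < 1)
  x <- as.matrix(x)
  y <- if (task == "classification") as.numeric(as.logical(y))
       else as.numeric(y)
  if (is.null(fitter)) fitter <- penalized_fitter(task)
  strata <- if (task == "classification") y else lof_labels
  coefs <- NULL
  cutoffs <- numeric(iterations)
  rows <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    it_seed <- derive_seed(seed, it)
    set.seed(it_seed)
    test <- NULL
    for (try in 1:25) {
      cand <- stratified_split(y, test_fraction, strata)
      if (task == "regression" ||
          (length(unique(y[cand])) == 2L && length(unique(y[!cand])) == 2L)) {
        test <- cand
        break
      }
    }
    if (is.null(test)) {
      stop("could not produce a split with both classes on both sides",
           call. = FALSE)
    }
    sc <- fit_feature_scaling(x[!test, , drop = FALSE])
    xtr <- scale_features(x[!test, , drop = FALSE], sc)
    xte <- scale_features(x[test, , drop = FALSE], sc)
    model <- fitter$fit(xtr, y[!test], it_seed)
    if (task == "classification") {
      cut <- select_cutoff(fitter$predict(model, xtr), y[!test])
      m <- compute_metrics(fitter$predict(model, xte), y[test], cut)
      cutoffs[it] <- cut
      rows[[it]] <- as.data.frame(unclass(m))
    } else {
      pred <- fitter$predict(model, xte)
      cutoffs[it] <- NA_real_
      rows[[it]] <- data.frame(r_squared = r_squared(pred, y[test]),
                               rmse = sqrt(mean((pred - y[test])^2)))
    }
    cf <- fitter$coefs(model)
    if (!is.null(cf)) {
      if (is.null(coefs)) {
        coefs <- matrix(NA_real_, nrow = iterations, ncol = length(cf),
                        dimnames = list(NULL, names(cf)))
      }
      coefs[it, names(cf)] <- cf
    }
  }
  metrics <- do.call(rbind, rows)
  aggregate <- data.frame(
    metric = names(metrics),
    mean = vapply(metrics, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(metrics, function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
    row.names = NULL
  )
  structure(list(metrics = metrics, coefficients = coefs,
                 cutoffs = cutoffs, aggregate = aggregate,
                 split = c(train = sum(!test), test = sum(test)),
                 iterations = iterations, seed = seed, task = task,
                 fitter = fitter$name),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", x$iterations, "iterations of", x$fitter,
      "(", x$split["train"], "train /", x$split["test"], "test )\n")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}

#' Evaluate every (model type, feature set) grid cell
#'
#' Runs [repeated_evaluation()] for each combination of model type
#' (penalized regression, random forest, gradient boosting) and feature
#' set, and ranks cells by mean test AUC (classification) or mean R^2
#' (regression). A cell whose feature source is unavailable is marked
#' unavailable, never silently skipped.
#'
#' @param feature_sets named list of raw feature matrices (one per set).
#' @param y labels or response.
#' @param model_types character subset of the three model types.
#' @param iterations,test_fraction,seed protocol parameters.
#' @param task `"classification"` or `"regression"`.
#' @return list with `grid` (ranked data.frame) and `reports` (nested
#'   list by model type then feature set).
#' @export
model_selection <- function(feature_sets, y,
                            model_types = c("penalized", "random_forest",
                                            "gradient_boosting"),
                            iterations = 100, test_fraction = 0.2,
                            seed = 1,
                            task = c("classification", "regression")) {
  task <- match.arg(task)
  fitters <- list(penalized = penalized_fitter(task),
                  random_forest = random_forest_fitter(task),
                  gradient_boosting = gradient_boosting_fitter(task))
  fitters <- fitters[model_types]
  key_metric <- if (task == "classification") "auc" else "r_squared"
  rows <- list()
  reports <- list()
  for (mt in names(fitters)) {
    reports[[mt]] <- list()
    for (fs in names(feature_sets)) {
      xmat <- feature_sets[[fs]]
      if (is.null(xmat)) {
        rows[[length(rows) + 1L]] <-
          data.frame(model = mt, feature_set = fs, mean = NA_real_,
                     sd = NA_real_, available = FALSE)
        next
      }
      rep <- repeated_evaluation(xmat, y, iterations = iterations,
                                 test_fraction = test_fraction,
                                 seed = seed, fitter = fitters[[mt]],
                                 task = task)
      reports[[mt]][[fs]] <- rep
      agg <- rep$aggregate
      rows[[length(rows) + 1L]] <-
        data.frame(model = mt, feature_set = fs,
                   mean = agg$mean[agg$metric == key_metric],
                   sd = agg$sd[agg$metric == key_metric],
                   available = TRUE)
    }
  }
  grid <- do.call(rbind, rows)
  grid <- grid[order(-grid$mean), ]
  rownames(grid) <- NULL
  names(grid)[names(grid) == "mean"] <- paste0("mean_", key_metric)
  list(grid = grid, reports = reports)
}

#' Per-feature coefficient distribution across evaluation folds
#'
#' Summarizes the fitted LASSO coefficients across resampling iterations:
#' median, quartiles/IQR, Tukey-style whiskers (most extreme value within
#' 1.5 IQR of the quartiles), and the fraction of folds in which the
#' feature kept a nonzero coefficient. Comparable across features because
#' inputs were scaled 0-1.
#'
#' @param report an `evaluation_report` with retained coefficients.
#' @return data.frame sorted by `|median|` (descending).
#' @export
feature_importance <- function(report) {
  cf <- report$coefficients
  if (is.null(cf)) {
    stop("report has no per-fold coefficients (tree-ensemble fitter?)",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(colnames(cf), function(f) {
    v <- cf[, f]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- v[v >= q[1] - 1.5 * iqr]
    hi <- v[v <= q[3] + 1.5 * iqr]
    data.frame(feature = f, median = q[2], q25 = q[1], q75 = q[3],
               iqr = iqr,
               whisker_low = if (length(lo)) min(lo) else q[1],
               whisker_high = if (length(hi)) max(hi) else q[3],
               frac_nonzero = mean(v != 0),
               stringsAsFactors = FALSE)
  }))
  out[order(-abs(out$median)), ]
}

#' Train and evaluate the two subcellular-localization classifiers
#'
#' Localization is three-class (membrane / mixed / intracellular), so two
#' one-vs-rest models are trained: model A predicts full membrane
#' localization (membrane vs mixed-or-intracellular) and model B predicts
#' full intracellular retention (intracellular vs membrane-or-mixed).
#' Both use the same repeated random-subsampling protocol as the function
#' classifier.
#'
#' @param x raw feature matrix.
#' @param localization character vector of the three class labels.
#' @param iterations,test_fraction,seed protocol parameters.
#' @param fitter optional fitter contract (default tuned penalized model).
#' @return list with `membrane` and `intracellular` evaluation reports.
#' @export
fit_localization_models <- function(x, localization, iterations = 100,
                                    test_fraction = 0.3, seed = 1,
                                    fitter = NULL) {
  localization <- as.character(localization)
  classes <- c("membrane", "mixed", "intracellular")
  bad <- setdiff(unique(localization), classes)
  if (length(bad) > 0L) {
    stop("unknown localization class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(localization, levels = classes))
  if (any(counts == 0L)) {
    stop("degenerate labels: all three localization classes required",
         call. = FALSE)
  }
  list(
    membrane = repeated_evaluation(
      x, localization == "membrane", iterations = iterations,
      test_fraction = test_fraction, seed = derive_seed(seed, 1001L),
      fitter = fitter),
    intracellular = repeated_evaluation(
      x, localization == "intracellular", iterations = iterations,
      test_fraction = test_fraction, seed = derive_seed(seed, 1002L),
      fitter = fitter)
  )
}
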