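#' @useDynLib octnvep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' L1-penalized model path over a decreasing lambda grid
#'
#' Fits the LASSO coefficient path by coordinate descent with warm starts.
#' The objective is the mean negative log-likelihood (binomial) or
#' `1/(2n)` times the residual sum of squares (gaussian) plus
#' `lambda * sum(|beta_j|)` with an unpenalized intercept. No internal
#' standardization is performed: features are expected on the 0-1 scale
#' produced by [scale_features()].
#'
#' @param x numeric feature matrix (finite values).
#' @param y response: 0/1 labels (binomial) or numeric (gaussian).
#' @param family `"binomial"` or `"gaussian"`.
#' @param lambda optional decreasing penalty grid; by default `nlambda`
#'   log-spaced values from the smallest lambda that zeroes every
#'   coefficient down to `lambda_min_ratio` times it.
#' @param nlambda,lambda_min_ratio default grid shape.
#' @param tol convergence tolerance on coefficient updates.
#' @param max_sweeps coordinate-sweep cap per weighted subproblem.
#' @return list with `lambda`, `intercept` (length nlambda) and `beta`
#'   (p x nlambda matrix, rows named by feature).
#' @export
lasso_path <- function(x, y, family = c("binomial", "gaussian"),
                       lambda = NULL, nlambda = 50,
                       lambda_min_ratio = 1e-3, tol = 1e-7,
                       max_sweeps = 2000L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (!all(is.finite(y))) stop("non-finite response values", call. = FALSE)
  stopifnot(nrow(x) == length(y))
  if (family == "binomial") {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("binomial y must be 0/1", call. = FALSE)
    if (length(unique(y)) < 2L) {
      stop("degenerate labels: both classes must be present", call. = FALSE)
    }
  }
  if (is.null(lambda)) {
    lambda <- lambda_grid(x, y, family, nlambda, lambda_min_ratio)
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  fit <- .cd_lasso_path(x, y, lambda, family, tol, as.integer(max_sweeps))
  rownames(fit$beta) <- colnames(x)
  list(lambda = lambda, intercept = as.numeric(fit$intercept),
       beta = fit$beta, family = family)
}

# smallest lambda that zeroes all coefficients, then log-spaced descent
lambda_grid <- function(x, y, family, nlambda, lambda_min_ratio) {
  n <- nrow(x)
  resid0 <- if (family == "binomial") y - mean(y) else y - mean(y)
  lmax <- max(abs(crossprod(x, resid0)) / n)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

new_penalized_model <- function(task, intercept, coefficients, lambda,
                                cutoff = NULL, scaling = NULL) {
  structure(list(task = task, intercept = intercept,
                 coefficients = coefficients, lambda = lambda,
                 cutoff = cutoff, scaling = scaling),
            class = "penalized_model")
}

#' Fit an L1-penalized logistic regression model
#'
#' Minimizes the mean negative log-likelihood of the logistic model plus
#' `lambda * sum(|beta_j|)` (intercept unpenalized) by coordinate descent
#' within IRLS. Deterministic given (x, y, lambda, tol). For numerical
#' robustness the solver warms up along a short path from the
#' all-zero-coefficient lambda down to the requested value.
#'
#' @param x scaled feature matrix.
#' @param y 0/1 (or logical) LOF labels; both classes must be present.
#' @param lambda penalty weight (>= 0).
#' @param cutoff optional probability cutoff to store with the model.
#' @param scaling optional `feature_scaling` to store with the model.
#' @param tol convergence tolerance.
#' @return object of class `penalized_model` (task "classification").
#' @export
fit_penalized_logistic <- function(x, y, lambda, cutoff = NULL,
                                   scaling = NULL, tol = 1e-14) {
  stopifnot(lambda >= 0)
  if (!all(is.finite(as.matrix(x)))) {
    stop("non-finite feature values", call. = FALSE)
  }
  y <- as.numeric(y)
  path <- warmup_lambda(x, y, "binomial", lambda)
  fit <- lasso_path(x, y, "binomial", lambda = path, tol = tol)
  k <- length(path)
  new_penalized_model("classification", fit$intercept[k],
                      stats::setNames(fit$beta[, k], colnames(x)),
                      lambda, cutoff = cutoff, scaling = scaling)
}

#' Fit an L1-penalized linear regression model
#'
#' Minimizes `1/(2n)` times the residual sum of squares plus
#' `lambda * sum(|beta_j|)` (intercept unpenalized).
#'
#' @inheritParams fit_penalized_logistic
#' @param y numeric response (percent-of-WT function).
#' @return object of class `penalized_model` (task "regression").
#' @export
fit_penalized_linear <- function(x, y, lambda, scaling = NULL, tol = 1e-14) {
  stopifnot(lambda >= 0, length(y) >= 2L)
  if (!all(is.finite(as.matrix(x)))) {
    stop("non-finite feature values", call. = FALSE)
  }
  path <- warmup_lambda(x, y, "gaussian", lambda)
  fit <- lasso_path(x, y, "gaussian", lambda = path, tol = tol)
  k <- length(path)
  new_penalized_model("regression", fit$intercept[k],
                      stats::setNames(fit$beta[, k], colnames(x)),
                      lambda, scaling = scaling)
}

# short warm-start path ending exactly at the requested lambda
warmup_lambda <- function(x, y, family, lambda, steps = 10L) {
  x <- as.matrix(x)
  lmax <- max(lambda_grid(x, as.numeric(y), family, 2L, 0.999)[1], lambda)
  if (lmax <= lambda || lambda == 0) {
    lmax <- max(lmax, 1e-8)
    lo <- max(lambda, lmax * 1e-4)
    path <- exp(seq(log(lmax), log(lo), length.out = steps))
    return(unique(sort(c(path, lambda), decreasing = TRUE)))
  }
  exp(seq(log(lmax), log(lambda), length.out = steps))
}

#' @export
predict.penalized_model <- function(object, newdata,
                                    type = c("response", "link", "class"),
                                    ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  feats <- names(object$coefficients)
  if (!is.null(colnames(x))) {
    if (!all(feats %in% colnames(x))) {
      stop("newdata lacks feature column(s): ",
           paste(setdiff(feats, colnames(x)), collapse = ", "),
           call. = FALSE)
    }
    x <- x[, feats, drop = FALSE]
  } else if (ncol(x) != length(feats)) {
    stop("newdata has ", ncol(x), " columns; model expects ",
         length(feats), call. = FALSE)
  }
  eta <- drop(object$intercept + x %*% object$coefficients)
  if (object$task == "regression") return(eta)
  if (type == "link") return(eta)
  p <- stats::plogis(eta)
  if (type == "response") return(p)
  cutoff <- if (is.null(object$cutoff)) 0.5 else object$cutoff
  p > cutoff
}

#' @export
coef.penalized_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.penalized_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("penalized_model (", x$task, "): lambda = ", signif(x$lambda, 4),
      ", ", nz, "/", length(x$coefficients), " nonzero coefficients",
      if (!is.null(x$cutoff)) paste0(", cutoff = ", signif(x$cutoff, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a penalized model to JSON
#'
#' Stores coefficients, intercept, penalty, cutoff, scaling parameters and
#' seed so a trained predictor can be reloaded and applied elsewhere.
#'
#' @param model a `penalized_model`.
#' @param path output JSON path.
#' @param seed optional seed to record.
#' @export
write_model_json <- function(model, path, seed = NULL) {
  obj <- list(task = model$task, intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              lambda = model$lambda, cutoff = model$cutoff,
              seed = seed, version = "1")
  if (!is.null(model$scaling)) {
    obj$scaling <- list(features = model$scaling$features,
                        min = model$scaling$min, max = model$scaling$max,
                        impute_mean = model$scaling$impute_mean,
                        has_missing = model$scaling$has_missing)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized penalized model
#'
#' @param path JSON path written by [write_model_json()].
#' @return a `penalized_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaling <- NULL
  if (!is.null(obj$scaling)) {
    scaling <- structure(list(
      features = obj$scaling$features,
      min = stats::setNames(obj$scaling$min, obj$scaling$features),
      max = stats::setNames(obj$scaling$max, obj$scaling$features),
      impute_mean = stats::setNames(obj$scaling$impute_mean,
                                    obj$scaling$features),
      has_missing = stats::setNames(as.logical(obj$scaling$has_missing),
                                    obj$scaling$features),
      constant = obj$scaling$features[obj$scaling$min == obj$scaling$max]
    ), class = "feature_scaling")
  }
  new_penalized_model(obj$task, obj$intercept,
                      unlist(obj$coefficients), obj$lambda,
                      cutoff = obj$cutoff, scaling = scaling)
}
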