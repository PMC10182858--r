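#' Labeled set of amplitude profiles
#'
#' Container pairing amplitude-vs-distance profiles with the true generating
#' parameters, used to train and evaluate the inverse models.
#'
#' @param a_water,a_lipid numeric matrices, one row per configuration, one
#'   column per distance.
#' @param targets data frame with one row per configuration; conventional
#'   columns `dermis_water`, `dermis_thickness`, `hypodermis_thickness`.
#' @param distances mm, matching the matrix columns.
#' @param split optional character vector `"train"`/`"test"` per row.
#' @export
labeled_profile_set <- function(a_water, a_lipid, targets, distances,
                                split = NULL) {
  n <- nrow(targets)
  stopifnot(nrow(a_water) == n, nrow(a_lipid) == n,
            ncol(a_water) == length(distances),
            ncol(a_lipid) == length(distances))
  if (!is.null(split)) {
    stopifnot(length(split) == n, all(split %in% c("train", "test")))
  }
  structure(list(a_water = a_water, a_lipid = a_lipid,
                 targets = targets, distances = distances, split = split),
            class = "labeled_profile_set")
}

#' Assign a random train/test split
#'
#' @param set a [labeled_profile_set()].
#' @param test_fraction held-out fraction (default 5%).
#' @param seed split seed (recorded in downstream reports).
#' @export
assign_split <- function(set, test_fraction = 0.05, seed = 1) {
  n <- nrow(set$targets)
  nt <- max(1L, round(test_fraction * n))
  test <- withr::with_seed(seed, sample(n, nt))
  set$split <- rep("train", n)
  set$split[test] <- "test"
  set$split_seed <- seed
  set
}

feature_column <- function(set, feature = c("a_water", "a_lipid"),
                           distance) {
  feature <- match.arg(feature)
  j <- match(distance, set$distances)
  if (is.na(j)) stop("distance not in the profile set")
  set[[feature]][, j]
}

target_column <- function(set, target) {
  y <- set$targets[[target]]
  if (is.null(y)) stop("unknown target: ", target)
  y
}

#' Single-distance linear inverse model
#'
#' Univariate ordinary least squares of a skin parameter on one amplitude at
#' one source-detector distance.
#'
#' @param set a [labeled_profile_set()].
#' @param feature `"a_water"` or `"a_lipid"`.
#' @param distance mm, one of the set's distances.
#' @param target name of the target column in `set$targets`.
#' @param rows optional row indices to fit on (default: all rows, or the
#'   train split if one is assigned).
#' @return object of class `regression_model`.
#' @export
fit_single_distance <- function(set, feature, distance, target,
                                rows = NULL) {
  if (is.null(rows))
    rows <- if (is.null(set$split)) seq_len(nrow(set$targets)) else
      which(set$split == "train")
  if (length(rows) < 3) stop("need at least 3 training profiles")
  x <- feature_column(set, feature, distance)[rows]
  y <- target_column(set, target)[rows]
  if (sd(x) == 0) stop("zero-variance feature at this distance")
  X <- cbind(1, x)
  beta <- qr.coef(qr(X), y)
  structure(list(target = target, feature = feature, distance = distance,
                 intercept = unname(beta[1]), slope = unname(beta[2]),
                 n_train = length(rows), kind = "single-distance OLS"),
            class = "regression_model")
}

#' @export
predict.regression_model <- function(object, set, rows = NULL, ...) {
  if (is.null(rows)) rows <- seq_len(nrow(set$targets))
  if (object$kind == "single-distance OLS") {
    x <- feature_column(set, object$feature, object$distance)[rows]
    object$intercept + object$slope * x
  } else {
    X <- ridge_features(set)[rows, , drop = FALSE]
    drop(object$intercept + X %*% object$coefficients)
  }
}

#' Mean relative error per configuration set
#'
#' The headline accuracy metric: `delta = mean(|pred - true| / true)`.
#' Undefined (error) when any true value is zero.
#'
#' @param pred,truth equal-length numeric vectors.
#' @export
relative_error <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (any(truth == 0)) stop("relative error undefined for true value 0")
  mean(abs(pred - truth) / abs(truth))
}

#' Relative-error curve over source-detector distance
#'
#' For every distance, fits the single-distance model and evaluates the mean
#' relative error of the target. `mode = "insample"` (default) fits and
#' evaluates on all configurations, matching the plain regression protocol
#' for single-distance models; `mode = "heldout"` fits on the train split
#' and evaluates on the test split.
#'
#' @inheritParams fit_single_distance
#' @param mode `"insample"` or `"heldout"`.
#' @return data.frame of class `error_curve`: `distance`, `delta`; the
#'   minimizing distance is in `attr(, "argmin")`.
#' @export
error_vs_distance <- function(set, feature, target,
                              mode = c("insample", "heldout")) {
  mode <- match.arg(mode)
  n <- nrow(set$targets)
  if (mode == "heldout") {
    if (is.null(set$split)) stop("heldout mode requires an assigned split")
    fit_rows <- which(set$split == "train")
    eval_rows <- which(set$split == "test")
  } else {
    fit_rows <- eval_rows <- seq_len(n)
  }
  truth <- target_column(set, target)[eval_rows]
  delta <- vapply(set$distances, function(r) {
    m <- fit_single_distance(set, feature, r, target, rows = fit_rows)
    relative_error(predict(m, set, rows = eval_rows), truth)
  }, 1)
  out <- data.frame(distance = set$distances, delta = delta)
  class(out) <- c("error_curve", "data.frame")
  attr(out, "feature") <- feature
  attr(out, "target") <- target
  attr(out, "mode") <- mode
  attr(out, "argmin") <- set$distances[which.min(delta)]
  out
}

ridge_features <- function(set) {
  X <- cbind(set$a_water, set$a_lipid)
  colnames(X) <- c(paste0("a_water_", set$distances),
                   paste0("a_lipid_", set$distances))
  X
}

# closed-form ridge with unpenalized intercept on a centered,
# sample-sd-standardized design; alpha = 0 reduces to OLS
ridge_solve <- function(X, y, alpha) {
  xm <- colMeans(X)
  xs <- apply(X, 2, sd)
  xs[xs == 0] <- 1
  Xs <- scale(X, center = xm, scale = xs)
  ym <- mean(y)
  p <- ncol(X)
  A <- crossprod(Xs) + diag(rep(alpha, p), p)
  b <- drop(solve(A, crossprod(Xs, y - ym)))
  beta <- b / xs
  list(intercept = ym - sum(beta * xm), coefficients = beta)
}

#' All-distance ridge inverse model
#'
#' Linear regression of a skin parameter on the water and lipid amplitudes
#' at every source-detector distance jointly. The multi-distance amplitudes
#' are highly correlated, so the squared-norm (L2) penalty controls
#' overfitting; its strength is chosen by k-fold cross-validation on the
#' training split and the model is evaluated only on the untouched test
#' split.
#'
#' @param set a [labeled_profile_set()] with an assigned split (see
#'   [assign_split()]).
#' @param target name of the target column.
#' @param alphas candidate L2 penalties (default logarithmic,
#'   1e-4 ... 1e2, 13 points).
#' @param nfolds cross-validation folds on the training split.
#' @param seed fold-assignment seed.
#' @return `regression_model` with fields `alpha`, `report` (test-split
#'   [evaluate_predictions()]), `predictions_test` and provenance.
#' @export
fit_ridge_all_distances <- function(set, target,
                                    alphas = 10^seq(-4, 2, length.out = 13),
                                    nfolds = 5, seed = 1) {
  if (is.null(set$split)) stop("ridge model requires a train/test split")
  train <- which(set$split == "train")
  test <- which(set$split == "test")
  if (length(intersect(train, test)) > 0) stop("train/test overlap")
  X <- ridge_features(set)
  y <- target_column(set, target)
  alphas <- sort(alphas)
  alpha <- alphas[1]
  if (length(alphas) > 1) {
    folds <- withr::with_seed(seed,
                              sample(rep(seq_len(nfolds),
                                         length.out = length(train))))
    cv_mse <- vapply(alphas, function(a) {
      se <- unlist(lapply(seq_len(nfolds), function(f) {
        tr <- train[folds != f]
        va <- train[folds == f]
        fit <- ridge_solve(X[tr, , drop = FALSE], y[tr], a)
        pred <- drop(fit$intercept +
                       X[va, , drop = FALSE] %*% fit$coefficients)
        (pred - y[va])^2
      }))
      mean(se)
    }, 1)
    alpha <- alphas[which.min(cv_mse)]
  }
  fit <- ridge_solve(X[train, , drop = FALSE], y[train], alpha)
  pred_test <- drop(fit$intercept +
                      X[test, , drop = FALSE] %*% fit$coefficients)
  structure(list(target = target, feature = "a_water+a_lipid",
                 distance = set$distances,
                 intercept = fit$intercept, coefficients = fit$coefficients,
                 alpha = alpha, alphas = alphas,
                 n_train = length(train), n_test = length(test),
                 split_seed = set$split_seed, cv_seed = seed,
                 predictions_test = pred_test,
                 report = evaluate_predictions(pred_test, y[test]),
                 kind = "all-distance ridge"),
            class = "regression_model")
}

#' Leave-one-out evaluation of the ridge inverse model
#'
#' Each profile is predicted by a model trained on all the others; the
#' held-out predictions are aggregated into one evaluation report. Used for
#' small cohorts where a fixed test split would be wasteful.
#'
#' @param set a [labeled_profile_set()] (n >= 3).
#' @param target target column name.
#' @param alpha either a fixed numeric L2 penalty or `"cv"` to select it by
#'   cross-validation inside every fold.
#' @param alphas candidate grid when `alpha = "cv"`.
#' @param seed fold seed for the inner cross-validation.
#' @return list with the held-out `predictions`, `truth` and the
#'   [evaluate_predictions()] `report`.
#' @export
leave_one_out <- function(set, target, alpha = "cv",
                          alphas = 10^seq(-4, 2, length.out = 13),
                          seed = 1) {
  n <- nrow(set$targets)
  if (n < 3) stop("leave-one-out requires at least 3 profiles")
  X <- ridge_features(set)
  y <- target_column(set, target)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    a <- alpha
    if (identical(alpha, "cv")) {
      folds <- withr::with_seed(seed + i,
                                sample(rep(1:5, length.out = length(tr))))
      cv_mse <- vapply(alphas, function(aa) {
        se <- unlist(lapply(1:5, function(f) {
          t2 <- tr[folds != f]; v2 <- tr[folds == f]
          fit <- ridge_solve(X[t2, , drop = FALSE], y[t2], aa)
          (drop(fit$intercept + X[v2, , drop = FALSE] %*%
                  fit$coefficients) - y[v2])^2
        }))
        mean(se)
      }, 1)
      a <- alphas[which.min(cv_mse)]
    }
    fit <- ridge_solve(X[tr, , drop = FALSE], y[tr], a)
    pred[i] <- fit$intercept + sum(X[i, ] * fit$coefficients)
  }
  list(predictions = pred, truth = y,
       report = evaluate_predictions(pred, y))
}

#' Evaluation report for an inverse model
#'
#' RMSE, mean relative error, and the Pearson correlation between predicted
#' and true values with the two-sided p-value of the non-correlation
#' hypothesis (t-distribution, n-2 degrees of freedom).
#'
#' @param predictions,truths equal-length vectors, n >= 2.
#' @return object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(predictions, truths) {
  if (length(predictions) != length(truths)) stop("length mismatch")
  n <- length(truths)
  if (n < 2) stop("need at least 2 pairs")
  r <- suppressWarnings(cor(predictions, truths))
  # two-sided p from the t-distribution on n - 2 df; undefined for n = 2
  # and for numerically perfect correlation (p -> 0)
  p <- if (n < 3 || is.na(r)) {
    NA_real_
  } else if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rmse = sqrt(mean((predictions - truths)^2)),
                 relative_error = relative_error(predictions, truths),
                 pearson_r = r,
                 p_value = p,
                 n = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n=%d | RMSE %.4g | rel. error %.1f%% | Pearson R %.3f (p=%.2g)\n",
    x$n, x$rmse, 100 * x$relative_error, x$pearson_r, x$p_value))
  invisible(x)
}
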