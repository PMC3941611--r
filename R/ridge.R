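# Ridge regression from contact-vector features to binding free energy
# change, leave-one-out evaluation, and hot-spot classification metrics.

#' Fit a ridge regression model
#'
#' Columns are z-scored from the training rows (constant columns get a zero
#' coefficient), the response is centred, and the coefficients minimise
#' `||y - X b||^2 + lambda ||b||^2` on the normalised scale via the
#' deterministic closed-form solve.
#'
#' @param X Numeric feature matrix (rows = mutations).
#' @param y Numeric response (kcal/mol).
#' @param lambda Ridge penalty on the z-scored columns.
#' @return A `bacv_ridge` model: coefficients (normalised scale),
#'   per-column means/sds and the training mean of `y`.
#' @export
ridge_fit <- function(X, y, lambda = 1.0) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("ridge_fit needs at least 2 rows")
  stopifnot(nrow(X) == length(y), lambda >= 0)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  active <- which(sdv > 0)
  Z <- sweep(sweep(X[, active, drop = FALSE], 2, mu[active]), 2, sdv[active],
             "/")
  yc <- y - mean(y)
  b <- rep(0, ncol(X))
  if (length(active) > 0) {
    A <- crossprod(Z) + diag(lambda, length(active))
    sol <- tryCatch(solve(A, crossprod(Z, yc)), error = function(e) NULL)
    if (is.null(sol)) {
      # rank-deficient unpenalised fit: minimum-norm least squares
      sol <- qr.coef(qr(Z, LAPACK = TRUE), yc)
      sol[is.na(sol)] <- 0
    }
    b[active] <- sol
  }
  structure(list(coef = b, col_mean = mu, col_sd = sdv,
                 y_mean = mean(y), lambda = lambda),
            class = "bacv_ridge")
}

#' Coefficients of a ridge model on the original feature scale
#'
#' @param object A `bacv_ridge` model.
#' @param ... Unused.
#' @return Numeric vector: intercept followed by one coefficient per
#'   feature column.
#' @export
coef.bacv_ridge <- function(object, ...) {
  sdv <- ifelse(object$col_sd > 0, object$col_sd, 1)
  b <- object$coef / sdv
  c(intercept = object$y_mean - sum(b * object$col_mean), b)
}

#' Predict from a ridge model
#'
#' @param object A `bacv_ridge` model.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Predicted values (kcal/mol).
#' @export
predict.bacv_ridge <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  sdv <- ifelse(object$col_sd > 0, object$col_sd, 1)
  Z <- sweep(sweep(X, 2, object$col_mean), 2, sdv, "/")
  drop(object$y_mean + Z %*% object$coef)
}

#' Leave-one-out (or leave-one-group-out) cross-validated predictions
#'
#' Each row is predicted by a model trained on all other rows, with column
#' normalisation re-estimated inside every fold. With `groups`, all rows of
#' a group are held out together (leave-one-complex-out evaluation).
#'
#' @param X Feature matrix.
#' @param y Response vector.
#' @param lambda Ridge penalty.
#' @param groups Optional grouping vector (length `nrow(X)`).
#' @return Numeric vector of out-of-fold predictions.
#' @export
loocv_predict <- function(X, y, lambda = 1.0, groups = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out evaluation needs at least 3 rows")
  if (is.null(groups)) groups <- seq_len(n)
  pred <- numeric(n)
  for (g in unique(groups)) {
    out <- which(groups == g)
    fit <- ridge_fit(X[-out, , drop = FALSE], y[-out], lambda)
    pred[out] <- predict(fit, X[out, , drop = FALSE])
  }
  pred
}

#' Regression evaluation: correlation, squared error and outliers
#'
#' `SE` is the mean squared error with an `N - 1` denominator and `delta`
#' (average standard deviation) its square root. Predictions below -3 or
#' above 11 kcal/mol are flagged as outliers; the Pearson correlation is
#' reported both on all data and with the outliers removed. Outliers are
#' never dropped from `SE`/`delta`.
#'
#' @param pred,exp Predicted and experimental values (kcal/mol).
#' @param outlier_low,outlier_high Outlier bounds on the predictions.
#' @return List with `R`, `R_no_outliers`, `SE`, `delta`, `outliers`
#'   (indices). `R` is `NA` when either vector has zero variance.
#' @export
regression_metrics <- function(pred, exp, outlier_low = -3,
                               outlier_high = 11) {
  stopifnot(length(pred) == length(exp), length(pred) >= 3)
  n <- length(pred)
  SE <- sum((exp - pred)^2) / (n - 1)
  r_or_na <- function(p, e) {
    if (sd(p) == 0 || sd(e) == 0) NA_real_ else cor(p, e)
  }
  out <- which(pred < outlier_low | pred > outlier_high)
  keep <- setdiff(seq_len(n), out)
  list(R = r_or_na(pred, exp),
       R_no_outliers = if (length(keep) >= 3)
         r_or_na(pred[keep], exp[keep]) else NA_real_,
       SE = SE, delta = sqrt(SE), outliers = out)
}

#' Hot-spot call from predicted binding free energy change
#'
#' A mutation is a predicted hot spot iff its predicted change is at least
#' 2 kcal/mol (inclusive), the same threshold that defines true hot spots.
#'
#' @param pred Predicted values (kcal/mol).
#' @param threshold Hot-spot threshold (kcal/mol).
#' @return Logical vector.
#' @export
classify_hotspots <- function(pred, threshold = 2.0) {
  pred >= threshold
}

#' Hot-spot classification metrics
#'
#' Precision, recall, accuracy and F1 with hot spots as the positive class.
#' When there is no positive prediction, precision (and hence F1) is
#' reported as 0 with `precision_defined = FALSE`.
#'
#' @param pred_label,true_label Logical vectors (hot spot = `TRUE`).
#' @return List with `TP`, `FP`, `TN`, `FN`, `precision`, `recall`, `F1`,
#'   `accuracy`, `precision_defined`.
#' @export
classification_metrics <- function(pred_label, true_label) {
  stopifnot(length(pred_label) == length(true_label))
  TP <- sum(pred_label & true_label)
  FP <- sum(pred_label & !true_label)
  TN <- sum(!pred_label & !true_label)
  FN <- sum(!pred_label & true_label)
  prec_def <- (TP + FP) > 0
  precision <- if (prec_def) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(TP = TP, FP = FP, TN = TN, FN = FN, precision = precision,
       recall = recall, F1 = F1,
       accuracy = (TP + TN) / length(pred_label),
       precision_defined = prec_def)
}

#' Leave-one-out evaluation report
#'
#' Runs [loocv_predict()] and derives the regression and classification
#' measures in one report.
#'
#' @param X Feature matrix.
#' @param y Experimental binding free energy changes (kcal/mol).
#' @param lambda Ridge penalty.
#' @param groups Optional grouping for leave-one-complex-out evaluation.
#' @param threshold Hot-spot threshold (kcal/mol).
#' @return A `bacv_evaluation` list: predictions plus all fields of
#'   [regression_metrics()] and [classification_metrics()].
#' @export
evaluate_ddg <- function(X, y, lambda = 1.0, groups = NULL, threshold = 2.0) {
  pred <- loocv_predict(X, y, lambda, groups)
  reg <- regression_metrics(pred, y)
  cls <- classification_metrics(classify_hotspots(pred, threshold),
                                y >= threshold)
  structure(c(list(pred = pred, lambda = lambda, n = length(y)), reg, cls),
            class = "bacv_evaluation")
}

#' @export
print.bacv_evaluation <- function(x, ...) {
  cat("Leave-one-out evaluation of", x$n, "mutations (lambda =", x$lambda,
      ")\n")
  cat(sprintf("  R = %.3f (no outliers: %.3f), SE = %.3f, delta = %.3f\n",
              x$R, x$R_no_outliers, x$SE, x$delta))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  precision = %.3f, recall = %.3f, F1 = %.3f, accuracy = %.3f\n",
              x$precision, x$recall, x$F1, x$accuracy))
  invisible(x)
}
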