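# SVM classification of drowsy (+1) vs alert (-1) windows, with the C/gamma
# grid and leave-one-out validation protocol. The quadratic-programming dual
# is solved by the libsvm backend (e1071); the trained-model contract is the
# dual solution itself -- multipliers, bias, kernel -- and KKT feasibility is
# checked after every fit.

.label_pm1 <- function(y) {
  lab <- as.character(y)
  lab[lab == "drowsy"] <- "1"
  lab[lab == "alert"] <- "-1"
  v <- suppressWarnings(as.numeric(lab))
  if (any(is.na(v)) || !all(v %in% c(-1, 1)))
    stop("labels must be drowsy/alert or +1/-1")
  v
}

#' Default hyperparameter grid
#'
#' Linear kernel over C in {10, 1, 0.1} plus RBF kernel over the full
#' C x gamma product of {10, 1, 0.1} -- twelve cells, including the
#' historically best-performing cell (RBF, gamma = 0.1, C = 1).
#'
#' @param C,gamma Candidate values.
#' @return Data frame with columns `kernel`, `C`, `gamma` (`NA` for linear).
#' @export
default_svm_grid <- function(C = c(10, 1, 0.1), gamma = c(10, 1, 0.1)) {
  rbind(data.frame(kernel = "linear", C = C, gamma = NA_real_),
        expand.grid(kernel = "rbf", C = C, gamma = gamma,
                    stringsAsFactors = FALSE))
}

#' Train a soft-margin SVM
#'
#' Fits the C-classification SVM by solving the standard dual problem
#' (maximize the margin subject to `0 <= lambda_i <= C` and
#' `sum(lambda_i y_i) = 0`). Features are z-scored with statistics learned
#' from the training data only (the wavelet entropy and LF/HF features differ
#' by four orders of magnitude, which would make an unscaled RBF kernel
#' degenerate). Dual feasibility is verified after every fit.
#'
#' @param x Numeric matrix or data frame of feature vectors (rows = samples).
#' @param y Labels: `"drowsy"`/`"alert"` or `+1`/`-1`; both classes required.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C Soft-margin cost.
#' @param gamma RBF width parameter (ignored for the linear kernel).
#' @param standardize Z-score features using training statistics (default
#'   `TRUE`).
#' @return An object of class `svm_model`: list with the fitted backend
#'   model, `lambda` (dual multipliers), `coefs` (`y_i * lambda_i`), `rho`,
#'   support vectors, standardization parameters and the kernel spec.
#' @export
svm_train <- function(x, y, kernel = c("linear", "rbf"), C = 1, gamma = 1,
                      standardize = TRUE) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  yv <- .label_pm1(y)
  if (length(unique(yv)) < 2) stop("single-class input: both labels required")
  stopifnot(nrow(x) == length(yv), all(is.finite(x)), C > 0, gamma > 0)
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- e1071::svm(xs, factor(yv, levels = c(-1, 1)),
                    type = "C-classification",
                    kernel = if (kernel == "rbf") "radial" else "linear",
                    cost = C, gamma = gamma, scale = FALSE,
                    tolerance = 1e-6)
  # libsvm decision convention: positive side = first label seen internally
  pos_level <- as.numeric(as.character(levels(fit$fitted)[fit$labels[1]]))
  model <- structure(list(fit = fit, kernel = kernel, C = C, gamma = gamma,
                          center = center, scale = scale,
                          sv = fit$SV, coefs = as.numeric(fit$coefs),
                          lambda = abs(as.numeric(fit$coefs)),
                          rho = fit$rho, pos_level = pos_level),
                     class = "svm_model")
  kkt <- check_kkt(model)
  if (!kkt$ok)
    warning(sprintf("KKT conditions violated beyond tolerance (box %.2g, balance %.2g)",
                    kkt$box_violation, kkt$balance))
  model
}

#' Verify dual feasibility of a trained SVM
#'
#' Checks the box constraint `0 <= lambda_i <= C` and the balance constraint
#' `sum(lambda_i y_i) = 0` of the dual solution.
#'
#' @param model An [svm_train()] result.
#' @param tol Tolerance.
#' @return List with `ok`, `box_violation`, `balance`.
#' @export
check_kkt <- function(model, tol = 1e-6) {
  box <- max(c(0, -model$lambda, model$lambda - model$C))
  bal <- abs(sum(model$coefs))
  list(ok = box <= tol && bal <= tol, box_violation = box, balance = bal)
}

.kernel_matrix <- function(model, a, b) {
  if (model$kernel == "linear") return(a %*% t(b))
  # RBF: exp(-gamma * ||u - v||^2)
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  exp(-model$gamma * pmax(d2, 0))
}

#' Decision values of a trained SVM
#'
#' The signed distance surrogate `f(x) = sum_j coef_j K(sv_j, x) - rho`,
#' oriented so positive values mean drowsy.
#'
#' @param model An [svm_train()] result.
#' @param x New feature vectors (rows).
#' @return Numeric decision values.
#' @export
svm_decision <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop("feature dimension mismatch: model expects ", length(model$center))
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  dec <- as.numeric(.kernel_matrix(model, xs, model$sv) %*% model$coefs - model$rho)
  if (model$pos_level < 0) dec <- -dec
  dec
}

# exact zeros map to drowsy: when the machine cannot decide, fail safe
.decision_to_label <- function(dec) {
  if (any(dec == 0))
    warning("decision value exactly 0; assigning drowsy (+1) as the fail-safe class")
  ifelse(dec >= 0, 1, -1)
}

#' Predict drowsy/alert labels
#'
#' Sign of the decision function; an exact zero is mapped to `+1` (drowsy)
#' with a warning -- the fail-safe direction for a safety application.
#'
#' @inheritParams svm_decision
#' @return Vector of `+1` (drowsy) / `-1` (alert).
#' @export
svm_predict <- function(model, x) {
  .decision_to_label(svm_decision(model, x))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`, with drowsy as the positive class. A
#' zero-denominator sensitivity or specificity is returned as `NA`
#' (undefined), never as 0 or 1.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts; total must be positive.
#' @return An object of class `eval_metrics`: list of the counts plus
#'   `accuracy`, `sensitivity`, `specificity` as fractions in \[0, 1\].
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all confusion counts are zero")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / sum(counts),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> Ac %.1f%%  Se %.1f%%  Sp %.1f%% (tp %d tn %d fp %d fn %d)\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Leave-one-out validation over a hyperparameter grid
#'
#' For every grid cell and every sample: drop the sample, learn the
#' standardization and the SVM on the remaining data only (no leakage), and
#' predict the held-out sample; accumulate the confusion counts into Ac/Se/Sp
#' per cell. The best cell is selected by accuracy, with ties broken toward
#' the linear kernel, then smaller C, then smaller gamma.
#'
#' @param x Feature matrix (rows = samples); for the standard protocol a
#'   20-sample, 2-feature per-subject set.
#' @param y Labels; at least 2 samples per class.
#' @param grid Hyperparameter grid, see [default_svm_grid()].
#' @param standardize See [svm_train()].
#' @return List with `results` (per-cell data frame: kernel, C, gamma,
#'   confusion counts, accuracy, sensitivity, specificity) and `best` (the
#'   selected row).
#' @export
loo_validate <- function(x, y, grid = default_svm_grid(), standardize = TRUE) {
  x <- as.matrix(x)
  yv <- .label_pm1(y)
  if (min(table(yv)) < 2) stop("need at least 2 samples per class for LOO")
  n <- nrow(x)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    kern <- as.character(grid$kernel[g])
    Cc <- grid$C[g]
    gam <- if (is.na(grid$gamma[g])) 1 else grid$gamma[g]
    pred <- numeric(n)
    for (i in seq_len(n)) {
      m <- svm_train(x[-i, , drop = FALSE], yv[-i], kernel = kern, C = Cc,
                     gamma = gam, standardize = standardize)
      pred[i] <- svm_predict(m, x[i, , drop = FALSE])
    }
    tp <- sum(pred == 1 & yv == 1); tn <- sum(pred == -1 & yv == -1)
    fp <- sum(pred == 1 & yv == -1); fn <- sum(pred == -1 & yv == 1)
    met <- classification_metrics(tp, tn, fp, fn)
    rows[[g]] <- data.frame(kernel = kern, C = Cc, gamma = grid$gamma[g],
                            tp = tp, tn = tn, fp = fp, fn = fn,
                            accuracy = met$accuracy,
                            sensitivity = met$sensitivity,
                            specificity = met$specificity,
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  ord <- order(-results$accuracy,
               results$kernel != "linear",   # linear preferred on ties
               results$C,
               ifelse(is.na(results$gamma), 0, results$gamma))
  list(results = results, best = results[ord[1], , drop = FALSE])
}
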