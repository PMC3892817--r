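# Feature selection: ROC area (Mann-Whitney formulation) per feature, plus
# independent two-sample t-tests, drowsy always the positive class.

.check_labels <- function(labels) {
  lab <- as.character(labels)
  lab[lab %in% c("1", "+1", "TRUE")] <- "drowsy"
  lab[lab %in% c("-1", "FALSE")] <- "alert"
  if (!all(lab %in% c("alert", "drowsy")))
    stop("labels must be 'alert'/'drowsy' (or -1/+1)")
  lab
}

#' ROC area of one feature for drowsy-vs-alert separation
#'
#' The area under the empirical ROC curve with drowsy as the positive class,
#' computed by the rank-sum (Mann-Whitney) identity: the fraction of
#' (drowsy, alert) value pairs won by the drowsy member, ties credited one
#' half. 1.0 means every drowsy value exceeds every alert value; 0.5 means
#' the groups overlap completely; both high (>= 0.7) and low (<= 0.3) areas
#' mark a feature as acceptable for classification, since an inverted
#' separation is equally usable.
#'
#' @param values Numeric feature values.
#' @param labels Class labels: `"drowsy"`/`"alert"` or `+1`/`-1`.
#' @return An object of class `roc_result`: list with `feature_name`,
#'   `roc_area`, `direction` (`"drowsy_higher"` or `"drowsy_lower"`), and
#'   `acceptable`.
#' @export
roc_area <- function(values, labels) {
  lab <- .check_labels(labels)
  stopifnot(length(values) == length(lab))
  pos <- values[lab == "drowsy"]
  neg <- values[lab == "alert"]
  if (!length(pos) || !length(neg))
    stop("both classes must be non-empty")
  r <- rank(c(pos, neg), ties.method = "average")
  npos <- length(pos); nneg <- length(neg)
  auc <- (sum(r[seq_len(npos)]) - npos * (npos + 1) / 2) / (npos * nneg)
  nm <- deparse(substitute(values))
  structure(list(feature_name = nm, roc_area = auc,
                 direction = if (mean(pos) >= mean(neg)) "drowsy_higher" else "drowsy_lower",
                 acceptable = auc >= 0.7 || auc <= 0.3),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> area %.3f (%s)%s\n", x$roc_area, x$direction,
              if (x$acceptable) " [acceptable]" else ""))
  invisible(x)
}

#' Rank features by how far their ROC area is from chance
#'
#' Computes the ROC area of every feature column and sorts by
#' `|area - 0.5|`, descending (both strongly high and strongly low areas are
#' informative), breaking ties by feature name. This is the selection rule
#' used to pick the best wavelet feature to pair with the LF/HF ratio.
#'
#' @param features Data frame or matrix of feature columns (>= 1).
#' @param labels Class labels, one per row.
#' @return Data frame with columns `feature`, `roc_area`, `direction`,
#'   `acceptable`, ordered by discriminative strength.
#' @export
rank_features <- function(features, labels) {
  features <- as.data.frame(features)
  stopifnot(ncol(features) >= 1, nrow(features) == length(labels))
  rows <- lapply(names(features), function(nm) {
    r <- roc_area(features[[nm]], labels)
    data.frame(feature = nm, roc_area = r$roc_area, direction = r$direction,
               acceptable = r$acceptable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$roc_area - 0.5), out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Independent two-sample t-test between drowsy and alert groups
#'
#' Pooled-variance (Student) test by default -- the primary row of the usual
#' statistical-software output -- with the Welch variant available. Two-tailed
#' throughout; significance flagged at alpha = 0.05. No multiple-testing
#' correction is applied by default, matching the per-feature selection
#' protocol; set `adjust = "BH"` in [feature_ttests()] for
#' Benjamini-Hochberg.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @param var_equal Pooled variance (`TRUE`, default) or Welch (`FALSE`).
#' @param feature_name Optional identifier carried into the result.
#' @return An object of class `ttest_result`: list with `feature_name`,
#'   `t_statistic`, `p_two_tailed`, `significant`, `method`.
#' @export
ttest_independent <- function(group_a, group_b, var_equal = TRUE,
                              feature_name = NA_character_) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (var_equal && var(group_a) + var(group_b) == 0)
    stop("zero pooled variance: t statistic undefined")
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  structure(list(feature_name = feature_name,
                 t_statistic = unname(tt$statistic),
                 p_two_tailed = tt$p.value,
                 significant = tt$p.value < 0.05,
                 method = if (var_equal) "pooled" else "welch"),
            class = "ttest_result")
}

#' Per-feature t-tests over a labelled feature table
#'
#' @param features Data frame or matrix of feature columns.
#' @param labels Class labels, one per row.
#' @param var_equal See [ttest_independent()].
#' @param adjust P-value adjustment method passed to [stats::p.adjust()];
#'   `"none"` (default) or e.g. `"BH"`.
#' @return Data frame `feature`, `t`, `p`, `p_adjusted`, `significant`.
#' @export
feature_ttests <- function(features, labels, var_equal = TRUE, adjust = "none") {
  features <- as.data.frame(features)
  lab <- .check_labels(labels)
  rows <- lapply(names(features), function(nm) {
    r <- ttest_independent(features[[nm]][lab == "drowsy"],
                           features[[nm]][lab == "alert"],
                           var_equal = var_equal, feature_name = nm)
    data.frame(feature = nm, t = r$t_statistic, p = r$p_two_tailed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p_adjusted < 0.05
  out
}

#' Combined ROC + t-test ranking table
#'
#' The selection report: one row per feature with ROC area, direction,
#' acceptability, and t-test results, ordered by ROC strength.
#'
#' @inheritParams feature_ttests
#' @return Data frame `feature`, `roc_area`, `direction`, `acceptable`, `t`,
#'   `p`.
#' @export
selection_report <- function(features, labels, var_equal = TRUE) {
  rk <- rank_features(features, labels)
  tt <- feature_ttests(features, labels, var_equal = var_equal)
  merge_order <- match(rk$feature, tt$feature)
  rk$t <- tt$t[merge_order]
  rk$p <- tt$p[merge_order]
  rk
}
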