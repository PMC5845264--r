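# ROC analysis of pocket-pair scores over a labelled benchmark.  The AUC
# is computed by the rank-sum (Mann-Whitney) identity with ties credited
# 0.5, which equals the trapezoidal integral of the stored curve points;
# the test suite asserts that equality as a dual-computation check.

#' Labelled pocket-pair table
#'
#' Validates and normalises a benchmark table: one row per pocket pair
#' with a `label` column (`positive`/`negative`) and one numeric column
#' per scoring method.
#'
#' @param df data frame with columns `pair_id`, `label`, and method columns.
#' @return the validated data frame, invisibly classed `labeled_pairs`.
#' @export
labeled_pairs <- function(df) {
  if (!all(c("pair_id", "label") %in% names(df))) {
    .stopf("need columns pair_id and label")
  }
  if (!all(df$label %in% c("positive", "negative"))) {
    .stopf("label must be 'positive' or 'negative'")
  }
  class(df) <- c("labeled_pairs", class(df))
  df
}

#' ROC curve and AUC for one scoring method
#'
#' Sweeps all distinct score values as thresholds to build the ROC curve
#' (FPR, TPR), and computes the AUC through the Mann-Whitney identity with
#' ties counted as half a win.  Pairs with a missing score are excluded
#' and counted on the result.
#'
#' @param pairs a `labeled_pairs` data frame.
#' @param method name of the score column to evaluate.
#' @param higher_is_similar if `FALSE` the score is negated first (for
#'   distance-like scores).
#' @return object of class `roc_curve`: `thresholds`, `fpr`, `tpr`,
#'   `auc`, `n_pos`, `n_neg`, `n_excluded`, `method`.
#' @export
roc_auc <- function(pairs, method, higher_is_similar = TRUE) {
  if (!method %in% names(pairs)) .stopf("no score column '%s'", method)
  s <- pairs[[method]]
  keep <- !is.na(s)
  n_excluded <- sum(!keep)
  s <- s[keep]
  lab <- pairs$label[keep] == "positive"
  if (!higher_is_similar) s <- -s
  P <- sum(lab)
  N <- sum(!lab)
  if (P == 0 || N == 0) .stopf("need both classes; got %d positive, %d negative", P, N)

  # curve: thresholds descending, cumulative TP/FP
  ord <- order(-s)
  ss <- s[ord]
  ll <- lab[ord]
  # last index of each distinct threshold value
  last <- cumsum(rle(ss)$lengths)
  tp <- cumsum(ll)[last]
  fp <- cumsum(!ll)[last]
  thresholds <- ss[last]
  fpr <- c(0, fp / N)
  tpr <- c(0, tp / P)

  # Mann-Whitney AUC with midranks (ties get 0.5 credit)
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[lab]) - P * (P + 1) / 2) / (as.numeric(P) * N)

  structure(list(thresholds = c(Inf, thresholds), fpr = fpr, tpr = tpr,
                 auc = auc, n_pos = P, n_neg = N, n_excluded = n_excluded,
                 method = method),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve [%s]: AUC %.4f (%d positive, %d negative, %d excluded)\n",
              x$method, x$auc, x$n_pos, x$n_neg, x$n_excluded))
  invisible(x)
}

#' Trapezoidal integral of a stored ROC curve
#'
#' Independent of the Mann-Whitney computation in [roc_auc()]; the two
#' agree to numerical precision (a property the tests assert).
#'
#' @param curve a `roc_curve`.
#' @return area under the stored (FPR, TPR) points.
#' @export
roc_trapezoid_auc <- function(curve) {
  x <- curve$fpr
  y <- curve$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Sensitivity at a fixed false-positive rate
#'
#' Returns the TPR at the largest achieved FPR not exceeding `fpr_level`
#' (step-function convention).
#'
#' @param curve a `roc_curve`.
#' @param fpr_level target FPR in (0, 1).
#' @return TPR at that operating point.
#' @export
sensitivity_at_fpr <- function(curve, fpr_level) {
  if (fpr_level <= 0 || fpr_level >= 1) .stopf("fpr_level must be in (0, 1)")
  ok <- which(curve$fpr <= fpr_level)
  max(curve$tpr[ok][curve$fpr[ok] == max(curve$fpr[ok])])
}

#' Compare scoring methods on one labelled benchmark
#'
#' Runs [roc_auc()] for each method column and tabulates AUC, sensitivity
#' at 1% and 5% FPR, class sizes and exclusions.  A method that errors
#' (e.g. absent scores) yields an `NA` row; the rest of the report is
#' still produced.
#'
#' @param pairs a `labeled_pairs` data frame.
#' @param methods character vector of score column names.
#' @param higher_is_similar logical, recycled over methods.
#' @return list with `report` (data frame) and `curves` (named list of
#'   `roc_curve` objects).
#' @export
evaluate_methods <- function(pairs, methods, higher_is_similar = TRUE) {
  higher_is_similar <- rep_len(higher_is_similar, length(methods))
  rows <- list()
  curves <- list()
  for (i in seq_along(methods)) {
    m <- methods[i]
    res <- tryCatch(roc_auc(pairs, m, higher_is_similar[i]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[m]] <- data.frame(method = m, auc = NA_real_,
                              tpr_at_fpr01 = NA_real_, tpr_at_fpr05 = NA_real_,
                              n_pos = NA_integer_, n_neg = NA_integer_,
                              n_excluded = NA_integer_,
                              note = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      curves[[m]] <- res
      rows[[m]] <- data.frame(method = m, auc = res$auc,
                              tpr_at_fpr01 = sensitivity_at_fpr(res, 0.01),
                              tpr_at_fpr05 = sensitivity_at_fpr(res, 0.05),
                              n_pos = res$n_pos, n_neg = res$n_neg,
                              n_excluded = res$n_excluded, note = "",
                              stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(method = character(0), auc = numeric(0),
               tpr_at_fpr01 = numeric(0), tpr_at_fpr05 = numeric(0),
               n_pos = integer(0), n_neg = integer(0),
               n_excluded = integer(0), note = character(0))
  rownames(report) <- NULL
  list(report = report, curves = curves)
}

#' Write a method-comparison report to disk
#'
#' Emits the summary table and one (FPR, TPR) point file per method.
#'
#' @param evaluation result of [evaluate_methods()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(evaluation, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(evaluation$report, file.path(dir, "methods.tsv"))
  for (m in names(evaluation$curves)) {
    cv <- evaluation$curves[[m]]
    write_tsv(data.frame(threshold = cv$thresholds, fpr = cv$fpr, tpr = cv$tpr),
              file.path(dir, sprintf("roc_%s.tsv", m)))
  }
  invisible(dir)
}
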