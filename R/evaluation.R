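#' @title Evaluation: confusion metrics, ROC/C-statistic, and printed-value
#'   reconstruction
#'
#' @description
#' Confusion-matrix metrics at a fixed threshold (accuracy, sensitivity,
#' specificity, PPV, NPV, F1), ROC curves with the area computed twice (by
#' trapezoid and by pairwise concordance, asserted equal), and an exhaustive
#' integer-search utility that recovers the confusion matrices behind
#' published metric tables. Undefined metrics (zero denominators) are
#' reported as `NA`, never 0. The C-statistic is the ROC AUC.
#'
#' @name evaluation
NULL

#' Confusion matrix from binary vectors
#'
#' @param labels 0/1 gold labels
#' @param predictions 0/1 predicted labels
#' @return a `confusion_matrix`: list with counts `tp`, `fn`, `fp`, `tn`
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  stopifnot(length(labels) >= 1L, all(labels %in% 0:1),
            all(predictions %in% 0:1))
  confusion_matrix(tp = sum(labels == 1 & predictions == 1),
                   fn = sum(labels == 1 & predictions == 0),
                   fp = sum(labels == 0 & predictions == 1),
                   tn = sum(labels == 0 & predictions == 0))
}

#' @rdname confusion
#' @param tp,fn,fp,tn non-negative counts
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn >= 1)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn)),
            class = "confusion_matrix")
}

safe_ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)

#' The six classification metrics of a confusion matrix
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), ppv = tp/(tp+fp),
#' npv = tn/(tn+fn), accuracy = (tp+tn)/n, f1 = 2tp/(2tp+fp+fn). Any metric
#' with a zero denominator is `NA`.
#'
#' @param cm a `confusion_matrix`
#' @return named numeric vector: accuracy, sensitivity, specificity, ppv,
#'   npv, f1
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  with(cm, c(
    accuracy = (tp + tn) / (tp + fn + fp + tn),
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    ppv = safe_ratio(tp, tp + fp),
    npv = safe_ratio(tn, tn + fn),
    f1 = safe_ratio(2 * tp, 2 * tp + fp + fn)))
}

round_half_up <- function(x, digits) floor(x * 10^digits + 0.5) / 10^digits

#' ROC curve with doubly computed AUC
#'
#' Thresholds sweep the distinct scores from high to low (classify positive
#' at score >= threshold). The area is computed by the trapezoidal rule over
#' the curve and, independently, as the pairwise concordance probability
#' (ties counted 1/2) via the rank-sum identity; the two must agree to
#' 1e-12 or the function aborts.
#'
#' @param labels 0/1 vector containing both classes
#' @param scores numeric scores (higher = more positive)
#' @return a `roc_curve`: list with `points` (data.frame threshold, fpr,
#'   tpr, beginning at (0,0) and ending at (1,1)) and `auc`
#' @export
roc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg, 0)
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc_trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                     utils::tail(pts$tpr, -1)) / 2)
  r <- rank(scores)  # midranks handle ties as 1/2 concordance
  auc_conc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  if (abs(auc_trap - auc_conc) > 1e-12) {
    stop(sprintf("AUC mismatch: trapezoid %.15f vs concordance %.15f",
                 auc_trap, auc_conc), call. = FALSE)
  }
  structure(list(points = pts, auc = auc_trap), class = "roc_curve")
}

#' Recover integer confusion matrices behind printed metrics
#'
#' Exhaustively enumerates `tp` in `[0, n_pos]` and `fp` in `[0, n - n_pos]`
#' and returns every matrix whose metrics print as `reported` at the given
#' precision. A value "prints as" the target when it matches after
#' round-half-up to `decimals` places, or after truncation to `decimals`
#' places — the latter accommodates published tables where an exact decimal
#' tie (e.g. 0.964375) was stored as an IEEE double slightly below the tie
#' and therefore printed rounded down.
#'
#' @param n total count
#' @param n_pos positive count (`<= n`)
#' @param reported named vector with any of `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `f1`; `NA` entries are unconstrained
#' @param decimals printed precision (default 4)
#' @return list of `confusion_matrix` (possibly empty)
#' @export
reconstruct_cm <- function(n, n_pos, reported, decimals = 4L) {
  stopifnot(n_pos <= n, n >= 1)
  n_neg <- n - n_pos
  grid <- expand.grid(tp = 0:n_pos, fp = 0:n_neg)
  tp <- grid$tp; fp <- grid$fp
  fn <- n_pos - tp; tn <- n_neg - fp
  vals <- list(
    accuracy = (tp + tn) / n,
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    ppv = safe_ratio(tp, tp + fp),
    npv = safe_ratio(tn, tn + fn),
    f1 = safe_ratio(2 * tp, 2 * tp + fp + fn))
  keep <- rep(TRUE, nrow(grid))
  for (nm in names(vals)) {
    target <- suppressWarnings(as.numeric(reported[nm]))
    if (is.na(target)) next
    v <- vals[[nm]]
    ok <- !is.na(v) &
      (round_half_up(v, decimals) == target |
         floor(v * 10^decimals) / 10^decimals == target)
    keep <- keep & ok
  }
  lapply(which(keep), function(i) {
    confusion_matrix(tp[i], fn[i], fp[i], tn[i])
  })
}

#' End-to-end evaluation of a trained model on a labeled corpus
#'
#' Extract features, predict, form the confusion matrix at the model's
#' threshold, compute the six metrics and the ROC/C-statistic.
#'
#' @param model a `hemobleed_model`
#' @param visits labeled `patient_visit` list
#' @param catalog a `feature_catalog`
#' @param features optional precomputed feature matrix for `visits`
#' @return an `evaluation_report`: list with `confusion`, `metrics`,
#'   `roc`, `predictions`, `n`, `n_pos`
#' @export
evaluate_model <- function(model, visits, catalog = load_catalog(),
                           features = NULL) {
  labels <- corpus_labels(visits)
  if (anyNA(labels)) stop("evaluation requires labeled visits", call. = FALSE)
  if (is.null(features)) {
    features <- extract_feature_matrix(visits, catalog)
  }
  preds <- predict(model, features)
  cm <- confusion(labels, preds$label)
  structure(list(confusion = cm,
                 metrics = metrics(cm),
                 roc = roc(labels, preds$probability),
                 predictions = preds,
                 n = length(labels),
                 n_pos = sum(labels)),
            class = "evaluation_report")
}

#' Serialize an evaluation report to JSON (plus optional ROC CSV)
#'
#' @param report an `evaluation_report`
#' @param path JSON destination
#' @param roc_path optional CSV destination (columns threshold, fpr, tpr)
#' @return `path`, invisibly
#' @export
write_report <- function(report, path, roc_path = NULL) {
  payload <- list(confusion = unclass(report$confusion),
                  metrics = as.list(report$metrics),
                  auc = report$roc$auc,
                  n = report$n, n_pos = report$n_pos)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(roc_path)) {
    utils::write.csv(report$roc$points, roc_path, row.names = FALSE)
  }
  invisible(path)
}
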