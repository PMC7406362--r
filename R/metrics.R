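#' Classification accuracy
#'
#' Proportion of correct class calls, i.e. one minus the misclassification
#' error, thresholding predicted probabilities at `threshold`.
#'
#' @param preds Predicted probabilities.
#' @param labels True labels in \{0, 1\}.
#' @param threshold Probability cut for calling class 1 (default 0.5).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(preds, labels, threshold = 0.5) {
  stopifnot(length(preds) == length(labels))
  mean((preds > threshold) == (labels == 1))
}

#' Positive and negative predictive value
#'
#' `PPV = TP / (TP + FP)` and `NPV = TN / (TN + FN)` at a probability
#' threshold. A zero denominator (e.g. a classifier that predicts no
#' positives) leaves the corresponding value missing, with a warning — an
#' all-negative predictor has an undefined PPV, not a perfect or zero one.
#'
#' @inheritParams accuracy
#' @return One-row tibble `ppv, npv, tp, fp, tn, fn`.
#' @export
ppv_npv <- function(preds, labels, threshold = 0.5) {
  pos <- preds > threshold
  y <- labels == 1
  tp <- sum(pos & y); fp <- sum(pos & !y)
  tn <- sum(!pos & !y); fn <- sum(!pos & y)
  ppv <- if (tp + fp > 0L) tp / (tp + fp) else {
    warning("no predicted positives; PPV undefined", call. = FALSE)
    NA_real_
  }
  npv <- if (tn + fn > 0L) tn / (tn + fn) else {
    warning("no predicted negatives; NPV undefined", call. = FALSE)
    NA_real_
  }
  tibble::tibble(ppv = ppv, npv = npv, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the ROC curve
#'
#' Rank-based (tie-corrected) AUC: the probability that a randomly chosen
#' positive observation is scored higher than a randomly chosen negative
#' one, with ties counting one half.
#'
#' @param scores Numeric scores or probabilities.
#' @param labels True labels in \{0, 1\}; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- labels == 1
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Contiguous-in-time cross-validation folds
#'
#' Splits events into `k` folds that are contiguous blocks of stream time,
#' the form of cross-validation appropriate for time-dependent observations:
#' training and test events never interleave in time. With
#' `require_positive`, fold boundaries are placed between consecutive
#' positive-class events so that every fold contains at least one positive
#' event (an error when there are fewer positives than folds).
#'
#' @param events Tibble with `event_id`, `start_time` and, when
#'   `require_positive` is used, a `label` column (1 = positive).
#' @param k Number of folds.
#' @param require_positive Guarantee at least one positive event per fold.
#' @return A list of class `fold_plan`: `assignment` (tibble `event_id,
#'   fold`), `boundaries` (fold start times) and `k`.
#' @export
blocked_folds <- function(events, k, require_positive = FALSE) {
  stopifnot(k >= 1L, nrow(events) >= k)
  ev <- dplyr::arrange(events, .data$start_time)
  if (k == 1L) {
    plan <- tibble::tibble(event_id = ev$event_id, fold = 1L)
    return(structure(list(assignment = plan, boundaries = min(ev$start_time),
                          k = 1L), class = "fold_plan"))
  }
  if (require_positive) {
    pos <- ev[ev$label == 1L & !is.na(ev$label), , drop = FALSE]
    if (nrow(pos) < k)
      stop("fewer positive events (", nrow(pos), ") than folds (", k, ")",
           call. = FALSE)
    # one boundary between the positive events allotted to adjacent folds
    cuts <- floor(seq(1L, nrow(pos) + 1L, length.out = k + 1L))[2:k]
    boundaries <- vapply(cuts, function(ci) {
      ceiling((pos$start_time[ci - 1L] + pos$start_time[ci]) / 2)
    }, numeric(1))
  } else {
    qs <- stats::quantile(ev$start_time, probs = seq_len(k - 1L) / k,
                          names = FALSE, type = 1)
    boundaries <- unique(qs + 1)
  }
  fold <- findInterval(ev$start_time, c(-Inf, boundaries))
  plan <- tibble::tibble(event_id = ev$event_id, fold = as.integer(fold))
  structure(list(assignment = plan,
                 boundaries = c(min(ev$start_time), boundaries), k = k),
            class = "fold_plan")
}

#' Per-age metric report
#'
#' Computes accuracy, PPV, NPV and AUC per age stratum of a prediction
#' table, together with the contingency counts from which the threshold
#' metrics derive.
#'
#' @param preds Tibble with `age`, `label` and `prob` columns.
#' @param threshold Probability threshold for class calls.
#' @return Tibble with one row per age.
#' @export
metric_report <- function(preds, threshold = 0.5) {
  preds |>
    dplyr::group_by(.data$age) |>
    dplyr::group_modify(function(d, key) {
      cont <- suppressWarnings(ppv_npv(d$prob, d$label, threshold))
      tibble::tibble(n = nrow(d),
                     accuracy = accuracy(d$prob, d$label, threshold),
                     ppv = cont$ppv, npv = cont$npv,
                     auc = auc(d$prob, d$label),
                     tp = cont$tp, fp = cont$fp, tn = cont$tn,
                     fn = cont$fn, threshold = threshold)
    }) |>
    dplyr::ungroup()
}
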