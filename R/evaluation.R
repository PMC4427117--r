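confusion_counts <- function(tp, fp, fn, tn, level) {
  out <- tibble(tp = as.integer(tp), fp = as.integer(fp),
                fn = as.integer(fn), tn = as.integer(tn), level = level)
  if (any(unlist(out[1, 1:4]) < 0)) wx_abort("confusion counts must be >= 0")
  class(out) <- c("wx_confusion", class(tibble()))
  out
}

# Reduced IRanges of one sequence's intervals (1-based closed).
intervals_ir <- function(x) {
  IRanges::reduce(IRanges::IRanges(start = x$start + 1L, end = x$end))
}

check_one_sequence <- function(predicted, truth, what) {
  ids <- unique(c(predicted$sequence_id, truth$sequence_id))
  if (length(ids) > 1L) {
    wx_abort(sprintf("%s: predictions and truth name different sequences (%s)",
                     what, paste(ids, collapse = ", ")))
  }
  invisible(ids)
}

#' Segment-level confusion counts
#'
#' Whole exons and whole noncoding units are the counting units. A truth exon
#' is a true positive when predictions cover at least `overlap_rule` of its
#' length; otherwise it is a false negative. A prediction overlapping no
#' truth exon is a false positive. True negatives are the noncoding units not
#' falsely called: `tn = noncoding_units - fp` (floored at 0). By default the
#' noncoding units are the gaps between and flanking the truth exons
#' (`n_exons + 1`).
#'
#' @param predicted,truth `wx_intervals` tibbles on the same sequence.
#' @param noncoding_units Number of noncoding segment units; default
#'   `nrow(truth) + 1`.
#' @param overlap_rule Fraction of a truth exon that must be covered to count
#'   it detected (default 0.5).
#' @return A one-row `wx_confusion` tibble (`tp`, `fp`, `fn`, `tn`,
#'   `level = "segment"`).
#' @export
segment_confusion <- function(predicted, truth, noncoding_units = NULL,
                              overlap_rule = 0.5) {
  check_one_sequence(predicted, truth, "segment_confusion")
  if (is.null(noncoding_units)) noncoding_units <- nrow(truth) + 1L
  noncoding_units <- as.integer(noncoding_units)
  if (noncoding_units < 0L) wx_abort("noncoding_units must be >= 0")
  ir_p <- intervals_ir(predicted)
  ir_t <- intervals_ir(truth)
  covered <- vapply(seq_along(ir_t), function(i) {
    sum(IRanges::width(IRanges::intersect(ir_p, ir_t[i])))
  }, 1L)
  tp <- sum(covered >= overlap_rule * IRanges::width(ir_t))
  fn <- length(ir_t) - tp
  fp <- sum(IRanges::countOverlaps(ir_p, ir_t) == 0L)
  tn <- max(0L, noncoding_units - fp)
  confusion_counts(tp, fp, fn, tn, "segment")
}

#' Nucleotide-level confusion counts
#'
#' Position-by-position classification over `[0, seq_length)`; the four
#' counts sum to `seq_length`.
#'
#' @param predicted,truth `wx_intervals` tibbles on the same sequence.
#' @param seq_length Sequence length (nt).
#' @return A one-row `wx_confusion` tibble (`level = "nucleotide"`).
#' @export
nucleotide_confusion <- function(predicted, truth, seq_length) {
  check_one_sequence(predicted, truth, "nucleotide_confusion")
  seq_length <- as.integer(seq_length)
  if (any(c(predicted$end, truth$end) > seq_length) ||
      any(c(predicted$start, truth$start) < 0L)) {
    wx_abort("interval out of bounds [0, seq_length)")
  }
  mask <- function(x) {
    m <- logical(seq_length)
    for (i in seq_len(nrow(x))) m[(x$start[i] + 1L):x$end[i]] <- TRUE
    m
  }
  p <- if (nrow(predicted)) mask(predicted) else logical(seq_length)
  t <- if (nrow(truth)) mask(truth) else logical(seq_length)
  confusion_counts(sum(p & t), sum(p & !t), sum(!p & t), sum(!p & !t),
                   "nucleotide")
}

#' Classification metrics from confusion counts
#'
#' The eight standard ratios: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' accuracy (TP+TN)/total, positive precision TP/(TP+FP), negative precision
#' TN/(TN+FN), error rate (FP+FN)/total, false discovery rate FP/(TP+FP) and
#' false omission rate FN/(TN+FN). A ratio with a zero denominator is
#' reported as `NA` (undefined), never as 0 or 1.
#'
#' @param counts A `wx_confusion` tibble (one row).
#' @return A one-row `wx_metrics` tibble carrying the counts and the eight
#'   metrics; has a [tidy()] method.
#' @export
#' @examples
#' compute_metrics(segment_confusion(
#'   genomic_intervals("g", 0, 100),
#'   genomic_intervals("g", 0, 100, label = "exon")
#' ))
compute_metrics <- function(counts) {
  if (!inherits(counts, "wx_confusion") || nrow(counts) != 1L) {
    wx_abort("compute_metrics expects a one-row confusion-count tibble")
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total == 0L) wx_abort("degenerate input: all confusion counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble(
    level = counts$level, tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy = (tp + tn) / total,
    positive_precision = ratio(tp, tp + fp),
    negative_precision = ratio(tn, tn + fn),
    error_rate = (fp + fn) / total,
    false_discovery_rate = ratio(fp, tp + fp),
    false_omission_rate = ratio(fn, tn + fn)
  )
  class(out) <- c("wx_metrics", class(tibble()))
  out
}

#' @exportS3Method generics::tidy
tidy.wx_metrics <- function(x, ...) {
  metric_cols <- c("sensitivity", "specificity", "accuracy",
                   "positive_precision", "negative_precision", "error_rate",
                   "false_discovery_rate", "false_omission_rate")
  tibble(metric = metric_cols,
         value = as.numeric(x[1, metric_cols]))
}

#' ROC curve of a profile against truth annotations
#'
#' Sweeps the thresholds, computes one (FPR, TPR) point per threshold at the
#' chosen granularity (nucleotide level thresholds the profile directly;
#' segment level runs [call_regions()] with `min_region_length = 1`,
#' `merge_gap = 0`), anchors the curve at (0,0) and (1,1) and integrates by
#' the trapezoid rule. With thresholds at every distinct profile value, the
#' nucleotide-level AUC equals the Mann-Whitney statistic.
#'
#' @param profile A `wx_signal` tibble at stage `"normalized"`, one sequence.
#' @param truth `wx_intervals` tibble of true exons on that sequence.
#' @param thresholds At least two thresholds (default 0.05 ... 0.95 by 0.05).
#' @param level `"nucleotide"` (default) or `"segment"`.
#' @return A `wx_roc` object: `$points` tibble (threshold, fpr, tpr), `$auc`,
#'   `$level`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
roc_curve <- function(profile, truth,
                      thresholds = seq(0.05, 0.95, by = 0.05),
                      level = c("nucleotide", "segment")) {
  level <- match.arg(level)
  assert_stage(profile, "normalized", "roc_curve")
  if (length(thresholds) < 2L) wx_abort("need at least two thresholds",
                                        "wx_config_error")
  p <- profile[order(profile$pos), ]
  check_one_sequence(p[, "sequence_id", drop = FALSE], truth, "roc_curve")
  n <- nrow(p)
  pts <- purrr::map(sort(thresholds), function(t) {
    cc <- if (level == "nucleotide") {
      pred_pos <- p$pos[p$value >= t]
      pred <- if (length(pred_pos)) {
        ir <- IRanges::reduce(IRanges::IRanges(pred_pos, width = 1L))
        genomic_intervals(rep(p$sequence_id[1], length(ir)),
                          IRanges::start(ir) - 1L, IRanges::end(ir))
      } else genomic_intervals()
      nucleotide_confusion(pred, truth, n)
    } else {
      pred <- call_regions(p, caller_spec(t, min_region_length = 1L,
                                          merge_gap = 0L))
      segment_confusion(pred, truth)
    }
    if (cc$tp + cc$fn == 0L || cc$fp + cc$tn == 0L) {
      wx_abort("degenerate truth: need both positives and negatives")
    }
    tibble(threshold = t,
           fpr = cc$fp / (cc$fp + cc$tn),
           tpr = cc$tp / (cc$tp + cc$fn))
  }) |>
    dplyr::bind_rows()
  curve <- unique(rbind(tibble(threshold = NA_real_, fpr = c(0, 1),
                               tpr = c(0, 1)),
                        pts)[, c("fpr", "tpr")])
  curve <- curve[order(curve$fpr, curve$tpr), ]
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, level = level), class = "wx_roc")
}

#' @export
print.wx_roc <- function(x, ...) {
  cat(sprintf("<wx_roc> %s-level ROC, %d thresholds, AUC = %.4f\n",
              x$level, nrow(x$points), x$auc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wx_roc <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.wx_roc <- function(x, ...) {
  tibble(auc = x$auc, level = x$level, n_thresholds = nrow(x$points))
}

#' @exportS3Method ggplot2::autoplot
autoplot.wx_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f (%s level)", object$auc,
                                  object$level))
}

#' Coding-to-noncoding signal-to-noise ratio
#'
#' `10 * log10(mean profile energy inside truth exons / mean outside)`, in
#' decibels; larger means better discrimination of coding from noncoding
#' sequence.
#'
#' @param profile A `wx_signal` tibble, one sequence.
#' @param truth `wx_intervals` tibble of true exons; must be non-empty and
#'   must not cover the whole sequence.
#' @return SNR in dB (`Inf` if the noncoding mean is zero).
#' @export
snr_db <- function(profile, truth) {
  p <- profile[order(profile$pos), ]
  check_one_sequence(p[, "sequence_id", drop = FALSE], truth, "snr_db")
  n <- nrow(p)
  if (nrow(truth) == 0L) wx_abort("truth is empty")
  inside <- logical(n)
  for (i in seq_len(nrow(truth))) {
    inside[(truth$start[i] + 1L):truth$end[i]] <- TRUE
  }
  if (all(inside)) wx_abort("truth covers the whole sequence")
  num <- mean(p$value[inside])
  den <- mean(p$value[!inside])
  if (den == 0) {
    rlang::warn("noncoding energy is zero: SNR is infinite")
    return(Inf)
  }
  10 * log10(num / den)
}
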