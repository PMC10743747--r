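#' Per-class Dice coefficients for a patient
#'
#' For each class c in \{EL, IC, TZ\}, the Dice coefficient
#' `2|P_c intersect T_c| / (|P_c| + |T_c|)` pooled over all slices of the
#' patient, plus their arithmetic mean. When a class is absent from both
#' prediction and truth the score is defined as 1 (perfect agreement on
#' absence) — required for blank, skipped slices.
#'
#' @param pred,truth [segmentation_stack()]s of identical dimensions.
#' @return an object of class `dice_report`: `dice_el`, `dice_ic`,
#'   `dice_tz`, `dice_mean`.
#' @export
dice_per_class <- function(pred, truth) {
  check_same_shape(pred, truth)
  p <- unlist(pred$slices); t <- unlist(truth$slices)
  dice_report(dice_binary(p == LABEL_EL, t == LABEL_EL),
              dice_binary(p == LABEL_IC, t == LABEL_IC),
              dice_binary(p == LABEL_TZ, t == LABEL_TZ))
}

#' Per-slice Dice coefficients
#'
#' Same scores as [dice_per_class()] but computed slice by slice, for
#' analyses that relate segmentation quality to slice position.
#'
#' @param pred,truth [segmentation_stack()]s of identical dimensions.
#' @return data.frame with columns `slice`, `dice_el`, `dice_ic`,
#'   `dice_tz`, `dice_mean`.
#' @export
dice_per_slice <- function(pred, truth) {
  check_same_shape(pred, truth)
  rows <- lapply(seq_len(n_slices(pred)), function(i) {
    r <- dice_per_class(
      segmentation_stack(pred$slices[i], pred$patient_id, pred$geometry),
      segmentation_stack(truth$slices[i], truth$patient_id, truth$geometry))
    data.frame(slice = i - 1L, dice_el = r$dice_el, dice_ic = r$dice_ic,
               dice_tz = r$dice_tz, dice_mean = r$dice_mean)
  })
  do.call(rbind, rows)
}

check_same_shape <- function(pred, truth) {
  if (n_slices(pred) != n_slices(truth) ||
      !all(dim(pred$slices[[1]]) == dim(truth$slices[[1]])))
    stop("prediction and truth stacks must have identical dimensions",
         call. = FALSE)
}

dice_binary <- function(p, t) {
  tot <- sum(p) + sum(t)
  if (tot == 0L) return(1)
  2 * sum(p & t) / tot
}

#' Assemble a Dice report
#' @param dice_el,dice_ic,dice_tz per-class Dice scores in \[0, 1\].
#' @return an object of class `dice_report`; `dice_mean` is their
#'   arithmetic mean.
#' @export
dice_report <- function(dice_el, dice_ic, dice_tz) {
  structure(list(dice_el = dice_el, dice_ic = dice_ic, dice_tz = dice_tz,
                 dice_mean = mean(c(dice_el, dice_ic, dice_tz))),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice EL %.3f  IC %.3f  TZ %.3f  mean %.3f\n",
              x$dice_el, x$dice_ic, x$dice_tz, x$dice_mean))
  invisible(x)
}

#' Patient-level confusion counts
#'
#' @param tp,fn,fp,tn non-negative patient counts; the positive class is
#'   an LVNC diagnosis.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' Accuracy (tp+tn)/total, recall tp/(tp+fn), precision tp/(tp+fp) and the
#' F1 score (harmonic mean of precision and recall). A ratio whose
#' denominator is zero is reported as `NA`, not 0.
#'
#' @param counts a [confusion_counts()].
#' @return an object of class `diagnostic_metrics` with fields `accuracy`,
#'   `recall`, `precision`, `f1`.
#' @export
diagnostic_metrics <- function(counts) {
  total <- counts$tp + counts$fn + counts$fp + counts$tn
  if (total == 0) stop("total patient count must be positive", call. = FALSE)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- safe_div(counts$tp, counts$tp + counts$fn)
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  f1 <- if (!is.na(recall) && !is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(accuracy = (counts$tp + counts$tn) / total,
                 recall = recall, precision = precision, f1 = f1),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f  recall %.3f  precision %.3f  F1 %.3f\n",
              x$accuracy, x$recall, x$precision, x$f1))
  invisible(x)
}

#' Paired before/after Dice comparison
#'
#' Tabulates, per image, the Dice score before and after post-processing,
#' the delta, and whether it improved, and summarises the counts of
#' improved / worsened / unchanged images and the mean delta over changed
#' images.
#'
#' @param before,after equal-length numeric vectors or lists of
#'   [dice_report()]s (mean Dice is compared for reports).
#' @return list with `table` (data.frame: before, after, delta, improved)
#'   and `summary` (improved, worsened, unchanged, mean_delta_changed).
#' @export
compare_dice_changes <- function(before, after) {
  as_scores <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(r) r$dice_mean, numeric(1))
  }
  b <- as_scores(before); a <- as_scores(after)
  if (length(b) != length(a))
    stop("before and after must have equal length", call. = FALSE)
  delta <- a - b
  tab <- data.frame(before = b, after = a, delta = delta,
                    improved = delta > 0)
  changed <- delta[delta != 0]
  list(table = tab,
       summary = list(improved = sum(delta > 0), worsened = sum(delta < 0),
                      unchanged = sum(delta == 0),
                      mean_delta_changed = if (length(changed))
                        mean(changed) else 0))
}
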