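#' Pixel-wise confusion counts
#'
#' Counts true/false positives and negatives with the ground truth as
#' reference.
#'
#' @param pred Predicted binary mask.
#' @param truth Ground-truth binary mask of the same shape.
#' @return Object of class \code{confusion_counts} with fields \code{TP},
#'   \code{FP}, \code{TN}, \code{FN}.
#' @export
confusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  p <- pred != 0; t <- truth != 0
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' Jaccard index
#'
#' \code{TP / (TP + FP + FN)}. When both masks are empty the overlap is
#' perfect by convention and 1 is returned with a warning.
#'
#' @param c A \code{confusion_counts}.
#' @return Number in \code{[0, 1]}.
#' @export
jaccard <- function(c) {
  den <- c$TP + c$FP + c$FN
  if (den == 0) {
    warning("both masks empty; Jaccard index defined as 1 by convention")
    return(1)
  }
  c$TP / den
}

#' Dice similarity coefficient
#'
#' \code{2 TP / (2 TP + FP + FN)}; equals \code{2 JI / (1 + JI)}.
#'
#' @param c A \code{confusion_counts}.
#' @return Number in \code{[0, 1]}.
#' @export
dice <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) {
    warning("both masks empty; Dice coefficient defined as 1 by convention")
    return(1)
  }
  2 * c$TP / den
}

#' Sensitivity, specificity and precision
#'
#' \code{TP/(TP+FN)}, \code{TN/(TN+FP)}, \code{TP/(TP+FP)}. A ratio with a
#' zero denominator is reported as \code{NA} (undefined, not zero) so batch
#' averages can exclude it.
#'
#' @param c A \code{confusion_counts}.
#' @return Named list \code{sensitivity}, \code{specificity},
#'   \code{precision}.
#' @export
sens_spec_prec <- function(c) {
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = rat(c$TP, c$TP + c$FN),
       specificity = rat(c$TN, c$TN + c$FP),
       precision = rat(c$TP, c$TP + c$FP))
}

#' All similarity metrics for a mask pair
#'
#' @param pred,truth Binary masks of the same shape.
#' @return Named list \code{ji}, \code{dsc}, \code{sensitivity},
#'   \code{specificity}, \code{precision}.
#' @export
metrics_record <- function(pred, truth) {
  cc <- confusion(pred, truth)
  ssp <- sens_spec_prec(cc)
  c(list(ji = jaccard(cc), dsc = dice(cc)), ssp)
}

#' Mean-intensity contrast between nucleus and cytoplasm
#'
#' Absolute difference of the mean intensities over the two regions.
#'
#' @param image Gray image matrix.
#' @param nucleus,cytoplasm Non-empty binary masks.
#' @return Non-negative number.
#' @export
region_contrast <- function(image, nucleus, cytoplasm) {
  if (sum(nucleus != 0) == 0 || sum(cytoplasm != 0) == 0) {
    stop("both regions must be non-empty to compute a contrast")
  }
  abs(mean(image[nucleus != 0]) - mean(image[cytoplasm != 0]))
}

#' Batch summary of per-image results
#'
#' Aggregates per-image records into per-class means of the nucleus
#' threshold, the whole-cell Otsu threshold, the region contrast and the
#' similarity metrics, plus Pearson correlations between predicted and
#' ground-truth region sizes. Undefined (NA) ratios are excluded from the
#' means, with the exclusion count reported.
#'
#' @param records Data frame with one row per image. Recognized columns:
#'   \code{class}, \code{epsilon_t}, \code{otsu_t}, \code{contrast},
#'   \code{nucleus_ji}, \code{nucleus_dsc}, \code{wbc_ji}, \code{wbc_dsc},
#'   \code{nucleus_size_pred}, \code{nucleus_size_truth},
#'   \code{wbc_size_pred}, \code{wbc_size_truth}; any subset works.
#' @return List with \code{per_class} (data frame of class means),
#'   \code{n_excluded} (NA count per averaged column) and
#'   \code{correlations} (named vector, nucleus and whole-cell size
#'   correlations where the size columns are present).
#' @export
batch_summary <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("empty record list")
  if (is.null(records$class)) records$class <- "all"
  num_cols <- intersect(c("epsilon_t", "otsu_t", "contrast",
                          "nucleus_ji", "nucleus_dsc", "wbc_ji", "wbc_dsc",
                          "sensitivity", "specificity", "precision"),
                        names(records))
  per_class <- do.call(rbind, lapply(split(records, records$class), function(d) {
    row <- data.frame(class = d$class[1], n = nrow(d))
    for (cl in num_cols) row[[paste0(cl, "_mean")]] <- mean(d[[cl]], na.rm = TRUE)
    row
  }))
  rownames(per_class) <- NULL
  n_excluded <- vapply(num_cols, function(cl) sum(is.na(records[[cl]])), 0L)
  correlations <- c()
  for (what in c("nucleus", "wbc")) {
    pc <- paste0(what, "_size_pred"); tc <- paste0(what, "_size_truth")
    if (all(c(pc, tc) %in% names(records)) && nrow(records) > 1 &&
        sd(records[[pc]]) > 0 && sd(records[[tc]]) > 0) {
      correlations[paste0(what, "_size_cor")] <- cor(records[[pc]], records[[tc]])
    }
  }
  list(per_class = per_class, n_excluded = n_excluded, correlations = correlations)
}

#' Evaluate predicted masks against a tri-level ground truth
#'
#' The nucleus is scored against label 255 and the whole cell against the
#' union of labels 255 and 128.
#'
#' @param nucleus_pred,wbc_pred Predicted binary masks.
#' @param truth Tri-level mask (\code{0/128/255}).
#' @return List of metric records \code{nucleus} and \code{wbc}.
#' @export
evaluate_against_truth <- function(nucleus_pred, wbc_pred, truth) {
  nuc_t <- matrix(as.integer(truth == 255), nrow(truth), ncol(truth))
  wbc_t <- matrix(as.integer(truth >= 128), nrow(truth), ncol(truth))
  list(nucleus = metrics_record(nucleus_pred, nuc_t),
       wbc = metrics_record(wbc_pred, wbc_t))
}
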