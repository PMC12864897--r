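# Evaluation surfaces: per-class precision/recall/F1, confusion matrix,
# pairwise AUROC contrasts, Cohen's kappa.

#' Per-class classification metrics
#'
#' One-vs-rest precision, recall and F1 for each of the three coarse
#' classes, the unweighted macro-mean F1, and the 3x3 confusion matrix
#' (rows = truth). Zero-denominator cells are reported as `NA` with an
#' `undefined` flag, never silently zero.
#'
#' @param truth,pred Equal-length label vectors over `levels`.
#' @param levels Class levels in severity order.
#' @return An `slhs_metrics` list: `confusion`, `per_class` (data.table
#'   with `precision`, `recall`, `f1`, `undefined_precision`,
#'   `undefined_recall`), `macro_f1`, `n`.
#' @export
class_metrics <- function(truth, pred, levels = coarse_label_levels()) {
  if (length(truth) != length(pred))
    .stopf("truth and prediction lengths differ")
  if (!all(truth %in% levels) || !all(pred %in% levels))
    .stopf("unknown label outside {%s}", paste(levels, collapse = ", "))
  tf <- factor(truth, levels = levels)
  pf <- factor(pred, levels = levels)
  cm <- table(truth = tf, prediction = pf)
  per <- data.table(class = levels)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  per[, `:=`(
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    recall = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
    undefined_precision = tp + fp == 0,
    undefined_recall = tp + fn == 0)]
  per[, f1 := ifelse(!is.na(precision) & !is.na(recall) &
                       (precision + recall) > 0,
                     2 * precision * recall / (precision + recall),
                     ifelse(is.na(precision) | is.na(recall), NA_real_, 0))]
  structure(list(confusion = unclass(cm),
                 per_class = per[],
                 macro_f1 = mean(per$f1, na.rm = TRUE),
                 n = length(truth)),
            class = "slhs_metrics")
}

#' @export
print.slhs_metrics <- function(x, ...) {
  cat("<slhs_metrics> n =", x$n, "\n")
  print(x$confusion)
  print(x$per_class[, .(class, precision, recall, f1)], digits = 3)
  cat(sprintf("macro F1 %.3f\n", x$macro_f1))
  invisible(x)
}

#' Pairwise AUROC between two label groups
#'
#' Rank-based AUROC (Mann-Whitney with midrank tie handling) of a score
#' for rows whose truth label lies in `positive` versus rows in
#' `negative`; all other rows are dropped. The two contrasts of interest
#' are confirmed vs no sepsis (possible-sepsis rows dropped) and
#' confirmed-or-possible vs no sepsis.
#'
#' @param truth Label vector.
#' @param score Numeric score (higher = more positive).
#' @param positive,negative Label sets defining the contrast.
#' @return AUROC in `[0, 1]`.
#' @export
pairwise_auroc <- function(truth, score, positive = "CS", negative = "NS") {
  sel <- truth %in% c(positive, negative)
  truth <- truth[sel]; score <- score[sel]
  pos <- truth %in% positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) .stopf("empty group in AUROC contrast")
  r <- rank(score)              # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa with a large-sample confidence interval
#'
#' Unweighted kappa between two raters over the same items, with the
#' standard large-sample Wald interval.
#'
#' @param a,b Equal-length label vectors.
#' @param conf_level Confidence level (default 0.95).
#' @return List `kappa`, `ci` (length 2), `po`, `pe`, `n`.
#' @export
cohens_kappa <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) .stopf("rater sequences differ in length")
  lev <- sort(unique(c(a, b)))
  ta <- factor(a, levels = lev); tb <- factor(b, levels = lev)
  cm <- table(ta, tb) / length(a)
  po <- sum(diag(cm))
  pe <- sum(rowSums(cm) * colSums(cm))
  if (pe == 1) return(list(kappa = 1, ci = c(1, 1), po = po, pe = pe,
                           n = length(a)))
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (length(a) * (1 - pe)^2))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kappa, ci = c(kappa - z * se, kappa + z * se),
       po = po, pe = pe, n = length(a))
}

#' Stay-level metrics report
#'
#' Combines the per-class metrics with the two AUROC contrasts used to
#' monitor the model: confirmed vs no sepsis, and confirmed-or-possible vs
#' no sepsis.
#'
#' @param truth Stay-level truth labels (NS/PS/CS).
#' @param pred Stay-level predicted labels.
#' @param cs_prob Stay-level confirmed-sepsis probability.
#' @return An `slhs_metrics` object with `auroc_cs_vs_ns` and
#'   `auroc_csps_vs_ns` added.
#' @export
metrics_report <- function(truth, pred, cs_prob) {
  m <- class_metrics(truth, pred)
  m$auroc_cs_vs_ns <- tryCatch(
    pairwise_auroc(truth, cs_prob, "CS", "NS"), error = function(e) NA_real_)
  m$auroc_csps_vs_ns <- tryCatch(
    pairwise_auroc(truth, cs_prob, c("CS", "PS"), "NS"),
    error = function(e) NA_real_)
  m
}
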