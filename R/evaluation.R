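#' Confusion-count performance metrics
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `Ac = (TP+TN)/(TP+FP+TN+FN)` and the Matthews correlation coefficient
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.  When any
#' factor of the MCC denominator is 0 the MCC is reported as 0 (the usual
#' convention for degenerate margins); `Sn`/`Sp` are `NaN` when their own
#' denominator is 0.
#'
#' @param tp,tn,fp,fn Non-negative integer counts (at least one positive).
#' @return List with `Sn`, `Sp`, `Ac`, `MCC` and the counts.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("negative confusion counts")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  ac <- (tp + tn) / sum(counts)
  denom <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fn * fp) / sqrt(denom)
  list(Sn = sn, Sp = sp, Ac = ac, MCC = mcc,
       counts = as.list(counts))
}

#' ROC curve and AUC
#'
#' The ROC is swept over the unique score values (equal scores collapse to
#' one threshold); a sample is called positive when `score >= threshold`.
#' The AUC is the trapezoidal area under `(1 - Sp, Sn)`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 (or logical) true labels; both classes required.
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) stop("ROC requires both classes")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # one point per unique score
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Stratified k-fold cross-validation
#'
#' Windows are assigned to folds stratified by label (fold sizes differ by at
#' most one per class, seeded and reproducible).  `trainer` is a function
#' `(train_dataset) -> model` and `scorer` a function
#' `(model, test_dataset) -> numeric scores`; each window is scored exactly
#' once, and a pooled ROC over all held-out scores is reported.
#'
#' @param dataset A `phospho_dataset` with both labels.
#' @param k Number of folds (default 4).
#' @param trainer,scorer Training and scoring functions.
#' @param seed Integer seed for the fold assignment.
#' @return List with `folds` (per-fold AUC), `pooled` (ROC + AUC over pooled
#'   held-out scores), `assignment` (fold id per window) and `scores`.
#' @export
kfold_cv <- function(dataset, k = 4L, trainer, scorer, seed = 1L) {
  stopifnot(k >= 2L)
  w <- dataset$windows
  y <- as.numeric(w$label == "positive")
  if (length(unique(y)) < 2L) stop("cross-validation requires both classes")
  set.seed(seed)
  fold <- integer(nrow(w))
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (min(table(fold, y)) == 0) {
    stop("a fold lost one class entirely; reduce k or enlarge the dataset")
  }
  scores <- numeric(nrow(w))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- new_dataset(w[fold != f, , drop = FALSE], dataset$flank_n,
                      dataset$residue_set, dataset$provenance)
    te <- new_dataset(w[fold == f, , drop = FALSE], dataset$flank_n,
                      dataset$residue_set, dataset$provenance)
    model <- trainer(tr)
    sc <- scorer(model, te)
    scores[fold == f] <- sc
    fold_auc[f] <- roc_auc(sc, y[fold == f])$auc
  }
  pooled <- roc_auc(scores, y)
  list(folds = data.frame(fold = seq_len(k), auc = fold_auc),
       pooled = pooled, assignment = fold, scores = scores)
}

#' Calibrate specificity-anchored decision thresholds
#'
#' The High/Medium/Low cutoffs target specificities of 95%, 90% and 85% on
#' negative scores: each cutoff is the corresponding empirical quantile of
#' the calibration negatives, with linear interpolation between order
#' statistics (`stats::quantile` type 7), so a negative scores below the
#' cutoff with approximately the target probability.  "All" has cutoff 0.
#'
#' @param negative_scores Scores of calibration negatives (warns below 200).
#' @param targets Named specificity targets for the three levels.
#' @return A data.frame (`level`, `target_sp`, `cutoff`) of class
#'   `threshold_table`, ordered High, Medium, Low, All.
#' @export
calibrate_thresholds <- function(negative_scores,
                                 targets = c(High = 0.95, Medium = 0.90,
                                             Low = 0.85)) {
  if (length(negative_scores) == 0L) stop("no calibration negatives")
  if (length(negative_scores) < 200L) {
    warning("fewer than 200 calibration negatives; cutoffs will be noisy")
  }
  cuts <- stats::quantile(negative_scores, probs = targets, type = 7,
                          names = FALSE)
  out <- data.frame(level = c(names(targets), "All"),
                    target_sp = c(unname(targets), NA_real_),
                    cutoff = c(cuts, 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("threshold_table", "data.frame")
  out
}
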