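# Confusion-matrix metrics, threshold sweeps and selection, ROC / PR
# curves, five-fold cross-validation and residue-composition analysis.
#
# Conventions (used consistently everywhere):
#   * a pattern is called positive iff score >= threshold (ties positive);
#   * sensitivity, specificity and accuracy are percentages in [0, 100];
#   * precision, recall-as-fraction and F1 are in [0, 1]; MCC in [-1, 1];
#   * any metric whose denominator is 0 is reported as 0.

#' Confusion-matrix metrics at a fixed decision threshold
#'
#' @param scores numeric prediction scores.
#' @param labels binary truth (0/1, logical, or "positive"/"negative").
#' @param threshold decision threshold; score >= threshold is a positive call.
#' @return one-row data frame: \code{threshold}, counts \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}, \code{sensitivity} (= recall, \%),
#'   \code{specificity} (\%), \code{accuracy} (\%), \code{precision} ([0,1]),
#'   \code{f1} ([0,1]) and \code{mcc} ([-1,1]).
#' @examples
#' metrics_at_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
#' @export
metrics_at_threshold <- function(scores, labels, threshold) {
  labels <- as_binary_labels(labels)
  if (length(scores) == 0L) stop("empty score vector")
  if (length(scores) != length(labels)) {
    stop("scores (", length(scores), ") and labels (", length(labels),
         ") differ in length")
  }
  call <- scores >= threshold
  tp <- sum(call & labels == 1L)
  fp <- sum(call & labels == 0L)
  tn <- sum(!call & labels == 0L)
  fn <- sum(!call & labels == 1L)
  frac <- function(num, den) if (den == 0) 0 else num / den
  sn <- 100 * frac(tp, tp + fn)
  sp <- 100 * frac(tn, tn + fp)
  acc <- 100 * (tp + tn) / (tp + tn + fp + fn)
  prec <- frac(tp, tp + fp)
  rec <- frac(tp, tp + fn)
  f1 <- frac(2 * prec * rec, prec + rec)
  mcc_den <- sqrt(prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))))
  mcc <- if (mcc_den == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  data.frame(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = sn, specificity = sp, accuracy = acc,
             precision = prec, f1 = f1, mcc = mcc)
}

#' Sweep decision thresholds over a score range
#'
#' Computes \code{\link{metrics_at_threshold}} at evenly spaced thresholds
#' including both endpoints.  Default ranges: ANN outputs are swept over
#' [0, 1]; SVM decision margins over [-1, 1]; step 0.1 in both cases.
#'
#' @inheritParams metrics_at_threshold
#' @param lo,hi inclusive sweep endpoints (\code{lo < hi}).
#' @param step positive step size.
#' @return data frame with one metrics row per threshold, ascending.
#' @export
sweep_thresholds <- function(scores, labels, lo, hi, step = 0.1) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo < hi)) {
    stop("invalid sweep range: need lo < hi")
  }
  if (!(is.numeric(step) && step > 0)) stop("step must be positive")
  thresholds <- lo + step * seq.int(0L, floor((hi - lo) / step + 1e-9))
  do.call(rbind, lapply(thresholds, function(t) {
    metrics_at_threshold(scores, labels, t)
  }))
}

#' Select the working threshold from a sweep table
#'
#' Lexicographic rule: keep the rows with maximum MCC; among them maximum
#' accuracy; then maximum precision (skipped when the table carries no
#' precision column, as printed ANN sweep tables may not); then least
#' absolute difference between sensitivity and specificity; any remaining
#' tie resolves to the lowest threshold.  The result does not depend on row
#' order.
#'
#' @param rows data frame with columns \code{threshold}, \code{mcc},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity} and optionally
#'   \code{precision} (e.g. from \code{\link{sweep_thresholds}}).
#' @return the selected threshold (numeric scalar).
#' @export
select_threshold <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0L)
  need <- c("threshold", "mcc", "accuracy", "sensitivity", "specificity")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("sweep table lacks column(s): ",
                         paste(miss, collapse = ", "))
  eps <- 1e-9
  keep_max <- function(df, v) df[v >= max(v) - eps, , drop = FALSE]
  rows <- keep_max(rows, rows$mcc)
  rows <- keep_max(rows, rows$accuracy)
  if ("precision" %in% names(rows) && !all(is.na(rows$precision))) {
    rows <- keep_max(rows, rows$precision)
  }
  rows <- keep_max(rows, -abs(rows$sensitivity - rows$specificity))
  min(rows$threshold)
}

#' ROC curve and area under it
#'
#' The ROC traces true-positive proportion TP/(TP+FN) against
#' false-positive proportion FP/(FP+TN) over every distinct score used as a
#' threshold (ties called positive); AUC is the trapezoidal area under the
#' resulting polyline.
#'
#' @inheritParams metrics_at_threshold
#' @return list with \code{auc} (in [0,1]) and \code{points}, a data frame
#'   of \code{threshold}, \code{fpr}, \code{tpr} ordered by ascending FPR.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2L) {
    stop("ROC requires both classes to be present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cum_tp <- cumsum(l == 1L); cum_fp <- cumsum(l == 0L)
  last <- findInterval(-thr, -s)  # index of last item with score >= thr
  tpr <- c(0, cum_tp[last] / n_pos, 1)
  fpr <- c(0, cum_fp[last] / n_neg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       points = data.frame(threshold = c(Inf, thr, -Inf), fpr = fpr, tpr = tpr))
}

#' Precision-recall curve
#'
#' @inheritParams metrics_at_threshold
#' @return data frame of \code{threshold}, \code{recall} ([0,1]) and
#'   \code{precision} ([0,1]) over all distinct score thresholds, ordered by
#'   ascending recall.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2L) {
    stop("PR curve requires both classes to be present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  rows <- do.call(rbind, lapply(thr, function(t) {
    m <- metrics_at_threshold(scores, labels, t)
    data.frame(threshold = t, recall = m$sensitivity / 100,
               precision = m$precision)
  }))
  rows[order(rows$recall, rows$threshold), , drop = FALSE]
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin into `n_folds` folds.  Call inside with_seed().
make_stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Five-fold cross-validation with a threshold sweep
#'
#' Patterns are randomly divided into five stratified folds (class ratio
#' preserved); each fold serves as the test set exactly once while a model
#' is trained on the remaining four.  Per fold, test-set scores are swept
#' over the backend's threshold range; the fold-averaged table is the
#' arithmetic mean of the five per-fold metric tables at each threshold, and
#' the working threshold is selected on that averaged table.  The reported
#' AUC is the mean of per-fold AUCs; pooled out-of-fold scores provide the
#' ROC and precision-recall points.
#'
#' By default folds are drawn at the pattern level.  \code{split_by_chain =
#' TRUE} instead assigns whole chains to folds, which prevents near-identical
#' overlapping windows of one protein from appearing in both train and test
#' (pattern-level splitting is optimistically biased in that respect).
#'
#' @inheritParams train_model
#' @param n_folds number of folds (default 5).
#' @param step sweep step (default 0.1).
#' @param split_by_chain assign whole chains to folds instead of patterns.
#' @return object of class \code{cv_report}: list with \code{per_fold}
#'   (list of sweep tables), \code{averaged} (fold-averaged sweep table),
#'   \code{fold_auc}, \code{auc}, \code{roc}, \code{pr},
#'   \code{selected_threshold}, \code{scores} (pooled out-of-fold scores),
#'   \code{labels}, \code{fold} assignment and \code{seed}.
#' @export
five_fold_cv <- function(dataset, encoding = c("binary", "pssm"),
                         backend = c("svm", "ann"), profiles = NULL,
                         hyperparameters = list(), seed, n_folds = 5L,
                         step = 0.1, split_by_chain = FALSE) {
  encoding <- match.arg(encoding)
  backend <- match.arg(backend)
  stopifnot(inherits(dataset, "pattern_dataset"))
  x <- encode_patterns(dataset, encoding, profiles)
  y <- as_binary_labels(attr(x, "labels"))
  if (min(table(y)) < n_folds) {
    stop("five-fold cross-validation needs at least ", n_folds,
         " patterns per class; got ", paste(table(y), collapse = "/"))
  }
  fold <- with_seed(seed, {
    if (split_by_chain) {
      chains <- unique(dataset$patterns$chain_id)
      chain_fold <- stats::setNames(rep_len(seq_len(n_folds),
                                            length(chains))[sample.int(length(chains))],
                                    chains)
      unname(chain_fold[dataset$patterns$chain_id])
    } else {
      make_stratified_folds(y, n_folds)
    }
  })
  rng <- threshold_range(backend)
  meta <- list(technique = dataset$technique, encoding = encoding,
               L = unique(dataset$patterns$L), k = unique(dataset$patterns$k),
               regime = dataset$regime)
  per_fold <- vector("list", n_folds)
  fold_auc <- numeric(n_folds)
  pooled_scores <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    te <- fold == f
    if (!any(te) || length(unique(y[!te])) < 2L) {
      stop("fold ", f, " is degenerate (empty test set or single-class training set)")
    }
    model <- train_model_xy(x[!te, , drop = FALSE], y[!te], backend,
                            hyperparameters, seed = seed + f, meta = meta)
    s <- score_model(model, x[te, , drop = FALSE])
    pooled_scores[te] <- s
    per_fold[[f]] <- sweep_thresholds(s, y[te], rng[1], rng[2], step)
    fold_auc[f] <- if (length(unique(y[te])) < 2L) NA_real_
                   else roc_auc(s, y[te])$auc
  }
  averaged <- per_fold[[1]]
  metric_cols <- setdiff(names(averaged), "threshold")
  for (col in metric_cols) {
    averaged[[col]] <- Reduce(`+`, lapply(per_fold, `[[`, col)) / n_folds
  }
  roc <- roc_auc(pooled_scores, y)
  structure(list(per_fold = per_fold, averaged = averaged,
                 fold_auc = fold_auc, auc = mean(fold_auc, na.rm = TRUE),
                 roc = roc$points, pr = pr_curve(pooled_scores, y),
                 selected_threshold = select_threshold(averaged),
                 scores = pooled_scores, labels = y, fold = fold,
                 backend = backend, encoding = encoding,
                 technique = dataset$technique, seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  best <- x$averaged[which.min(abs(x$averaged$threshold - x$selected_threshold)), ]
  cat(sprintf(paste0("<cv_report> %s/%s/%s: AUC %.3f; threshold %.2f ",
                     "(MCC %.2f, Acc %.2f%%)\n"),
              x$backend, x$technique, x$encoding, x$auc,
              x$selected_threshold, best$mcc, best$accuracy))
  invisible(x)
}

#' Write a fold-averaged threshold sweep as TSV
#'
#' Column order mirrors the conventional sweep-table layout: Threshold,
#' Sensitivity, Specificity, Accuracy, MCC, plus Precision and F1.
#'
#' @param report a \code{cv_report} (or a sweep data frame).
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_sweep_tsv <- function(report, path) {
  tbl <- if (inherits(report, "cv_report")) report$averaged else report
  out <- tbl[, c("threshold", "sensitivity", "specificity", "accuracy",
                 "mcc", "precision", "f1")]
  names(out) <- c("Threshold", "Sensitivity", "Specificity", "Accuracy",
                  "MCC", "Precision", "F1")
  utils::write.table(format(out, digits = 4, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Residue composition of interacting vs non-interacting positions
#'
#' For each of the 20 standard amino acids, the percentage it contributes
#' to all GTP-interacting residues and to all non-interacting residues
#' across the supplied chains; each percentage vector sums to 100.
#'
#' @param chains list of \code{\link{labeled_chain}} with at least one
#'   residue in each class.
#' @return data frame with columns \code{residue},
#'   \code{interacting_pct}, \code{noninteracting_pct} and
#'   \code{difference} (interacting - noninteracting).
#' @export
composition_analysis <- function(chains) {
  stopifnot(is.list(chains), length(chains) > 0L)
  letters <- unlist(lapply(chains, function(ch) {
    strsplit(ch$sequence, "", fixed = TRUE)[[1]]
  }))
  labels <- unlist(lapply(chains, function(ch) ch$labels))
  if (sum(labels == 1L) == 0L) stop("no interacting residues in input")
  if (sum(labels == 0L) == 0L) stop("no non-interacting residues in input")
  pct <- function(mask) {
    counts <- table(factor(letters[mask], levels = .AA20))
    100 * as.numeric(counts) / sum(counts)
  }
  pos <- pct(labels == 1L)
  neg <- pct(labels == 0L)
  data.frame(residue = .AA20, interacting_pct = pos,
             noninteracting_pct = neg, difference = pos - neg)
}

#' Plot a ROC or precision-recall curve
#'
#' Base-graphics convenience plots for \code{\link{roc_auc}} /
#' \code{\link{pr_curve}} output or a \code{cv_report}.
#'
#' @param report a \code{cv_report}.
#' @param which "roc" or "pr".
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plot_curve <- function(report, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  stopifnot(inherits(report, "cv_report"))
  if (which == "roc") {
    plot(report$roc$fpr, report$roc$tpr, type = "l",
         xlab = "False positive proportion", ylab = "True positive proportion",
         main = sprintf("ROC (mean fold AUC = %.3f)", report$auc), ...)
    graphics::abline(0, 1, lty = 2, col = "grey")
  } else {
    plot(report$pr$recall, report$pr$precision, type = "l",
         xlab = "Recall", ylab = "Precision", ylim = c(0, 1),
         main = "Precision-recall curve", ...)
  }
  invisible(NULL)
}
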