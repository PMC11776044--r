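#' Exact-match accuracy of a prediction set
#'
#' A prediction counts as correct only when the predicted label *set* equals
#' the ground-truth set exactly (single-label mode: the predicted label
#' equals the primary label). This is the strictest multilabel accuracy: an
#' extra or missing label makes the whole prediction wrong.
#'
#' @param preds A `prediction_set`, or a list of them (pooled).
#' @return Fraction in `[0, 1]`.
#' @export
exact_match_accuracy <- function(preds) {
  if (inherits(preds, "prediction_set")) preds <- list(preds)
  if (length(preds) == 0L) stop("empty prediction set collection")
  hits <- unlist(lapply(preds, function(ps) {
    mapply(function(p, t) setequal(p, t), ps$predicted, ps$truth)
  }))
  mean(hits)
}

#' Per-label (Hamming) accuracy of a prediction set
#'
#' Mean over images and classes of the agreement between predicted and true
#' class membership; an upper bound on [exact_match_accuracy()].
#'
#' @inheritParams exact_match_accuracy
#' @return Fraction in `[0, 1]`.
#' @export
hamming_accuracy <- function(preds) {
  if (inherits(preds, "prediction_set")) preds <- list(preds)
  accs <- unlist(lapply(preds, function(ps) {
    vapply(seq_along(ps$predicted), function(i) {
      mean((ps$classes %in% ps$predicted[[i]]) ==
             (ps$classes %in% ps$truth[[i]]))
    }, 0)
  }))
  mean(accs)
}

# Average precision for one class by step integration of the PR staircase:
# AP = sum_k (R_k - R_{k-1}) * P_k over distinct-score thresholds in
# decreasing order. Tie groups enter together, so the value is invariant to
# the ordering of images.
average_precision <- function(scores, positive) {
  n_pos <- sum(positive)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  cum_tp <- cumsum(y)
  cut <- which(diff(s) != 0)            # last index of each tie group
  idx <- c(cut, length(s))
  tp <- cum_tp[idx]
  prec <- tp / idx
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Macro-averaged area under the precision-recall curve
#'
#' Computes the average precision of every class from the full score ranking
#' (step integration of the PR staircase, no linear interpolation) and
#' averages arithmetically over classes with at least one positive example;
#' classes without positives are excluded with a message.
#'
#' @param scores Numeric n x K score matrix, columns named by class, or a
#'   `prediction_set` / list of prediction sets (scores pooled).
#' @param truths List of n character label sets (ignored when `scores` is a
#'   prediction set).
#' @return Fraction in `[0, 1]`.
#' @export
macro_pr_auc <- function(scores, truths = NULL) {
  if (inherits(scores, "prediction_set")) scores <- list(scores)
  if (is.list(scores) && !is.data.frame(scores)) {
    truths <- unlist(lapply(scores, `[[`, "truth"), recursive = FALSE)
    # folds may carry different vocabularies (classes can be absent from a
    # training fold); align on the union, scoring missing classes 0
    vocab <- sort(unique(unlist(lapply(scores, function(ps) {
      colnames(ps$scores)
    }))))
    scores <- do.call(rbind, lapply(scores, function(ps) {
      m <- matrix(0, nrow(ps$scores), length(vocab),
                  dimnames = list(NULL, vocab))
      m[, colnames(ps$scores)] <- ps$scores
      m
    }))
  }
  scores <- as.matrix(scores)
  classes <- colnames(scores)
  stopifnot(!is.null(classes), length(truths) == nrow(scores))
  ap <- vapply(classes, function(cl) {
    pos <- vapply(truths, function(t) cl %in% t, TRUE)
    average_precision(scores[, cl], pos)
  }, 0)
  if (all(is.na(ap))) stop("no class has a positive example")
  skipped <- classes[is.na(ap)]
  if (length(skipped)) {
    message("macro_pr_auc: excluding classes without positives: ",
            paste(skipped, collapse = ", "))
  }
  mean(ap, na.rm = TRUE)
}

# fold-level confusion counts for one class
class_counts <- function(ps, cl) {
  pred <- vapply(ps$predicted, function(p) cl %in% p, TRUE)
  true <- vapply(ps$truth, function(t) cl %in% t, TRUE)
  c(TP = sum(pred & true), FP = sum(pred & !true),
    FN = sum(!pred & true), TN = sum(!pred & !true))
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Per-class deconvolution of cross-validated predictions
#'
#' For every class and fold computes precision = TP/(TP+FP), recall =
#' TP/(TP+FN) and F1 = 2PR/(P+R) (all as percentages; 0 when a denominator
#' is 0), then averages each metric across the folds in which the class
#' appears (has any true or predicted instance). Averaging per-fold F1 — not
#' taking the harmonic mean of the averaged precision and recall — is
#' deliberate: the two orderings differ. Classes whose fold-mean precision
#' reaches `precision_threshold` are flagged as reliably predictable.
#'
#' @param per_fold_preds List of `prediction_set`s (one per fold).
#' @param precision_threshold Minimum fold-mean precision, in percent
#'   (default 10).
#' @return An object of class `class_report`: a data frame (one row per
#'   class, sorted by decreasing fold-mean F1) with columns `class`,
#'   `support`, `n_folds`, `precision`, `recall`, `f1`,
#'   `passes_threshold`; attributes `grand_means` (mean precision/recall/F1
#'   over classes) and `per_fold` (long data frame of per-fold counts and
#'   metrics).
#' @export
class_deconvolution <- function(per_fold_preds, precision_threshold = 10) {
  if (inherits(per_fold_preds, "prediction_set")) {
    per_fold_preds <- list(per_fold_preds)
  }
  stopifnot(length(per_fold_preds) >= 1L)
  if (precision_threshold < 0 || precision_threshold > 100) {
    stop("precision_threshold must lie in [0, 100]")
  }
  classes <- sort(unique(unlist(lapply(per_fold_preds, `[[`, "classes"))))
  rows <- list()
  for (f in seq_along(per_fold_preds)) {
    ps <- per_fold_preds[[f]]
    for (cl in classes) {
      ct <- class_counts(ps, cl)
      if (ct["TP"] + ct["FP"] + ct["FN"] == 0) next  # class absent from fold
      p <- 100 * safe_ratio(ct["TP"], ct["TP"] + ct["FP"])
      r <- 100 * safe_ratio(ct["TP"], ct["TP"] + ct["FN"])
      f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, fold = ps$fold, TP = ct[["TP"]], FP = ct[["FP"]],
        FN = ct[["FN"]], TN = ct[["TN"]], precision = unname(p),
        recall = unname(r), f1 = unname(f1), stringsAsFactors = FALSE
      )
    }
  }
  per_fold <- do.call(rbind, rows)
  if (is.null(per_fold)) stop("no class appears in any fold")
  agg <- function(v, cl) vapply(split(v, cl), mean, 0)
  cl_f <- per_fold$class
  report <- data.frame(
    class = names(agg(per_fold$precision, cl_f)),
    support = as.integer(vapply(split(per_fold$TP + per_fold$FN, cl_f),
                                sum, 0)),
    n_folds = as.integer(vapply(split(cl_f, cl_f), length, 0L)),
    precision = unname(agg(per_fold$precision, cl_f)),
    recall = unname(agg(per_fold$recall, cl_f)),
    f1 = unname(agg(per_fold$f1, cl_f)),
    stringsAsFactors = FALSE
  )
  report$passes_threshold <- report$precision >= precision_threshold
  report <- report[order(-report$f1, report$class), , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "grand_means") <- c(precision = mean(report$precision),
                                   recall = mean(report$recall),
                                   f1 = mean(report$f1))
  attr(report, "precision_threshold") <- precision_threshold
  attr(report, "per_fold") <- per_fold
  class(report) <- c("class_report", "data.frame")
  report
}

#' @export
print.class_report <- function(x, ...) {
  gm <- attr(x, "grand_means")
  cat(sprintf(
    "<class_report> %d classes, %d pass precision >= %g%%; grand means: P %.2f%% R %.2f%% F1 %.2f%%\n",
    nrow(x), sum(x$passes_threshold), attr(x, "precision_threshold"),
    gm["precision"], gm["recall"], gm["f1"]
  ))
  print.data.frame(utils::head(as.data.frame(x), 25), digits = 4)
  invisible(x)
}

#' Write a class report as CSV (per-class table) and JSON (summary)
#'
#' @param report A `class_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_class_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    gm <- attr(report, "grand_means")
    jsonlite::write_json(
      list(grand_means = as.list(gm),
           precision_threshold = attr(report, "precision_threshold"),
           passing_classes = report$class[report$passes_threshold]),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(c(csv = csv_path, json = json_path))
}
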