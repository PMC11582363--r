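#' One-vs-rest confusion counts
#'
#' Per-class true/false positive/negative counts for a multi-class
#' prediction, treating each class in turn as the positive label.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class vocabulary; defaults to the sorted union of the
#'   observed labels.  Labels outside `classes` are an error.
#' @return A data frame of class `confusion_counts` with columns `class`,
#'   `tp`, `fp`, `fn`, `tn` (each row sums to `length(y_true)`).
#' @export
confusion_counts <- function(y_true, y_pred, classes = NULL) {
  if (!length(y_true) || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be equal-length, non-empty", call. = FALSE)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  classes <- as.character(classes)
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad))
    stop("label error: unseen label(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               tn = length(y_true) - tp - fp - fn)
  }))
  class(out) <- c("confusion_counts", class(out))
  out
}

safe_ratio <- function(num, den, what) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0))
    warning("zero denominator in ", what, "; reporting 0", call. = FALSE)
  out
}

#' Confusion-derived classification metrics
#'
#' Per-class precision `TP/(TP+FP)`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and the F-score (harmonic mean of precision
#' and recall), plus their unweighted macro averages and overall accuracy.
#' Zero-denominator metrics are reported as 0 with a warning rather than
#' failing, so small cross-validation folds never abort.
#'
#' @param counts A [confusion_counts()] data frame.
#' @return A list of class `metrics_report`: `per_class` (data frame) and
#'   `macro` (named vector with `precision`, `sensitivity`, `specificity`,
#'   `f_score`), plus `accuracy`.
#' @export
basic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  prec <- safe_ratio(counts$tp, counts$tp + counts$fp, "precision")
  sens <- safe_ratio(counts$tp, counts$tp + counts$fn, "sensitivity")
  spec <- safe_ratio(counts$tn, counts$tn + counts$fp, "specificity")
  f <- ifelse(prec + sens > 0, 2 * prec * sens / (prec + sens), 0)
  per_class <- data.frame(class = counts$class, precision = prec,
                          sensitivity = sens, specificity = spec,
                          f_score = f)
  n <- counts$tp[1] + counts$fp[1] + counts$fn[1] + counts$tn[1]
  structure(list(per_class = per_class,
                 macro = c(precision = mean(prec), sensitivity = mean(sens),
                           specificity = mean(spec), f_score = mean(f)),
                 accuracy = sum(counts$tp) / n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  print(x$per_class, digits = 4)
  cat(sprintf("macro: precision %.4f  sensitivity %.4f  specificity %.4f  F %.4f\n",
              x$macro["precision"], x$macro["sensitivity"],
              x$macro["specificity"], x$macro["f_score"]))
  cat(sprintf("accuracy %.4f\n", x$accuracy))
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(P_o - P_e) / (1 - P_e)`, where `P_o` is
#' the observed agreement rate and `P_e` the agreement expected from the
#' two label marginals.  Ranges from -1 (worse than chance) to 1 (perfect
#' agreement); returns `NA` with a warning when `P_e = 1` (both vectors
#' constant), where the statistic is undefined.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
kappa_score <- function(y_true, y_pred) {
  if (!length(y_true) || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be equal-length, non-empty", call. = FALSE)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  p_o <- mean(y_true == y_pred)
  p_e <- sum(vapply(classes, function(cl)
    mean(y_true == cl) * mean(y_pred == cl), numeric(1)))
  if (p_e >= 1 - 1e-12) {
    warning("expected agreement is 1; kappa undefined", call. = FALSE)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Kullback-Leibler divergence of two discrete distributions
#'
#' `D_KL(P || Q) = sum p * log(p / q)` in nats: nonnegative, zero exactly
#' when the distributions coincide.  Terms with `p = 0` contribute 0; a
#' cell with `q = 0 < p` yields `Inf` with a warning.  `paper_sign = TRUE`
#' evaluates the integrand with `p` and `q` swapped inside the logarithm
#' (which negates the divergence) for comparison with sources that print
#' it that way.
#'
#' @param p,q Nonnegative vectors of equal length summing to 1 within
#'   `1e-9`.
#' @param paper_sign Use the swapped-log form (default `FALSE`).
#' @return The divergence in nats (>= 0 in the standard orientation).
#' @export
kl_divergence <- function(p, q, paper_sign = FALSE) {
  if (length(p) != length(q))
    stop("p and q must have equal length", call. = FALSE)
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("normalization error: p and q must be distributions", call. = FALSE)
  support <- p > 0
  if (any(q[support] == 0)) {
    warning("q = 0 where p > 0: divergence is infinite", call. = FALSE)
    return(if (paper_sign) -Inf else Inf)
  }
  d <- sum(p[support] * log(p[support] / q[support]))
  if (paper_sign) -d else d
}

#' One-vs-rest ROC-AUC
#'
#' Area under the ROC curve per class from predicted class probabilities,
#' computed by the midrank (Wilcoxon) statistic so ties contribute 1/2,
#' plus the unweighted macro average.  A class absent from `y_true` is
#' reported `NA` and excluded from the macro mean.
#'
#' @param y_true Label vector.
#' @param scores Numeric matrix of per-class scores (columns named by, or
#'   ordered as, `classes`).
#' @param classes Class vocabulary; defaults to the score column names.
#' @return A list with `per_class` (named AUC vector) and `macro`.
#' @export
roc_auc <- function(y_true, scores, classes = NULL) {
  scores <- as.matrix(scores)
  if (is.null(classes)) classes <- colnames(scores)
  if (is.null(classes)) stop("classes (or score column names) required",
                             call. = FALSE)
  if (nrow(scores) != length(y_true))
    stop("scores rows must match labels", call. = FALSE)
  y_true <- as.character(y_true)
  aucs <- vapply(seq_along(classes), function(j) {
    pos <- y_true == as.character(classes[j])
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, j])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  names(aucs) <- as.character(classes)
  list(per_class = aucs, macro = mean(aucs, na.rm = TRUE))
}

#' Full metrics report for a stage prediction
#'
#' Convenience wrapper assembling [confusion_counts()], [basic_metrics()],
#' [kappa_score()], [kl_divergence()] of the predicted versus observed
#' class frequencies, and [roc_auc()] when probabilities are supplied.
#'
#' @param y_true,y_pred Label vectors.
#' @param probs Optional per-class probability matrix for ROC-AUC.
#' @param classes Class vocabulary.
#' @return A `metrics_report` list additionally carrying `kappa`,
#'   `kl_divergence` and (when `probs` given) `roc_auc`.
#' @export
evaluate_predictions <- function(y_true, y_pred, probs = NULL,
                                 classes = NULL) {
  if (is.null(classes))
    classes <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  counts <- confusion_counts(y_true, y_pred, classes)
  rep <- basic_metrics(counts)
  rep$counts <- counts
  rep$kappa <- kappa_score(y_true, y_pred)
  freq <- function(y) {
    tab <- table(factor(as.character(y), levels = as.character(classes)))
    (as.numeric(tab) + 0.5) / (length(y) + 0.5 * length(classes))
  }
  rep$kl_divergence <- kl_divergence(freq(y_true), freq(y_pred))
  if (!is.null(probs)) rep$roc_auc <- roc_auc(y_true, probs, classes)
  rep
}

#' Stratified k-fold cross-validation of the LSTM classifier
#'
#' Splits the objects into `k` folds preserving the class proportions
#' (each object appears in exactly one test fold), trains the configured
#' model on the remaining folds and evaluates on the held-out fold.
#'
#' @param ordinal An information/ordinal system with a decision attribute.
#' @param config An [lstm_config()]; its seed is offset per fold.
#' @param k Number of folds (>= 2); every class must have >= k members.
#' @param seed Integer seed for the fold assignment.
#' @return A list with `fold_accuracy` (length-k vector), `mean`, `sd`
#'   and `folds` (test-object ids per fold).
#' @export
stratified_kfold <- function(ordinal, config, k = 10, seed = 1) {
  stopifnot(inherits(ordinal, "information_system"), k >= 2)
  y <- ordinal$values[, ordinal$decision_attribute]
  classes <- sort(unique(y))
  sizes <- table(y)
  if (any(sizes < k))
    stop("stratification error: class ",
         names(sizes)[which.min(sizes)], " has fewer than k members",
         call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in classes) {
    rows <- sample(which(y == cl))
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }

  acc <- numeric(k)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold == f); train <- which(fold != f)
    sub <- replace_values(ordinal,
                          ordinal$values[train, , drop = FALSE])
    cfg <- config; cfg$seed <- config$seed + f
    model <- lstm_train(sub, cfg, split = c(1, 0))
    pred <- predict(model, ordinal$values[test, , drop = FALSE])
    acc[f] <- mean(pred == as.character(y[test]))
    folds[[f]] <- ordinal$object_ids[test]
  }
  list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
       folds = folds)
}
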