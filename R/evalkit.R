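## evalkit: stratified cross-validation, holdout evaluation, the weighted
## metric suite (accuracy, precision, recall, F-measure) and threshold-swept
## ROC / precision-recall curves. Curves are built from the pooled
## out-of-fold scores; metrics are class-weighted averages, matching the
## common reporting convention where weighted precision can differ from
## accuracy even on balanced data.

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members round-robin over
#' the folds, so per-class counts differ by at most one between folds.
#' Deterministic given `seed`.
#'
#' @param labels class labels.
#' @param k number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param seed integer seed.
#' @return Integer vector of fold ids in 1..k, one per instance.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  labels <- as_class_factor(labels)
  if (k < 2) stop_domain("stratified_folds: k must be >= 2")
  tab <- table(labels)
  if (any(tab < k)) {
    stop_domain("stratified_folds: class '%s' has %d member(s), fewer than k = %d",
                names(tab)[which(tab < k)[1]], min(tab), k)
  }
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

## ---- curves ----------------------------------------------------------------

# sweep distinct score thresholds (descending), grouping tied scores
sweep_thresholds <- function(scores, labels) {
  labels <- as_class_factor(labels)
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) {
    stop_domain("curve computation requires both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  list(tp = tp, fp = fp, n_pos = sum(pos), n_neg = sum(!pos),
       thresholds = s[grp_end])
}

#' ROC curve and area under it
#'
#' The curve is swept over all distinct score thresholds with tied scores
#' grouped; the area is the trapezoidal integral, which equals the normalized
#' Mann-Whitney U statistic (concordant pairs plus half the ties over
#' `n_pos * n_neg`).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels class labels.
#' @return List with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  sw <- sweep_thresholds(scores, labels)
  tpr <- c(0, sw$tp / sw$n_pos)
  fpr <- c(0, sw$fp / sw$n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, sw$thresholds)),
       auc = auc)
}

#' Precision-recall curve and area under it
#'
#' Step-wise integration (no linear interpolation): the area is
#' `sum over threshold groups of (recall_i - recall_{i-1}) * precision_i`.
#' With all scores tied the area equals the positive prevalence.
#'
#' @inheritParams roc_curve
#' @return List with `points` (data frame `recall`, `precision`, `threshold`)
#'   and `auprc`.
#' @export
pr_curve <- function(scores, labels) {
  sw <- sweep_thresholds(scores, labels)
  recall <- sw$tp / sw$n_pos
  precision <- sw$tp / (sw$tp + sw$fp)
  auprc <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = recall, precision = precision,
                           threshold = sw$thresholds),
       auprc = auprc)
}

## ---- confusion and weighted metrics ----------------------------------------

confusion_matrix <- function(truth, predicted) {
  truth <- as_class_factor(truth)
  predicted <- factor(as.character(predicted), levels = CLASS_LEVELS)
  table(truth = truth, predicted = predicted)
}

# class-weighted precision / recall / F from a 2x2 confusion matrix
weighted_metrics <- function(cm) {
  n <- sum(cm)
  support <- rowSums(cm)
  prec <- vapply(CLASS_LEVELS, function(cl) {
    denom <- sum(cm[, cl])
    if (denom == 0) 0 else cm[cl, cl] / denom
  }, numeric(1))
  rec <- vapply(CLASS_LEVELS, function(cl) {
    if (support[cl] == 0) 0 else cm[cl, cl] / support[cl]
  }, numeric(1))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  w <- support / n
  list(accuracy = sum(diag(cm)) / n,
       precision = sum(w * prec), recall = sum(w * rec),
       f_measure = sum(w * f1),
       per_class = data.frame(class = CLASS_LEVELS, precision = unname(prec),
                              recall = unname(rec), f_measure = unname(f1),
                              support = as.numeric(support)))
}

evaluation_report <- function(truth, scores, kind, seed = NA_integer_,
                              folds = NULL, fold_confusions = NULL) {
  predicted <- ifelse(scores > 0.5, "positive", "negative")
  cm <- confusion_matrix(truth, predicted)
  m <- weighted_metrics(cm)
  roc <- roc_curve(scores, truth)
  pr <- pr_curve(scores, truth)
  structure(list(kind = kind, seed = seed, folds = folds,
                 fold_confusions = fold_confusions,
                 confusion = cm, accuracy = m$accuracy,
                 precision = m$precision, recall = m$recall,
                 f_measure = m$f_measure, per_class = m$per_class,
                 roc = roc, pr = pr, auc = roc$auc, auprc = pr$auprc,
                 scores = scores, truth = as.character(truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s%s\n", x$kind,
              if (is.null(x$folds)) " (holdout)" else
                sprintf(" (%d-fold CV, seed %d)", max(x$folds), x$seed)))
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  F %.3f  AUC %.3f  AUPRC %.3f\n",
              x$accuracy, x$precision, x$recall, x$f_measure, x$auc, x$auprc))
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Trains on k-1 folds, scores the held-out fold, and pools the out-of-fold
#' scores into a single confusion matrix, metric set, and ROC/PR curve pair.
#'
#' @param table labeled `feature_table`.
#' @param kind classifier kind (see [fit_classifier()]).
#' @param k number of folds (default 5).
#' @param seed seed driving both the fold assignment and any stochastic
#'   learner.
#' @param ... passed to [fit_classifier()].
#' @return An `evaluation_report`.
#' @export
cross_validate <- function(table, kind = "bayesnet", k = 5, seed = 1, ...) {
  check_trainable(table)
  folds <- stratified_folds(table$labels, k = k, seed = seed)
  scores <- numeric(nrow(table$values))
  fold_cms <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- fit_classifier(kind, ft_subset(table, !test), seed = seed, ...)
    pred <- predict(model, ft_subset(table, test))
    scores[test] <- pred$prob_positive
    fold_cms[[f]] <- confusion_matrix(table$labels[test], pred$label)
  }
  evaluation_report(table$labels, scores, kind, seed = seed, folds = folds,
                    fold_confusions = fold_cms)
}

#' Evaluate a fitted model on an independent labeled set
#'
#' Single-pass scoring with the same metric suite as [cross_validate()], no
#' folding.
#'
#' @param model a `mirdiag_model`.
#' @param table labeled `feature_table` matching the model schema.
#' @return An `evaluation_report`.
#' @export
evaluate_holdout <- function(model, table) {
  if (is.null(table$labels)) stop_domain("evaluate_holdout requires labels")
  if (!nrow(table$values)) stop_domain("evaluate_holdout: empty table")
  pred <- predict(model, table)
  evaluation_report(table$labels, pred$prob_positive, model$kind)
}

#' Learning-curve experiment
#'
#' For each per-class training size, subsamples that many instances of each
#' class (nested subsets within a seed, so sizes are paired), runs
#' cross-validation, and averages accuracy over seeds.
#'
#' @param table labeled `feature_table`.
#' @param kind classifier kind.
#' @param sizes integer vector of per-class training counts.
#' @param seeds integer vector of seeds to average over.
#' @param k folds for the inner cross-validation.
#' @param ... passed to [fit_classifier()].
#' @return List with `runs` (data frame `size`, `seed`, `accuracy`, `auc`)
#'   and `summary` (mean and sd of accuracy per size).
#' @export
learning_curve <- function(table, kind = "bayesnet", sizes = c(20, 40),
                           seeds = 1:10, k = 5, ...) {
  check_trainable(table)
  tab <- table(table$labels)
  if (any(sizes > min(tab))) {
    stop_domain("learning_curve: size %d exceeds smallest class count %d",
                max(sizes), min(tab))
  }
  runs <- expand.grid(size = sizes, seed = seeds)
  runs$accuracy <- NA_real_
  runs$auc <- NA_real_
  for (s in seeds) {
    # one permutation per class per seed; size-s subset = its first s members,
    # so smaller training sets are nested inside larger ones (paired design)
    perm <- withr::with_seed(s, lapply(CLASS_LEVELS, function(cl)
      sample(which(table$labels == cl))))
    for (sz in sizes) {
      idx <- sort(unlist(lapply(perm, utils::head, sz)))
      rep_ <- cross_validate(ft_subset(table, idx), kind, k = k, seed = s, ...)
      row <- runs$size == sz & runs$seed == s
      runs$accuracy[row] <- rep_$accuracy
      runs$auc[row] <- rep_$auc
    }
  }
  summary <- do.call(rbind, lapply(sizes, function(sz) {
    a <- runs$accuracy[runs$size == sz]
    data.frame(size = sz, mean_accuracy = mean(a), sd_accuracy = stats::sd(a))
  }))
  list(runs = runs, summary = summary)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @param extra named list merged into the artifact (e.g. provenance fields).
#' @export
write_report_json <- function(report, path, extra = list()) {
  obj <- c(list(kind = report$kind, seed = report$seed,
                accuracy = report$accuracy, precision = report$precision,
                recall = report$recall, f_measure = report$f_measure,
                auc = report$auc, auprc = report$auprc,
                confusion = list(
                  tn = unname(report$confusion["negative", "negative"]),
                  fp = unname(report$confusion["negative", "positive"]),
                  fn = unname(report$confusion["positive", "negative"]),
                  tp = unname(report$confusion["positive", "positive"]))),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
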