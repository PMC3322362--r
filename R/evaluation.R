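# Performance evaluation: confusion-matrix metrics, ROC/AUC, stratified
# k-fold cross-validation and leave-one-out.

#' Classification metrics from confusion counts
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN);
#' accuracy = (TP+TN)/(TP+TN+FP+FN);
#' F-measure = 2 * precision * recall / (precision + recall).
#' A ratio with a zero denominator is undefined and reported as `NA`,
#' never silently coerced to 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A one-row tibble `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `precision`, `recall`, `f_measure`.
#' @export
#' @examples
#' compute_metrics(tp = 3, fp = 1, tn = 5, fn = 1)
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("confusion counts are all zero", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f_measure <- if (is.na(precision) || is.na(recall) ||
                   precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / total,
                 precision = precision, recall = recall,
                 f_measure = f_measure)
}

confusion_counts <- function(predicted, truth) {
  tibble::tibble(
    tp = sum(predicted == "positive" & truth == "positive"),
    fp = sum(predicted == "positive" & truth == "negative"),
    tn = sum(predicted == "negative" & truth == "negative"),
    fn = sum(predicted == "negative" & truth == "positive")
  )
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct scores, producing ROC
#' points from (0, 0) to (1, 1), and integrates by the trapezoidal rule.
#' Because tied scores are grouped into a single threshold step, the
#' trapezoidal area equals the Mann-Whitney concordance probability with
#' ties counted 1/2.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels `"positive"`/`"negative"` (or logical/0-1) truth labels;
#'   both classes must be present.
#' @return A list with `auc` and `roc`, a tibble of `threshold`, `fpr`,
#'   `tpr` (thresholds descending; the leading (0,0) point carries
#'   threshold `Inf`).
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) labels <- ifelse(labels > 0, "positive", "negative")
  pos <- labels == "positive"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # group tied scores into one threshold step
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(p)[last_of_group]
  cum_fp <- cumsum(!p)[last_of_group]
  roc <- tibble::tibble(
    threshold = c(Inf, s[last_of_group]),
    fpr = c(0, cum_fp / n_neg),
    tpr = c(0, cum_tp / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, roc = roc)
}

# stratified (or plain) fold assignment: returns an integer vector of fold
# ids in 1..k; stratified keeps class proportions balanced across folds
make_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  fold_id <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold_id <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  fold_id
}

#' k-fold cross-validation of a pair classifier
#'
#' Stratified folds under a seeded shuffle; every pair is scored exactly
#' once while held out; confusion counts are pooled over folds
#' (micro-averaged) and ROC/AUC computed on the pooled held-out scores.
#'
#' @param features Encoded feature tibble ([encode_dataset()]) with a
#'   `label` column containing both classes.
#' @param config A [model_config()].
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold shuffle (and, combined with the model
#'   seed, per-fold training); defaults to the config seed.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @return An object of class `rpi_eval`: pooled `metrics`, `auc`, `roc`
#'   points, per-fold metrics and the held-out `predictions` table.
#' @export
cross_validate <- function(features, config = model_config(), folds = 10L,
                           seed = config$seed, stratified = TRUE) {
  stopifnot(inherits(config, "model_config"), folds >= 2)
  y <- label_factor(features$label)
  if (length(unique(y)) < 2) {
    stop("cross-validation requires both classes", call. = FALSE)
  }
  if (stratified && folds > min(table(y))) {
    stop("fold count (", folds, ") exceeds the minority class size (",
         min(table(y)), ")", call. = FALSE)
  }
  fold_id <- with_seed(seed, make_folds(y, folds, stratified))
  n <- nrow(features)
  prob <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fold_config <- config
    fold_config$seed <- config$seed + f
    model <- train_model(features[tr, ], fold_config)
    prob[!tr] <- predict_proba(model, features[!tr, ])
  }
  predicted <- classify(prob, config$decision_threshold)
  truth <- as.character(y)

  per_fold <- purrr::map_dfr(seq_len(folds), function(f) {
    te <- fold_id == f
    cc <- confusion_counts(predicted[te], truth[te])
    dplyr::bind_cols(tibble::tibble(fold = f),
                     compute_metrics(cc$tp, cc$fp, cc$tn, cc$fn))
  })
  cc <- confusion_counts(predicted, truth)
  roc <- roc_auc(prob, truth)

  predictions <- tibble::tibble(
    protein_id = features[["protein_id"]] %||% NA_character_,
    rna_id = features[["rna_id"]] %||% NA_character_,
    fold = fold_id,
    label = truth,
    probability = prob,
    predicted = predicted
  )
  structure(list(metrics = compute_metrics(cc$tp, cc$fp, cc$tn, cc$fn),
                 auc = roc$auc,
                 roc = roc$roc,
                 per_fold = per_fold,
                 predictions = predictions,
                 folds = folds,
                 config = config,
                 seed = seed),
            class = "rpi_eval")
}

#' Leave-one-out cross-validation
#'
#' Equivalent to [cross_validate()] with as many folds as pairs and no
#' stratification constraint.
#'
#' @inheritParams cross_validate
#' @return An `rpi_eval` object (per-fold metrics omitted: single-pair
#'   folds have degenerate confusion tables).
#' @export
leave_one_out <- function(features, config = model_config(),
                          seed = config$seed) {
  n <- nrow(features)
  if (n < 2) stop("leave-one-out requires at least 2 pairs", call. = FALSE)
  out <- cross_validate(features, config, folds = n, seed = seed,
                        stratified = FALSE)
  out$per_fold <- NULL
  out
}

#' @export
print.rpi_eval <- function(x, ...) {
  m <- x$metrics
  cat("<rpi_eval> ", x$folds, "-fold CV, ", nrow(x$predictions),
      " pairs\n", sep = "")
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  F %.3f  AUC %.3f\n",
              m$accuracy, m$precision, m$recall, m$f_measure, x$auc))
  invisible(x)
}

#' @method tidy rpi_eval
#' @export
tidy.rpi_eval <- function(x, ...) {
  if (is.null(x$per_fold)) {
    stop("per-fold metrics unavailable (leave-one-out report)",
         call. = FALSE)
  }
  x$per_fold
}

#' @method glance rpi_eval
#' @export
glance.rpi_eval <- function(x, ...) {
  dplyr::bind_cols(x$metrics, tibble::tibble(auc = x$auc, folds = x$folds))
}

#' Plot the ROC curve of a cross-validation report
#'
#' @param object An `rpi_eval` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot rpi_eval
#' @export
autoplot.rpi_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}
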