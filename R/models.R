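# Classifier families over the 599-feature pair encoding.
#
# Random forest: 20 trees, 10 candidate features per split (the setting
# used for the 599-feature representation; 500 trees for large-scale
# comparisons). Probability = fraction of trees voting positive.
#
# SVM: C-SVC on a normalized polynomial kernel of order 2,
# K(x,y) = (x.y + 1)^2 / sqrt((x.x + 1)^2 (y.y + 1)^2), C = 1, tolerance
# 0.001, with a logistic (Platt) model fitted to 3-fold cross-validated
# margins to turn the SVM output into a probability.

MODEL_VERSION <- "rpinet-model-1"

#' Classifier configuration
#'
#' @param family `"random_forest"` or `"svm"`.
#' @param rf_trees Trees in the forest (default 20; use 500 for the
#'   large-ensemble setting).
#' @param rf_features_per_split Candidate features per split (default 10
#'   for the 599-feature encoding). `NULL` applies the fallback rule
#'   `floor(log2(n_features)) + 1`.
#' @param svm_c Soft-margin cost C.
#' @param svm_tolerance SMO convergence tolerance.
#' @param svm_kernel_degree Polynomial kernel order.
#' @param svm_epsilon Round-off constant carried for fidelity with the
#'   original SMO configuration; inert in this implementation.
#' @param calibrate Fit a logistic model to cross-validated SVM margins so
#'   predictions are probabilities (Platt scaling).
#' @param seed Integer seed governing all training randomness.
#' @param decision_threshold Probability at or above which a pair is called
#'   positive.
#' @return A list of class `model_config`.
#' @export
model_config <- function(family = c("random_forest", "svm"),
                         rf_trees = 20L,
                         rf_features_per_split = 10L,
                         svm_c = 1.0,
                         svm_tolerance = 0.0010,
                         svm_kernel_degree = 2L,
                         svm_epsilon = 1.0e-12,
                         calibrate = TRUE,
                         seed = 1L,
                         decision_threshold = 0.50) {
  family <- match.arg(family)
  stopifnot(rf_trees >= 1, svm_c > 0, svm_tolerance > 0,
            svm_kernel_degree >= 1,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(family = family,
                 rf_trees = as.integer(rf_trees),
                 rf_features_per_split =
                   if (is.null(rf_features_per_split)) NULL
                   else as.integer(rf_features_per_split),
                 svm_c = svm_c,
                 svm_tolerance = svm_tolerance,
                 svm_kernel_degree = as.integer(svm_kernel_degree),
                 svm_epsilon = svm_epsilon,
                 calibrate = isTRUE(calibrate),
                 seed = as.integer(seed),
                 decision_threshold = decision_threshold),
            class = "model_config")
}

#' Normalized polynomial kernel
#'
#' `K(x, y) = (x.y + 1)^degree`, normalized to
#' `K(x, y) / sqrt(K(x, x) K(y, y))`. Symmetric, equal to 1 at `x == y`,
#' and in (0, 1\] for non-negative feature vectors.
#'
#' @param x,y Equal-length numeric vectors.
#' @param degree Polynomial order (default 2).
#' @return The kernel value, a single number.
#' @export
#' @examples
#' normalized_poly_kernel(c(1, 0), c(0, 1))  # 1/4
normalized_poly_kernel <- function(x, y, degree = 2L) {
  if (length(x) != length(y)) {
    stop("kernel arguments must have equal length (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  kxy <- (sum(x * y) + 1)^degree
  kxx <- (sum(x * x) + 1)^degree
  kyy <- (sum(y * y) + 1)^degree
  kxy / sqrt(kxx * kyy)
}

# Gram matrix of the normalized polynomial kernel between the rows of two
# matrices; one crossprod, then row/column normalization
normalized_poly_gram <- function(a, b = a, degree = 2L) {
  k_ab <- (tcrossprod(a, b) + 1)^degree
  k_aa <- (rowSums(a * a) + 1)^degree
  k_bb <- (rowSums(b * b) + 1)^degree
  k_ab / sqrt(outer(k_aa, k_bb))
}

# split a feature tibble into the numeric matrix and the label factor
# (levels: negative, positive so that "positive" is the second class)
features_to_matrix <- function(features, schema = NULL) {
  meta <- intersect(c("protein_id", "rna_id", "label"), names(features))
  x <- as.matrix(features[, setdiff(names(features), meta)])
  if (!is.null(schema)) {
    if (!identical(colnames(x), schema)) {
      stop("feature columns do not match the model's feature schema",
           call. = FALSE)
    }
  }
  x
}

label_factor <- function(labels) {
  bad <- setdiff(unique(labels), c("positive", "negative"))
  if (length(bad)) {
    stop("training labels must be positive/negative; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(labels, levels = c("negative", "positive"))
}

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Train a classifier on an encoded pair dataset
#'
#' @param features A feature tibble from [encode_dataset()] (columns
#'   `protein_id`, `rna_id`, `label`, then the feature columns), or any
#'   tibble with a `label` column of `"positive"`/`"negative"` plus numeric
#'   features.
#' @param config A [model_config()].
#' @return An object of class `rpi_model`.
#' @export
train_model <- function(features, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  if (!"label" %in% names(features)) {
    stop("features must carry a `label` column", call. = FALSE)
  }
  y <- label_factor(features$label)
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  x <- features_to_matrix(features)
  schema <- colnames(x)

  fit <- if (config$family == "random_forest") {
    mtry <- config$rf_features_per_split
    if (is.null(mtry)) mtry <- floor(log2(ncol(x))) + 1L
    mtry <- min(mtry, ncol(x))
    with_seed(config$seed,
              randomForest::randomForest(x = x, y = y,
                                         ntree = config$rf_trees,
                                         mtry = mtry))
  } else {
    train_svm(x, y, config)
  }

  structure(list(version = MODEL_VERSION,
                 config = config,
                 feature_schema = schema,
                 fit = fit),
            class = "rpi_model")
}

# kernel-matrix SVM with Platt calibration on 3-fold CV margins
train_svm <- function(x, y, config) {
  gram <- normalized_poly_gram(x, degree = config$svm_kernel_degree)
  fit <- fit_oriented_ksvm(gram, y, config)
  calibration <- NULL
  if (config$calibrate) {
    folds <- with_seed(config$seed, make_folds(y, 3L, stratified = TRUE))
    margin <- rep(NA_real_, length(y))
    for (f in seq_len(3L)) {
      tr <- folds != f
      te <- folds == f
      sub_fit <- fit_oriented_ksvm(gram[tr, tr], y[tr], config)
      margin[te] <- svm_margin(sub_fit, gram[te, tr, drop = FALSE])
    }
    # separable folds push fitted probabilities to 0/1; the resulting
    # steep logistic is still a valid calibrator, so silence the warning
    calibration <- suppressWarnings(
      stats::glm(I(y == "positive") ~ margin,
                 family = stats::binomial(),
                 data = data.frame(margin = margin))
    )
    calibration <- calibration[c("coefficients")]
  }
  list(ksvm = fit$ksvm, flip = fit$flip, x_train = x,
       calibration = calibration)
}

# fit a kernel-matrix C-SVC and record the decision-value orientation:
# kernlab's sign convention depends on internal label coding, so it is
# established empirically from the training margins
fit_oriented_ksvm <- function(gram, y, config) {
  ksvm_fit <- kernlab::ksvm(kernlab::as.kernelMatrix(gram), y,
                            type = "C-svc", C = config$svm_c,
                            tol = config$svm_tolerance, prob.model = FALSE)
  d <- svm_margin_raw(ksvm_fit, gram)
  flip <- mean(d[y == "positive"]) < mean(d[y == "negative"])
  list(ksvm = ksvm_fit, flip = flip)
}

svm_margin_raw <- function(ksvm_fit, gram_new_train) {
  k <- kernlab::as.kernelMatrix(
    gram_new_train[, kernlab::SVindex(ksvm_fit), drop = FALSE])
  as.numeric(kernlab::predict(ksvm_fit, k, type = "decision"))
}

# decision value oriented so that larger = more "positive"
svm_margin <- function(fit, gram_new_train) {
  d <- svm_margin_raw(fit$ksvm, gram_new_train)
  if (fit$flip) -d else d
}

#' @export
print.rpi_model <- function(x, ...) {
  cat("<rpi_model> family =", x$config$family)
  if (x$config$family == "random_forest") {
    cat(" (", x$config$rf_trees, " trees)", sep = "")
  } else {
    cat(" (normalized poly kernel, order ", x$config$svm_kernel_degree,
        if (!is.null(x$fit$calibration)) ", Platt-calibrated" else "",
        ")", sep = "")
  }
  cat(";", length(x$feature_schema), "features\n")
  invisible(x)
}

#' Predict interaction probabilities
#'
#' For a random forest, the probability is the fraction of trees voting
#' positive; for a calibrated SVM, the logistic transform of the decision
#' margin. Vectorized over the rows of `features`.
#'
#' @param model An [rpi_model][train_model()].
#' @param features Feature tibble or matrix whose feature columns match the
#'   model's schema.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "rpi_model"))
  x <- if (is.matrix(features)) features else features_to_matrix(features)
  if (!identical(colnames(x), model$feature_schema)) {
    stop("feature columns do not match the model's feature schema",
         call. = FALSE)
  }
  if (model$config$family == "random_forest") {
    votes <- stats::predict(model$fit, x, type = "vote")
    return(unname(votes[, "positive"]))
  }
  gram_new <- normalized_poly_gram(x, model$fit$x_train,
                                   degree = model$config$svm_kernel_degree)
  margin <- svm_margin(model$fit, gram_new)
  if (is.null(model$fit$calibration)) {
    # uncalibrated: clamp the margin through a unit logistic for a bounded
    # score (documented as a score, not a calibrated probability)
    return(stats::plogis(margin))
  }
  co <- model$fit$calibration$coefficients
  stats::plogis(co[[1]] + co[[2]] * margin)
}

#' Threshold probabilities into labels
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param threshold Decision threshold; the comparison is inclusive, so a
#'   probability exactly at the threshold is called positive.
#' @return Character vector of `"positive"`/`"negative"`.
#' @export
classify <- function(probabilities, threshold = 0.50) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1, na.rm = TRUE))
  ifelse(probabilities >= threshold, "positive", "negative")
}

#' Rank features by random-forest importance
#'
#' @param model An [rpi_model][train_model()] with
#'   `family = "random_forest"`.
#' @return A tibble `feature`, `importance` (mean Gini impurity decrease),
#'   `rank`, covering every feature in the schema; ties broken by feature
#'   name.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "rpi_model"))
  if (model$config$family != "random_forest") {
    stop("feature importance is available for random_forest models only",
         call. = FALSE)
  }
  imp <- randomForest::importance(model$fit)[, "MeanDecreaseGini"]
  out <- tibble::tibble(feature = names(imp), importance = unname(imp))
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Greedy forward feature selection with a random-forest evaluator
#'
#' At each step, adds the feature whose inclusion maximizes k-fold
#' cross-validated accuracy of a random forest restricted to the selected
#' set; stops when `max_features` is reached or no candidate improves the
#' score.
#'
#' @param features Encoded feature tibble with a `label` column.
#' @param config A [model_config()] (`random_forest`).
#' @param max_features Maximum number of features to select.
#' @param folds Internal cross-validation folds (default 3).
#' @param candidates Optional character vector restricting the search space
#'   (useful: pre-screen by [feature_importance()] first); default all.
#' @return A list with `selected` (character vector, in selection order)
#'   and `trace` (tibble `step`, `feature`, `cv_accuracy`).
#' @export
greedy_forward_select <- function(features, config = model_config(),
                                  max_features = 10L, folds = 3L,
                                  candidates = NULL) {
  if (max_features < 1) stop("max_features must be >= 1", call. = FALSE)
  y <- label_factor(features$label)
  x <- features_to_matrix(features)
  if (is.null(candidates)) candidates <- colnames(x)
  fold_id <- with_seed(config$seed, make_folds(y, folds, stratified = TRUE))

  cv_acc <- function(cols) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      # a zero-variance subset carries no signal (and the forest grower
      # spins on it): score it as the majority-class baseline
      if (all(apply(x[tr, cols, drop = FALSE], 2,
                    function(col) length(unique(col))) == 1)) {
        majority <- names(which.max(table(y[tr])))
        correct <- correct + sum(y[!tr] == majority)
        next
      }
      m <- with_seed(
        config$seed,
        randomForest::randomForest(
          x = x[tr, cols, drop = FALSE], y = y[tr],
          ntree = config$rf_trees,
          mtry = min(length(cols),
                     config$rf_features_per_split %||% length(cols)))
      )
      pred <- stats::predict(m, x[!tr, cols, drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }

  selected <- character(0)
  trace <- tibble::tibble(step = integer(), feature = character(),
                          cv_accuracy = double())
  best_score <- -Inf
  while (length(selected) < max_features) {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    scores <- vapply(remaining, function(f) cv_acc(c(selected, f)),
                     double(1))
    step_best <- max(scores)
    if (step_best <= best_score) break
    pick <- remaining[which.max(scores)]
    selected <- c(selected, pick)
    best_score <- step_best
    trace <- dplyr::bind_rows(trace,
                              tibble::tibble(step = length(selected),
                                             feature = pick,
                                             cv_accuracy = step_best))
    if (best_score >= 1) break
  }
  list(selected = selected, trace = trace)
}

#' Persist / restore a trained model
#'
#' The on-disk artifact is a versioned single-file container; loading a
#' file with a different version tag (or one that is not an `rpi_model`)
#' fails rather than guessing.
#'
#' @param model An [rpi_model][train_model()].
#' @param path File path.
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rpi_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!inherits(obj, "rpi_model") || !identical(obj$version, MODEL_VERSION)) {
    stop("'", path, "' is not a compatible model artifact (expected ",
         MODEL_VERSION, ")", call. = FALSE)
  }
  obj
}

#' @method tidy rpi_model
#' @export
tidy.rpi_model <- function(x, ...) {
  if (x$config$family == "random_forest") return(feature_importance(x))
  tibble::tibble(
    term = c("intercept", "margin"),
    estimate = if (!is.null(x$fit$calibration)) {
      unname(x$fit$calibration$coefficients)
    } else {
      c(NA_real_, NA_real_)
    }
  )
}

#' @method glance rpi_model
#' @export
glance.rpi_model <- function(x, ...) {
  tibble::tibble(
    family = x$config$family,
    n_features = length(x$feature_schema),
    rf_trees = if (x$config$family == "random_forest") {
      x$config$rf_trees
    } else {
      NA_integer_
    },
    calibrated = x$config$family == "svm" && !is.null(x$fit$calibration),
    seed = x$config$seed
  )
}
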