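#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals members round-robin into k
#' folds, so per-fold class proportions differ from the global ones by at
#' most one sample. Deterministic given \code{seed}.
#'
#' @param labels class vector.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of k elements, each \code{list(train = idx, test = idx)};
#'   the test sets partition \code{seq_along(labels)}.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  tabs <- table(labels)
  small <- names(tabs)[tabs < k]
  if (length(small) > 0)
    stop("class '", small[1L], "' has fewer than k = ", k, " members",
         call. = FALSE)
  set.seed(seed)
  fold_of <- integer(length(labels))
  for (cl in names(tabs)) {
    members <- which(labels == cl)
    members <- members[sample.int(length(members))]
    fold_of[members] <- rep_len(seq_len(k), length(members))
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Accuracy, recall and F1 for binary predictions
#'
#' Disease (1) is the positive class. F1 is 0 when precision + recall = 0.
#'
#' @param truth 0/1 status vector.
#' @param predicted 0/1 predictions of equal length.
#' @return named numeric vector (accuracy, recall, f1).
#' @export
binary_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ", call. = FALSE)
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  tp <- sum(truth == 1L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  fp <- sum(truth == 0L & predicted == 1L)
  acc <- mean(truth == predicted)
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (is.na(rec)) NA_real_
        else if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, recall = rec, f1 = f1)
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random disease sample outscores a random
#' healthy one, ties counted one half (the rank-sum / concordance
#' definition). The ROC is the threshold sweep over the unique scores; with
#' tie-free scores its trapezoidal area equals the concordance AUC.
#'
#' @param truth 0/1 status vector containing both classes.
#' @param scores disease probabilities or scores (higher = more diseased).
#' @return list with \code{roc} (data.frame threshold, fpr, tpr, starting at
#'   (0,0) and ending at (1,1)) and \code{auc}.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  if (length(truth) != length(scores))
    stop("truth and scores lengths differ", call. = FALSE)
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tpr <- cumsum(t)[keep] / n1
  fpr <- cumsum(1 - t)[keep] / n0
  roc <- data.frame(threshold = c(Inf, s[keep]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  list(roc = roc, auc = auc)
}

## model zoo for cross-validation; each entry fits on (x, y) and returns a
## score function over new x. Baselines run at library defaults: they are a
## comparison harness, not part of the method.
fit_score_model <- function(spec, x, y, seed) {
  name <- if (is.list(spec)) spec$name else spec
  args <- if (is.list(spec)) spec[setdiff(names(spec), "name")] else list()
  set.seed(seed)
  switch(name,
    transformer = ,
    baseline = {
      cfgargs <- args$train %||% list()
      cfgargs$seed <- cfgargs$seed %||% seed
      cfg <- do.call(train_config, cfgargs)
      margs <- args$model %||% list()
      margs$use_dynamic_residual <- identical(name, "transformer")
      fit <- do.call(train_model,
                     c(list(x = x, labels = y, config = cfg), margs))
      function(newx) predict(fit$model, newx)[, "disease"]
    },
    lr = {
      n <- nrow(x)
      if (ncol(x) >= 2) {
        fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                              lambda = 1 / n, standardize = TRUE)
        function(newx) as.numeric(stats::predict(fit, newx,
                                                 type = "response"))
      } else {
        df <- data.frame(y = y, x)
        fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
        function(newx) stats::predict(fit, data.frame(newx),
                                      type = "response")
      }
    },
    svm = {
      requireNamespace("e1071")
      fit <- e1071::svm(x, factor(y), probability = TRUE)
      function(newx) {
        p <- attr(stats::predict(fit, newx, probability = TRUE),
                  "probabilities")
        p[, "1"]
      }
    },
    rf = {
      requireNamespace("randomForest")
      fit <- randomForest::randomForest(x, factor(y))
      function(newx) stats::predict(fit, newx, type = "prob")[, "1"]
    },
    gbt = {
      requireNamespace("xgboost")
      fit <- xgboost::xgboost(data = x, label = y, nrounds = 50,
                              objective = "binary:logistic",
                              nthread = 1, verbose = 0)
      function(newx) stats::predict(fit, newx)
    },
    knn = {
      requireNamespace("class")
      function(newx) {
        pr <- class::knn(x, newx, factor(y), k = 5, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      }
    },
    stop("unknown model spec: ", name, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated evaluation of a diagnosis model on one tissue
#'
#' Restricts the cohort to the given tissue and site panel, assigns
#' stratified folds once from \code{seed} (so model comparisons at the same
#' seed share folds), trains the requested model per fold, and reports
#' per-fold accuracy/recall/F1 plus the pooled ROC/AUC over all held-out
#' scores.
#'
#' @param matrix a \code{\link{methyl_matrix}}.
#' @param metadata sample metadata.
#' @param tissue tissue label (or NULL to use all samples).
#' @param sites site panel (default: all sites in the matrix).
#' @param model_spec model name or list with \code{name} plus arguments.
#'   Names: \code{"transformer"} (dynamic residual on),
#'   \code{"baseline"} (residual off), \code{"lr"}, \code{"svm"},
#'   \code{"rf"}, \code{"gbt"}, \code{"knn"}.
#' @param k folds (default 5).
#' @param seed integer seed for folds and model fits.
#' @return list (class \code{cv_metrics}) with \code{per_fold} (data.frame
#'   fold, accuracy, recall, f1), \code{mean_accuracy}, \code{mean_recall},
#'   \code{mean_f1}, \code{auc}, \code{roc}, \code{scores}, \code{truth},
#'   \code{seed}.
#' @export
crossval_evaluate <- function(matrix, metadata, tissue = NULL, sites = NULL,
                              model_spec = "transformer", k = 5L,
                              seed = 1L) {
  stopifnot(inherits(matrix, "methyl_matrix"))
  md <- metadata[match(rownames(matrix), metadata$sample_id), ]
  rows <- if (is.null(tissue)) seq_len(nrow(matrix))
          else which(md$tissue == tissue)
  if (length(rows) == 0) stop("no samples for tissue ", tissue, call. = FALSE)
  sites <- sites %||% colnames(matrix)
  x <- unclass(matrix)[rows, sites, drop = FALSE]
  y <- md$status[rows]
  if (length(unique(y)) < 2)
    stop("both statuses required for evaluation", call. = FALSE)

  folds <- stratified_kfold(y, k = k, seed = seed)
  per_fold <- data.frame()
  scores <- numeric(length(y)); truth <- y
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    scorer <- fit_score_model(model_spec, x[tr, , drop = FALSE], y[tr],
                              seed = seed + f)
    sc <- scorer(x[te, , drop = FALSE])
    scores[te] <- sc
    m <- binary_metrics(y[te], as.integer(sc >= 0.5))
    per_fold <- rbind(per_fold,
                      data.frame(fold = f, accuracy = m[["accuracy"]],
                                 recall = m[["recall"]], f1 = m[["f1"]]))
  }
  ra <- roc_auc(truth, scores)
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 mean_recall = mean(per_fold$recall),
                 mean_f1 = mean(per_fold$f1),
                 auc = ra$auc, roc = ra$roc,
                 scores = scores, truth = truth, seed = seed),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf(
    "cv_metrics: %d folds | accuracy %.3f | recall %.3f | F1 %.3f | AUC %.3f\n",
    nrow(x$per_fold), x$mean_accuracy, x$mean_recall, x$mean_f1, x$auc))
  invisible(x)
}
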