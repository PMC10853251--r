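## Five-fold cross-validated heart-failure classification with six standard
## models. Standardization is fitted on the training folds only.

CLASSIFIER_MODELS <- c("LR", "SVM", "KNN", "DTC", "RF", "XGBoost")

.std_fit <- function(x) {
  list(center = colMeans(x), scale = pmax(apply(x, 2, stats::sd), 1e-12))
}

.std_apply <- function(x, fit) {
  scale(x, center = fit$center, scale = fit$scale)
}

## stratified fold assignment: within each class, shuffled indices are dealt
## round-robin into k folds
.stratified_folds <- function(cls, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(cls))
  for (lv in levels(cls)) {
    idx <- sample(which(cls == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## hyperparameter grids tried on inner folds of the training data; an empty
## grid means library defaults are used directly
.model_grid <- function(model) {
  switch(model,
    SVM = lapply(c(0.1, 1, 10), function(C) list(cost = C)),
    KNN = lapply(c(3, 5, 7), function(k) list(k = k)),
    DTC = lapply(c(30, 5, 3), function(d) list(maxdepth = d)),
    list(list()))
}

## fit one model with given hyperparameters; returns P(CHF) for test rows
.fit_score_hp <- function(model, xtr, ytr, xte, seed, hp = list()) {
  pos <- "CHF"
  set.seed(as.integer(seed))
  switch(model,
    LR = {
      df <- data.frame(xtr, y = as.integer(ytr == pos))
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      suppressWarnings(
        stats::predict(fit, newdata = data.frame(xte), type = "response"))
    },
    SVM = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial",
                        cost = if (is.null(hp$cost)) 1 else hp$cost,
                        probability = TRUE)
      pr <- stats::predict(fit, xte, probability = TRUE)
      attr(pr, "probabilities")[, pos]
    },
    KNN = {
      k <- if (is.null(hp$k)) 5 else hp$k
      pr <- class::knn(xtr, xte, cl = ytr, k = k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == pos, p, 1 - p)
    },
    DTC = {
      ## unpruned tree with per-sample leaves: the defaults of the standard
      ## Python implementation the depth grid refers to
      df <- data.frame(xtr, y = ytr)
      ctl <- rpart::rpart.control(
        maxdepth = if (is.null(hp$maxdepth)) 30 else hp$maxdepth,
        minsplit = 2, minbucket = 1, cp = 0, xval = 0)
      fit <- rpart::rpart(y ~ ., data = df, method = "class", control = ctl)
      stats::predict(fit, newdata = data.frame(xte), type = "prob")[, pos]
    },
    RF = {
      fit <- randomForest::randomForest(xtr, ytr)
      stats::predict(fit, xte, type = "prob")[, pos]
    },
    XGBoost = {
      dtr <- xgboost::xgb.DMatrix(as.matrix(xtr),
                                  label = as.integer(ytr == pos))
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              max_depth = 3, eta = 0.3,
                                              nthread = 1, seed = seed),
                                data = dtr, nrounds = 100, verbose = 0)
      stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(xte)))
    },
    stop("configuration error: unknown model '", model, "'"))
}

## select hyperparameters by 3-fold cross-validation inside the training
## fold (accuracy criterion; first grid point wins ties)
.fit_score <- function(model, xtr, ytr, xte, seed) {
  grid <- .model_grid(model)
  hp <- grid[[1]]
  if (length(grid) > 1) {
    inner <- .stratified_folds(ytr, 3, seed)
    acc <- vapply(grid, function(g) {
      mean(vapply(1:3, function(fi) {
        tr <- inner != fi
        sc <- try(.fit_score_hp(model, xtr[tr, , drop = FALSE], ytr[tr],
                                xtr[!tr, , drop = FALSE], seed, g),
                  silent = TRUE)
        if (inherits(sc, "try-error")) return(0)
        mean((sc >= 0.5) == (ytr[!tr] == "CHF"))
      }, numeric(1)))
    }, numeric(1))
    hp <- grid[[which.max(acc)]]
  }
  .fit_score_hp(model, xtr, ytr, xte, seed, hp)
}

.fold_metrics <- function(y, score) {
  pos <- "CHF"
  pred <- ifelse(score >= 0.5, pos, "control")
  tp <- sum(pred == pos & y == pos)
  fp <- sum(pred == pos & y != pos)
  tn <- sum(pred != pos & y != pos)
  fn <- sum(pred != pos & y == pos)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = as.numeric(score),
    levels = c("control", pos), direction = "<", quiet = TRUE)))
  data.frame(accuracy = (tp + tn) / length(y),
             auc = auc,
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             f1 = 2 * tp / (2 * tp + fp + fn),
             tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Stratified k-fold cross-validated classification
#'
#' Evaluates one model (LR, SVM, KNN, DTC, RF or XGBoost) on a labeled
#' feature table with stratified k-fold cross-validation. Features are
#' standardized with the training-fold mean and sd only; where a model has
#' a small hyperparameter grid (SVM cost, KNN neighbours, tree depth and
#' split size), the value is selected by 3-fold cross-validation inside the
#' training fold. Sensitivity is the recall of the CHF class, specificity
#' the recall of the control class, and the AUC is computed from continuous
#' scores. Deterministic given the seed. With \code{grouped = TRUE}, folds
#' are formed over subjects (column \code{subject_id}) so repeated samples
#' of one subject never straddle the train/test split.
#'
#' @param table labeled feature table (see \code{\link{sampleFeatures}}).
#' @param model one of "LR", "SVM", "KNN", "DTC", "RF", "XGBoost".
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @param grouped form folds over subjects instead of rows.
#' @return a \linkS4class{CVMetrics}.
#' @export
crossvalClassify <- function(table, model = "LR", k = 5, seed = 1,
                             grouped = FALSE) {
  if (!model %in% CLASSIFIER_MODELS)
    stop("configuration error: unknown model '", model, "'")
  cls <- factor(table$class, levels = c("control", "CHF"))
  if (any(is.na(cls))) stop("configuration error: class must be control/CHF")
  if (min(table(cls)) < 10)
    stop("configuration error: need at least 10 rows per class")
  x <- as.matrix(table[, FEATURE_NAMES])
  if (any(!is.finite(x))) stop("configuration error: missing feature values")
  fold <- if (grouped) {
    if (is.null(table$subject_id))
      stop("configuration error: grouped CV needs a subject_id column")
    sid <- as.character(table$subject_id)
    subj <- !duplicated(sid)
    sf <- .stratified_folds(droplevels(cls[subj]), k, seed)
    sf[match(sid, sid[subj])]
  } else .stratified_folds(cls, k, seed)
  rows <- lapply(seq_len(k), function(fi) {
    tr <- fold != fi
    sc <- .std_fit(x[tr, , drop = FALSE])
    xtr <- .std_apply(x[tr, , drop = FALSE], sc)
    xte <- .std_apply(x[!tr, , drop = FALSE], sc)
    score <- .fit_score(model, xtr, cls[tr], xte, seed + fi)
    cbind(fold = fi, .fold_metrics(cls[!tr], score))
  })
  folds <- do.call(rbind, rows)
  mets <- c("accuracy", "auc", "sensitivity", "specificity", "f1")
  summ <- data.frame(metric = mets,
                     mean = vapply(folds[mets], mean, numeric(1)),
                     sd = vapply(folds[mets], stats::sd, numeric(1)),
                     row.names = NULL)
  new("CVMetrics", model = model, folds = folds, summary = summ,
      nFolds = as.integer(k), seed = as.integer(seed))
}

#' Cross-validate all six classifiers
#'
#' @param table labeled feature table.
#' @param models character vector of models (default all six).
#' @param k folds.
#' @param seed integer RNG seed.
#' @return data.frame with one row per model and columns
#'   \code{<metric>_mean}, \code{<metric>_sd}.
#' @export
evaluateModels <- function(table, models = CLASSIFIER_MODELS, k = 5,
                           seed = 1) {
  rows <- lapply(models, function(m) {
    cv <- crossvalClassify(table, m, k = k, seed = seed)
    s <- cv@summary
    out <- data.frame(model = m)
    for (i in seq_len(nrow(s))) {
      out[[paste0(s$metric[i], "_mean")]] <- s$mean[i]
      out[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
    }
    out
  })
  do.call(rbind, rows)
}
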