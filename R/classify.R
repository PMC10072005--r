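#' Classifier configuration
#'
#' @param costGrid candidate SVM regularization values for the inner grid
#'   search (default log-spaced 10^-2 .. 10^2).
#' @param innerFolds inner stratified CV folds (default 10).
#' @param nFeatures number of RFE-retained features per outer fold, or
#'   \code{"all"}.
#' @param rfeInFold run RFE inside each outer training fold (honest
#'   selection, default TRUE); FALSE ranks once on the full data.
#' @param seed master seed for fold splits.
#' @return Named list of class \code{"ClassifierConfig"}.
#' @export
classifierConfig <- function(costGrid = 10^seq(-2, 2, by = 1),
                             innerFolds = 10, nFeatures = "all",
                             rfeInFold = TRUE, seed = 1L) {
  stopifnot2(length(costGrid) >= 1 && all(costGrid > 0),
             "costGrid must be non-empty and positive")
  stopifnot2(innerFolds >= 2, "innerFolds must be at least 2")
  structure(list(costGrid = costGrid, innerFolds = as.integer(innerFolds),
                 nFeatures = nFeatures, rfeInFold = isTRUE(rfeInFold),
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

#' Standardize features on a training set
#'
#' Per-feature center and scale are estimated on \code{train} only and
#' applied to both tables (no leakage). Zero-variance features are
#' centered but not scaled, with a warning.
#'
#' @param train numeric matrix (subjects x features).
#' @param applyTo matrix to transform with the training statistics
#'   (default \code{train}).
#' @return List with \code{train}, \code{applied}, \code{center},
#'   \code{scale}.
#' @export
standardizeFeatures <- function(train, applyTo = train) {
  train <- as.matrix(train)
  applyTo <- as.matrix(applyTo)
  stopifnot2(nrow(train) >= 1, "train must be non-empty")
  center <- colMeans(train)
  scale <- apply(train, 2, sd)
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning("zero-variance feature(s) left unscaled: ",
            paste(colnames(train)[zero], collapse = ", "))
    scale[zero] <- 1
  }
  std <- function(m) sweep(sweep(m, 2, center), 2, scale, "/")
  list(train = std(train), applied = std(applyTo),
       center = center, scale = scale)
}

# One-versus-rest linear SVMs: one binary machine per class.
# Decision values are oriented so positive = the class.
.fitOvr <- function(X, y, cost) {
  classes <- levels(y)
  models <- lapply(classes, function(k) {
    yk <- factor(ifelse(y == k, "pos", "rest"), levels = c("pos", "rest"))
    e1071::svm(X, yk, kernel = "linear", cost = cost, scale = FALSE)
  })
  names(models) <- classes
  W <- vapply(models, function(m) {
    w <- crossprod(m$coefs, m$SV)[1, ]
    full <- setNames(numeric(ncol(X)), colnames(X))
    full[colnames(m$SV)] <- w
    full
  }, numeric(ncol(X)))
  list(models = models, classes = classes, W = W) # W: features x classes
}

.decisionOvr <- function(fit, X) {
  dv <- vapply(fit$models, function(m) {
    p <- predict(m, X, decision.values = TRUE)
    d <- attr(p, "decision.values")[, 1]
    # e1071 orients by its internal level order; flip if needed
    if (colnames(attr(p, "decision.values"))[1] != "pos/rest") -d else d
  }, numeric(nrow(X)))
  if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1)
  colnames(dv) <- fit$classes
  dv
}

.predictOvr <- function(fit, X) {
  dv <- .decisionOvr(fit, X)
  factor(fit$classes[max.col(dv, ties.method = "first")],
         levels = fit$classes)
}

#' Rank features by recursive feature elimination
#'
#' Fits a linear one-versus-rest SVM, aggregates \code{|w|} across the
#' class machines, removes the weakest feature and repeats. Returns the
#' ranking (best first) plus importance weights from the full-model fit,
#' normalized to sum to 1.
#'
#' @param X standardized feature matrix (subjects x features, >= 2).
#' @param y class factor with >= 2 levels present.
#' @param cost SVM cost used for the elimination fits.
#' @return List with \code{ranking} (feature names, best first),
#'   \code{importance} (named weights summing to 1) and
#'   \code{eliminated} (removal order, first removed first).
#' @export
rfeRank <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  stopifnot2(nlevels(y) >= 2, "need at least 2 classes")
  stopifnot2(ncol(X) >= 2, "need at least 2 features")
  stopifnot2(!is.null(colnames(X)), "X needs column names")
  full <- .fitOvr(X, y, cost)
  agg <- rowSums(abs(full$W))
  importance <- agg / sum(agg)
  active <- colnames(X)
  eliminated <- character(0)
  while (length(active) > 1) {
    fit <- .fitOvr(X[, active, drop = FALSE], y, cost)
    w <- rowSums(abs(fit$W))
    drop <- active[which.min(w)]
    eliminated <- c(eliminated, drop)
    active <- setdiff(active, drop)
  }
  list(ranking = rev(c(eliminated, active)), importance = importance,
       eliminated = eliminated)
}

# stratified fold assignment, deterministic under seed
.stratifiedFolds <- function(y, k, seed = NULL) {
  folds <- integer(length(y))
  withSeed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

.innerCvAccuracy <- function(X, y, cost, folds) {
  k <- max(folds)
  correct <- 0
  for (f in seq_len(k)) {
    te <- folds == f
    if (!any(te) || nlevels(droplevels(y[!te])) < nlevels(y)) next
    fit <- .fitOvr(X[!te, , drop = FALSE], y[!te], cost)
    correct <- correct + sum(.predictOvr(fit, X[te, , drop = FALSE]) ==
                               y[te])
  }
  correct / length(y)
}

#' Nested leave-one-out cross-validated OVR SVM classification
#'
#' Outer loop: leave-one-out over subjects. Per outer fold,
#' standardization, recursive feature elimination and the inner
#' stratified k-fold grid search over the cost grid all run on the
#' training subjects only; the best inner parameter is refit on the full
#' training fold and the held-out subject's prediction and decision
#' values are recorded. Pooled predictions give the confusion matrix and
#' accuracy; pooled decision values give per-class ROC curves.
#'
#' @param X feature matrix (subjects x features) with column names.
#' @param y class labels (factor or character).
#' @param config a \code{\link{classifierConfig}}.
#' @return A \linkS4class{ClassificationResult}.
#' @export
nestedCV <- function(X, y, config = classifierConfig()) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  n <- nrow(X)
  stopifnot2(n == length(y), "X rows and y must match")
  stopifnot2(all(table(y) >= 2),
             paste("every class needs >= 2 subjects so each training fold",
                   "contains all classes"))
  stopifnot2(n >= config$innerFolds + 1, "too few subjects for the inner CV")
  classes <- levels(y)
  nf <- if (identical(config$nFeatures, "all")) ncol(X)
        else min(as.integer(config$nFeatures), ncol(X))
  globalRank <- NULL
  pred <- factor(rep(classes[1], n), levels = classes)
  dvAll <- matrix(NA_real_, n, length(classes),
                  dimnames = list(rownames(X), classes))
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < length(classes))
      stop("class ", setdiff(classes, levels(ytr)),
           " absent from training fold ", i, call. = FALSE)
    sc <- suppressWarnings(
      standardizeFeatures(X[tr, , drop = FALSE], X[i, , drop = FALSE]))
    feats <- colnames(X)
    if (config$rfeInFold && ncol(X) >= 2 && nf < ncol(X)) {
      rk <- rfeRank(sc$train, ytr, cost = 1)
      feats <- rk$ranking[seq_len(nf)]
    } else if (nf < ncol(X)) {
      if (is.null(globalRank))
        globalRank <- rfeRank(
          suppressWarnings(standardizeFeatures(X)$train), y, cost = 1)
      feats <- globalRank$ranking[seq_len(nf)]
    }
    Xtr <- sc$train[, feats, drop = FALSE]
    innerFolds <- .stratifiedFolds(ytr, config$innerFolds,
                                   seed = deriveSeed(config$seed, 31, i))
    acc <- vapply(config$costGrid, function(cst)
      .innerCvAccuracy(Xtr, ytr, cst, innerFolds), numeric(1))
    best <- config$costGrid[which.max(acc)] # ties: smallest cost wins
    fit <- .fitOvr(Xtr, ytr, best)
    Xte <- sc$applied[, feats, drop = FALSE]
    pred[i] <- .predictOvr(fit, Xte)
    dvAll[i, ] <- .decisionOvr(fit, Xte)[1, ]
    folds[[i]] <- list(heldOut = i, cost = best, features = feats,
                       center = sc$center, scale = sc$scale,
                       innerAccuracy = setNames(acc,
                                                format(config$costGrid)))
  }
  confusion <- table(true = y, predicted = pred)
  confusion <- unclass(confusion)
  accuracy <- sum(diag(confusion)) / n
  roc <- lapply(classes, function(k)
    rocCurve(dvAll[, k], y == k))
  names(roc) <- classes
  rates <- ovrRates(confusion)
  rates$rocAUC <- vapply(roc, function(r) r$auc, numeric(1))[rates$class]
  fullRank <- rfeRank(suppressWarnings(standardizeFeatures(X)$train), y,
                      cost = 1)
  ranking <- data.frame(feature = fullRank$ranking,
                        rank = seq_along(fullRank$ranking),
                        weight = fullRank$importance[fullRank$ranking],
                        stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  new("ClassificationResult", confusion = confusion, accuracy = accuracy,
      perClass = rates, roc = roc, folds = folds, ranking = ranking,
      decisionValues = dvAll)
}

#' Per-class sensitivity and specificity (one-versus-rest)
#'
#' For class k, sensitivity = TP / (TP + FN) and specificity =
#' TN / (TN + FP) with all other classes pooled as "rest".
#'
#' @param x a \linkS4class{ClassificationResult} or a confusion matrix
#'   (rows = true, columns = predicted).
#' @return data.frame with class, sensitivity, specificity; rates are
#'   \code{NA} for empty classes.
#' @export
ovrRates <- function(x) {
  cm <- if (is(x, "ClassificationResult")) x@confusion else as.matrix(x)
  classes <- rownames(cm)
  total <- sum(cm)
  out <- do.call(rbind, lapply(classes, function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    data.frame(class = k,
               sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
               specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' ROC curve and area from decision values
#'
#' True- and false-positive rates at every distinct decision-value
#' threshold (ties move the curve diagonally in one simultaneous step);
#' the area is the trapezoidal integral.
#'
#' @param scores numeric decision values (larger = more positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return List with \code{points} (data.frame threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot2(length(scores) == length(labels),
             "scores and labels must match")
  stopifnot2(any(labels) && any(!labels),
             "both classes must be present in labels")
  np <- sum(labels)
  nn <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s)) # tied scores collapse into one step
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(threshold = s[last], fpr = fp[last] / nn,
                    tpr = tp[last] / np)
  pts <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), pts)
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}

#' Accuracy as a function of the retained RFE feature count
#'
#' Reruns the nested CV for every retained-feature count, mirroring the
#' common "best first k features" selection sweep.
#'
#' @param X,y as in \code{\link{nestedCV}}.
#' @param config a \code{\link{classifierConfig}} (its nFeatures is
#'   overridden).
#' @param counts feature counts to evaluate (default 1..ncol(X)).
#' @return data.frame with nFeatures and accuracy.
#' @export
featureCountSweep <- function(X, y, config = classifierConfig(),
                              counts = seq_len(ncol(X))) {
  do.call(rbind, lapply(counts, function(k) {
    cfg <- config
    cfg$nFeatures <- k
    res <- nestedCV(X, y, cfg)
    data.frame(nFeatures = k, accuracy = res@accuracy)
  }))
}
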