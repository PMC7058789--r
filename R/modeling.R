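#' Stratified training/validation split
#'
#' Within each class, a seeded random permutation assigns the first
#' `round(ratio * n_class)` patients to training and the remainder to
#' validation. With class sizes 76/40/48 at ratio 0.7 this yields training
#' counts 53/28/34.
#'
#' @param labels class labels (coerced to factor).
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed.
#' @return An object of class `split_plan`: integer index vectors `train`
#'   and `validation`, plus `ratio` and `seed`.
#' @export
stratified_split <- function(labels, ratio = 0.7, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < 2))
    stop("invalid stratum: every class needs at least 2 members",
         call. = FALSE)
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]", call. = FALSE)
  train <- integer(0)
  withr::with_seed(sub_seed(seed, 404L), {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n_tr <- round(ratio * length(idx))
      train <- c(train, idx[seq_len(n_tr)])
    }
  })
  train <- sort(train)
  structure(list(train = train,
                 validation = setdiff(seq_along(labels), train),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_plan")
}

#' Evaluate a classifier kernel
#'
#' Reference formulas for the four SVM kernels considered: linear
#' `<x, y>`; gaussian `exp(-sigma ||x - y||^2)`; laplacian
#' `exp(-sigma ||x - y||)` (Euclidean distance in the exponent); ANOVA RBF
#' `(sum_i exp(-sigma (x_i - y_i)^2))^d`.
#'
#' @param kind one of `"linear"`, `"gaussian"`, `"laplacian"`, `"anova_rbf"`.
#' @param params list with `sigma` and (for ANOVA RBF) `degree`.
#' @param x,y numeric vectors of equal length.
#' @return Kernel value (scalar).
#' @export
kernel_eval <- function(kind, params = list(sigma = 1, degree = 1), x, y) {
  kind <- match.arg(kind, c("linear", "gaussian", "laplacian", "anova_rbf"))
  if (length(x) != length(y) || !all(is.finite(c(x, y))))
    stop("invalid argument: x and y must be finite vectors of equal length",
         call. = FALSE)
  s <- if (is.null(params$sigma)) 1 else params$sigma
  d <- if (is.null(params$degree)) 1 else params$degree
  switch(kind,
    linear = sum(x * y),
    gaussian = exp(-s * sum((x - y)^2)),
    laplacian = exp(-s * sqrt(sum((x - y)^2))),
    anova_rbf = sum(exp(-s * (x - y)^2))^d)
}

# Median heuristic for the kernel scale on standardized training data.
median_heuristic <- function(x, kind) {
  dmat <- as.numeric(dist(x))
  dmat <- dmat[dmat > 0]
  med <- if (length(dmat)) median(dmat) else 1
  switch(kind,
    gaussian = 1 / (2 * med^2),
    laplacian = 1 / med,
    anova_rbf = 1 / (2 * med^2 / max(ncol(x), 1)),
    1)
}

kernlab_kernel <- function(kind, sigma, degree) {
  switch(kind,
    linear = kernlab::vanilladot(),
    gaussian = kernlab::rbfdot(sigma = sigma),
    laplacian = kernlab::laplacedot(sigma = sigma),
    anova_rbf = kernlab::anovadot(sigma = sigma, degree = degree))
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

standardize_apply <- function(x, st) {
  sweep(sweep(as.matrix(x), 2, st$mean, "-"), 2, st$sd, "/")
}

#' Train a multi-class soft-margin kernel SVM
#'
#' Features are z-scored on training statistics; the multi-class problem is
#' solved by one-vs-one pairwise classifiers with majority voting
#' (kernlab's C-svc). The kernel scale defaults to the median heuristic on
#' the standardized training distances.
#'
#' @param x numeric feature matrix or data.frame (rows = patients).
#' @param y class labels.
#' @param kernel kernel family (see [kernel_eval()]).
#' @param C soft-margin cost.
#' @param sigma kernel scale; `NULL` for the median heuristic.
#' @param degree ANOVA RBF degree.
#' @param seed integer seed.
#' @return An object of class `pcn_svm` usable with [predict()].
#' @export
train_svm <- function(x, y, kernel = "gaussian", C = 1, sigma = NULL,
                      degree = 1, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least two classes", call. = FALSE)
  x <- as.matrix(x)
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  kernel <- match.arg(kernel, c("linear", "gaussian", "laplacian",
                                "anova_rbf"))
  if (is.null(sigma)) sigma <- median_heuristic(xs, kernel)
  fit <- withr::with_seed(sub_seed(seed, 505L),
    kernlab::ksvm(xs, y, type = "C-svc", C = C,
                  kernel = kernlab_kernel(kernel, sigma, degree),
                  scaled = FALSE))
  structure(list(fit = fit, standardize = st, levels = levels(y),
                 kernel = kernel, C = C, sigma = sigma, degree = degree),
            class = "pcn_svm")
}

#' @export
predict.pcn_svm <- function(object, newdata, ...) {
  xs <- standardize_apply(as.matrix(newdata), object$standardize)
  factor(as.character(kernlab::predict(object$fit, xs)),
         levels = object$levels)
}

#' Train a random forest classifier
#'
#' Bagged trees with `mtry` candidate variables per split (features enter
#' unscaled, as is standard for trees). The fitted object retains the
#' out-of-bag error trajectory for every tree count `1..n_trees` (overall
#' and per class), which is how the stabilization of the forest with
#' growing tree number is assessed.
#'
#' @param x feature matrix or data.frame.
#' @param y class labels.
#' @param n_trees number of trees (default 3000).
#' @param mtry candidate variables per split (default 2).
#' @param seed integer seed.
#' @return An object of class `pcn_rf` with fields `fit` and `oob`
#'   (error-rate matrix, one row per tree count).
#' @export
train_rf <- function(x, y, n_trees = 3000L, mtry = 2L, seed = 1L) {
  y <- droplevels(as.factor(y))
  x <- as.data.frame(x)
  if (mtry > ncol(x))
    stop("invalid argument: mtry exceeds the feature count", call. = FALSE)
  fit <- withr::with_seed(sub_seed(seed, 606L),
    randomForest::randomForest(x = x, y = y, ntree = as.integer(n_trees),
                               mtry = as.integer(mtry)))
  structure(list(fit = fit, oob = fit$err.rate, levels = levels(y)),
            class = "pcn_rf")
}

#' @export
predict.pcn_rf <- function(object, newdata, ...) {
  factor(as.character(predict(object$fit, as.data.frame(newdata))),
         levels = object$levels)
}

#' Train a single-hidden-layer neural network
#'
#' Softmax output, cross-entropy loss with an L2 weight-decay penalty,
#' quasi-Newton (BFGS) optimization from small seeded random
#' initializations. Several restarts are run and the fit with the best
#' training loss is kept. Features are z-scored on training statistics.
#'
#' @param x feature matrix or data.frame.
#' @param y class labels.
#' @param hidden_units hidden-layer size.
#' @param weight_decay L2 penalty weight.
#' @param seed integer seed.
#' @param restarts number of random restarts (default 5).
#' @return An object of class `pcn_ann`.
#' @export
train_ann <- function(x, y, hidden_units = 14L, weight_decay = 1,
                      seed = 1L, restarts = 5L) {
  y <- droplevels(as.factor(y))
  x <- as.matrix(x)
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  target <- nnet::class.ind(y)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- withr::with_seed(sub_seed(seed, 707L, r),
      nnet::nnet(xs, target, size = as.integer(hidden_units),
                 decay = weight_decay, softmax = TRUE, maxit = 500,
                 trace = FALSE, rang = 0.5,
                 MaxNWts = 10000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(list(fit = best, standardize = st, levels = levels(y),
                 hidden_units = hidden_units, weight_decay = weight_decay),
            class = "pcn_ann")
}

#' @export
predict.pcn_ann <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- standardize_apply(as.matrix(newdata), object$standardize)
  pr <- predict(object$fit, xs)
  if (type == "prob") return(pr)
  factor(object$levels[max.col(pr, ties.method = "first")],
         levels = object$levels)
}

#' Default hyperparameter grids
#'
#' SVM: four kernel families crossed with integer costs 1..10. RF: tree
#' counts up to 3000 crossed with 2 or 3 candidate variables per split.
#' ANN: 10..15 hidden units crossed with weight decays
#' 2, 1, 0.5, 0.25, 0.125, 0.0625.
#'
#' @return A `data.frame`, one row per grid point.
#' @export
svm_grid <- function() {
  expand.grid(kernel = c("linear", "laplacian", "gaussian", "anova_rbf"),
              C = 1:10, stringsAsFactors = FALSE)
}

#' @rdname svm_grid
#' @export
rf_grid <- function() {
  expand.grid(n_trees = c(500L, 1000L, 2000L, 3000L), mtry = c(2L, 3L))
}

#' @rdname svm_grid
#' @export
ann_grid <- function() {
  expand.grid(hidden_units = 10:15,
              weight_decay = c(2, 1, 0.5, 0.25, 0.125, 0.0625))
}

stratified_folds <- function(y, folds, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  withr::with_seed(sub_seed(seed, 808L), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
  })
  if (any(table(fold, y) == 0))
    stop("stratification failure: a fold is missing a class", call. = FALSE)
  fold
}

#' Cross-validated grid selection
#'
#' SVM and ANN grid points are scored by stratified k-fold cross-validation
#' (mean misclassification error for SVM, mean accuracy for ANN); RF grid
#' points are scored by the forest's own out-of-bag error on the full
#' training data. The winner is the best score with a deterministic
#' tie-break: smallest C, then kernel order as listed, for SVM; fewest
#' hidden units then smallest decay for ANN; fewest trees then smallest
#' mtry for RF.
#'
#' @param model_kind `"svm"`, `"rf"` or `"ann"`.
#' @param grid `data.frame` of candidate settings (defaults to the standard
#'   grid of the model kind).
#' @param x,y training features and labels.
#' @param folds number of CV folds (default 4).
#' @param seed integer seed.
#' @return List with `best` (one-row `data.frame`) and `cv_table` (the grid
#'   with a `score` column; error for SVM/RF, accuracy for ANN).
#' @export
cv_select <- function(model_kind, grid = NULL, x, y, folds = 4L, seed = 1L) {
  model_kind <- match.arg(model_kind, c("svm", "rf", "ann"))
  if (is.null(grid))
    grid <- switch(model_kind, svm = svm_grid(), rf = rf_grid(),
                   ann = ann_grid())
  y <- droplevels(as.factor(y))
  x <- as.matrix(x)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  score <- numeric(nrow(grid))
  if (model_kind == "rf") {
    for (g in seq_len(nrow(grid))) {
      fit <- train_rf(x, y, n_trees = grid$n_trees[g], mtry = grid$mtry[g],
                      seed = sub_seed(seed, 909L, g))
      score[g] <- fit$oob[nrow(fit$oob), "OOB"]
    }
  } else {
    fold <- stratified_folds(y, folds, seed)
    fold_scores <- matrix(NA_real_, nrow(grid), folds)
    for (g in seq_len(nrow(grid))) {
      for (f in seq_len(folds)) {
        tr <- fold != f
        model <- if (model_kind == "svm") {
          train_svm(x[tr, , drop = FALSE], y[tr],
                    kernel = grid$kernel[g], C = grid$C[g],
                    seed = sub_seed(seed, 909L, g, f))
        } else {
          train_ann(x[tr, , drop = FALSE], y[tr],
                    hidden_units = grid$hidden_units[g],
                    weight_decay = grid$weight_decay[g],
                    seed = sub_seed(seed, 909L, g, f), restarts = 3L)
        }
        pred <- predict(model, x[!tr, , drop = FALSE])
        acc <- mean(pred == y[!tr])
        fold_scores[g, f] <- if (model_kind == "svm") 1 - acc else acc
      }
      score[g] <- mean(fold_scores[g, ])
    }
  }
  cv_table <- if (model_kind == "rf") cbind(grid, score = score) else {
    colnames(fold_scores) <- paste0("fold", seq_len(folds))
    cbind(grid, fold_scores, score = score)
  }
  ord <- switch(model_kind,
    svm = order(score, grid$C,
                match(grid$kernel, c("linear", "laplacian", "gaussian",
                                     "anova_rbf"))),
    ann = order(-score, grid$hidden_units, grid$weight_decay),
    rf = order(score, grid$n_trees, grid$mtry))
  best <- grid[ord[1], , drop = FALSE]
  rownames(best) <- NULL
  list(best = best, cv_table = cv_table)
}
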