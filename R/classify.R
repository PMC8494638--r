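#' Cell-type classification from morphoelectric features
#'
#' Trains a classifier to predict the transcriptomic type from a feature
#' matrix over repeated stratified 70/30 train/test splits, reporting the
#' mean and standard deviation of the class-balanced accuracy (mean
#' per-class recall on the test set), a representative confusion matrix from
#' the first split, and a shuffled-label chance baseline from the same
#' splitting procedure. Features are standardized (train-set mean/sd) inside
#' every split. A split in which a class is absent from the test set is
#' resampled.
#'
#' Models: `"logistic"` (ridge-regularized multinomial logistic regression,
#' the default) or `"forest"` (bagged CART with random feature subsampling;
#' `n_trees` defaults to 600 but should be reduced for quick runs).
#'
#' @param x Cells x features matrix (no missing values).
#' @param labels Class label per cell; >= 2 classes with >= 5 cells each.
#' @param model `"logistic"` or `"forest"`.
#' @param n_splits Number of random splits (1000 by convention; reduce for
#'   tests).
#' @param train_frac Training fraction per split.
#' @param seed Integer seed; the full accuracy vector is reproducible.
#' @param shuffle Also compute the shuffled-label baseline.
#' @param n_trees,max_depth,mtry Forest hyper-parameters.
#' @return List: `accuracy`, `accuracy_sd`, `accuracies` (per split),
#'   `baseline`, `baseline_sd`, `baseline_accuracies`, `confusion`
#'   (representative split), `model`.
#' @export
classify_types <- function(x, labels, model = c("logistic", "forest"),
                           n_splits = 1000, train_frac = 0.7, seed = 1L,
                           shuffle = TRUE, n_trees = 600, max_depth = 6,
                           mtry = NULL) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- factor(labels)
  if (nlevels(y) < 2 || any(table(y) < 5))
    stop("need >= 2 classes with >= 5 cells each")
  set.seed(seed)
  run <- function(yy) {
    accs <- numeric(n_splits)
    confusion <- NULL
    for (s in seq_len(n_splits)) {
      repeat {
        tr <- .stratified_train(yy, train_frac)
        if (nlevels(droplevels(yy[-tr])) == nlevels(yy) &&
            nlevels(droplevels(yy[tr])) == nlevels(yy)) break
      }
      mu <- colMeans(x[tr, , drop = FALSE])
      sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(x[-tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      pred <- if (model == "logistic")
        .fit_predict_logistic(xtr, yy[tr], xte)
      else .fit_predict_forest(xtr, yy[tr], xte, n_trees, max_depth, mtry)
      accs[s] <- .balanced_accuracy(yy[-tr], pred)
      if (s == 1)
        confusion <- table(truth = yy[-tr],
                           predicted = factor(pred, levels = levels(yy)))
    }
    list(accs = accs, confusion = confusion)
  }
  obs <- run(y)
  base <- NULL
  if (shuffle) base <- run(sample(y))
  list(accuracy = mean(obs$accs), accuracy_sd = stats::sd(obs$accs),
       accuracies = obs$accs,
       baseline = if (shuffle) mean(base$accs) else NA_real_,
       baseline_sd = if (shuffle) stats::sd(base$accs) else NA_real_,
       baseline_accuracies = if (shuffle) base$accs else numeric(0),
       confusion = obs$confusion, model = model)
}

.stratified_train <- function(y, frac) {
  unlist(lapply(split(seq_along(y), y), function(ix) {
    n_tr <- max(1L, round(frac * length(ix)))
    if (n_tr >= length(ix)) n_tr <- length(ix) - 1L
    sample(ix, n_tr)
  }), use.names = FALSE)
}

.balanced_accuracy <- function(truth, pred) {
  mean(vapply(levels(droplevels(truth)), function(cl)
    mean(pred[truth == cl] == cl), 0))
}

.fit_predict_logistic <- function(xtr, ytr, xte) {
  # a short decreasing path is more robust than a single lambda in glmnet
  fit <- glmnet::glmnet(xtr, ytr, family = "multinomial", alpha = 0,
                        lambda = c(0.1, 0.01, 1e-3))
  as.character(stats::predict(fit, xte, s = 1e-3, type = "class")[, 1])
}

# --- minimal bagged CART (gini) with per-node random feature subsampling ---

.fit_predict_forest <- function(xtr, ytr, xte, n_trees, max_depth, mtry) {
  p <- ncol(xtr)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  lv <- levels(ytr)
  votes <- matrix(0L, nrow(xte), length(lv))
  n <- nrow(xtr)
  for (b in seq_len(n_trees)) {
    boot <- sample(n, n, replace = TRUE)
    tree <- .grow_tree(xtr[boot, , drop = FALSE], as.integer(ytr[boot]),
                       length(lv), mtry, max_depth)
    pred <- .predict_tree(tree, xte)
    votes[cbind(seq_len(nrow(xte)), pred)] <-
      votes[cbind(seq_len(nrow(xte)), pred)] + 1L
  }
  lv[max.col(votes, ties.method = "first")]
}

.gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

.grow_tree <- function(x, y, n_class, mtry, depth_left, min_node = 5L) {
  n <- length(y)
  counts <- tabulate(y, n_class)
  maj <- which.max(counts)
  if (depth_left == 0 || n < min_node || .gini(counts) == 0)
    return(list(leaf = TRUE, class = maj))
  feats <- sample(ncol(x), mtry)
  best <- NULL; best_imp <- .gini(counts) - 1e-9
  for (j in feats) {
    xv <- x[, j]
    cuts <- stats::quantile(xv, probs = seq(0.1, 0.9, by = 0.1),
                            names = FALSE, type = 1)
    for (cut in unique(cuts)) {
      left <- xv <= cut
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      imp <- (nl * .gini(tabulate(y[left], n_class)) +
                (n - nl) * .gini(tabulate(y[!left], n_class))) / n
      if (imp < best_imp) { best_imp <- imp; best <- list(j = j, cut = cut) }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, class = maj))
  left <- x[, best$j] <= best$cut
  list(leaf = FALSE, j = best$j, cut = best$cut,
       left = .grow_tree(x[left, , drop = FALSE], y[left], n_class, mtry,
                         depth_left - 1L, min_node),
       right = .grow_tree(x[!left, , drop = FALSE], y[!left], n_class, mtry,
                          depth_left - 1L, min_node))
}

.predict_tree <- function(tree, x) {
  out <- integer(nrow(x))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    go_left <- x[idx, node$j] <= node$cut
    rec(node$left, idx[go_left])
    rec(node$right, idx[!go_left])
  }
  rec(tree, seq_len(nrow(x)))
  out
}
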