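#' k-nearest-neighbour prediction
#'
#' Plain brute-force k-NN under Euclidean distance.  Distance ties are
#' broken by lower training-sample index; a tied majority vote (possible
#' only for even `k`) goes to class 1, i.e. `classes[1]`.
#'
#' @param train numeric matrix, training samples as rows, features as
#'   columns.
#' @param train_labels character vector of training labels.
#' @param test numeric matrix of test samples (same feature count).
#' @param k neighbour count, `1 <= k <= nrow(train)`.
#' @param metric distance name; only `"euclidean"` is supported.
#' @param classes ordered pair fixing which label is class 1 for vote
#'   tie-breaking; defaults to order of first appearance in `train_labels`.
#' @return character vector of predicted labels, one per test row.
#' @export
knn_predict <- function(train, train_labels, test, k = 5L,
                        metric = "euclidean", classes = NULL) {
  if (!identical(metric, "euclidean")) {
    stop("unsupported metric: ", metric, call. = FALSE)
  }
  train <- as.matrix(train)
  test <- as.matrix(test)
  if (nrow(train) == 0L || ncol(train) == 0L) {
    stop("empty training set or zero features", call. = FALSE)
  }
  if (ncol(test) != ncol(train)) {
    stop("train and test feature counts differ", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L || k > nrow(train)) {
    stop(sprintf("k must be in [1, %d], got %d", nrow(train), k),
         call. = FALSE)
  }
  if (is.null(classes)) classes <- unique(train_labels)
  d2 <- sq_dist(test, train)
  is1 <- train_labels == classes[1L]
  preds <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    nn <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    votes1 <- sum(is1[nn])
    preds[i] <- if (votes1 >= k - votes1) classes[1L] else classes[2L]
  }
  preds
}

# squared Euclidean distances, test rows x train rows
sq_dist <- function(test, train) {
  d2 <- outer(rowSums(test^2), rowSums(train^2), "+") -
    2 * tcrossprod(test, train)
  d2[d2 < 0] <- 0   # numerical noise
  d2
}

#' Classification accuracy as a percentage
#'
#' `(c / t) * 100` where `c` counts correctly classified samples and `t` is
#' the total.
#'
#' @param predicted,truth equal-length nonempty label vectors.
#' @return a percentage in `[0, 100]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    stop("predicted and truth must be equal-length nonempty vectors",
         call. = FALSE)
  }
  100 * mean(predicted == truth)
}

# Stratified fold assignment: within each class, samples are shuffled once
# (seeded) and dealt round-robin, so class proportions are preserved per
# fold.  Returns an integer fold id per sample.
stratified_folds <- function(labels, n_folds, seed, class_names) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  smallest <- min(table(labels))
  if (n_folds > smallest) {
    stop(sprintf("n_folds (%d) exceeds the smaller class size (%d)",
                 n_folds, smallest), call. = FALSE)
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in class_names) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Cross-validated k-NN accuracy of a gene subset
#'
#' The wrapper fitness function: stratified n-fold cross-validation of a
#' k-NN classifier restricted to the given genes, returning per-fold and
#' mean accuracy.  The empty gene set is a defined degenerate case with
#' fitness 0 and no cross-validation run.
#'
#' @param ds an [expression_dataset()].
#' @param genes integer vector of gene row indices to classify with (may be
#'   empty).
#' @param k neighbour count.
#' @param n_folds number of folds, at most the smaller class size.
#' @param seed integer seed controlling the one-time sample shuffle.
#' @param scale `"none"` (default) or `"zscore"` for per-gene
#'   standardization using training-fold statistics.
#' @return a `FitnessResult` list: `fold_accuracies`, `mean_accuracy`,
#'   `c_total`, `t_total`.
#' @export
cv_fitness <- function(ds, genes, k = 5L, n_folds = 5L, seed = 1L,
                       scale = c("none", "zscore")) {
  scale <- match.arg(scale)
  genes <- as.integer(genes)
  if (length(genes) == 0L) {
    return(structure(list(fold_accuracies = numeric(0), mean_accuracy = 0,
                          c_total = 0L, t_total = 0L),
                     class = "FitnessResult"))
  }
  folds <- stratified_folds(ds$labels, n_folds, seed, ds$class_names)
  x <- t(ds$matrix[genes, , drop = FALSE])   # samples x features
  fold_acc <- numeric(n_folds)
  c_total <- 0L
  t_total <- 0L
  for (f in seq_len(n_folds)) {
    te <- folds == f
    tr_x <- x[!te, , drop = FALSE]
    te_x <- x[te, , drop = FALSE]
    if (scale == "zscore") {
      mu <- colMeans(tr_x)
      sdv <- apply(tr_x, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      tr_x <- sweep(sweep(tr_x, 2L, mu), 2L, sdv, "/")
      te_x <- sweep(sweep(te_x, 2L, mu), 2L, sdv, "/")
    }
    pred <- knn_predict(tr_x, ds$labels[!te], te_x, k = k,
                        classes = ds$class_names)
    correct <- sum(pred == ds$labels[te])
    fold_acc[f] <- 100 * correct / sum(te)
    c_total <- c_total + correct
    t_total <- t_total + sum(te)
  }
  structure(list(fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 c_total = c_total, t_total = t_total),
            class = "FitnessResult")
}

#' Build a fast, cached CV-fitness closure over a candidate gene set
#'
#' Precomputes the sample-by-feature view of the top-m candidate genes and a
#' single seeded stratified fold assignment, then returns a function mapping
#' an optimizer position vector in `[0,1]^m` to mean CV accuracy.  Results
#' are cached by decoded mask, since many positions decode to the same gene
#' subset.
#'
#' @param ds an [expression_dataset()].
#' @param candidate_genes integer vector of gene row indices (the top-m
#'   set); its length fixes the optimizer dimension.
#' @param k,n_folds,seed,scale as in [cv_fitness()].
#' @return a function `position -> fitness` with attribute
#'   `"candidate_genes"`.
#' @export
make_cv_fitness <- function(ds, candidate_genes, k = 5L, n_folds = 5L,
                            seed = 1L, scale = c("none", "zscore")) {
  scale <- match.arg(scale)
  candidate_genes <- as.integer(candidate_genes)
  folds <- stratified_folds(ds$labels, n_folds, seed, ds$class_names)
  x <- t(ds$matrix[candidate_genes, , drop = FALSE])
  labels <- ds$labels
  classes <- ds$class_names
  fold_idx <- lapply(seq_len(n_folds), function(f) {
    list(tr = which(folds != f), te = which(folds == f))
  })
  cache <- new.env(parent = emptyenv())
  fn <- function(position) {
    mask <- decode(position)
    if (length(mask) == 0L) return(0)
    key <- paste(mask, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    sub <- x[, mask, drop = FALSE]
    acc <- 0
    for (fi in fold_idx) {
      tr_x <- sub[fi$tr, , drop = FALSE]
      te_x <- sub[fi$te, , drop = FALSE]
      if (scale == "zscore") {
        mu <- colMeans(tr_x)
        sdv <- apply(tr_x, 2L, stats::sd)
        sdv[sdv == 0] <- 1
        tr_x <- sweep(sweep(tr_x, 2L, mu), 2L, sdv, "/")
        te_x <- sweep(sweep(te_x, 2L, mu), 2L, sdv, "/")
      }
      pred <- knn_predict(tr_x, labels[fi$tr], te_x, k = k,
                          classes = classes)
      acc <- acc + 100 * mean(pred == labels[fi$te])
    }
    val <- acc / length(fold_idx)
    cache[[key]] <- val
    val
  }
  attr(fn, "candidate_genes") <- candidate_genes
  fn
}
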