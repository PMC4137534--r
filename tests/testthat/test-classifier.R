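test_that("knn_predict: zero-distance, hand-worked example, limit cases", {
  train <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(5, 5))
  lab <- c("A", "A", "B", "B", "B")

  # test point identical to a training point at k = 1
  expect_equal(knn_predict(train, lab, rbind(c(1, 0)), k = 1), "B")

  # hand-worked: neighbours of (0, 0.4) at k = 3 are A, A, B
  expect_equal(knn_predict(train, lab, rbind(c(0, 0.4)), k = 3), "A")

  # k = training size -> global majority everywhere
  expect_equal(knn_predict(train, lab, rbind(c(0, 0), c(9, 9)), k = 5),
               c("B", "B"))

  expect_error(knn_predict(train[0, , drop = FALSE], character(0),
                           rbind(c(0, 0)), k = 1), "empty")
  expect_error(knn_predict(train, lab, rbind(c(0, 0)), k = 6), "k must be")
  expect_error(knn_predict(train, lab, rbind(c(0, 0, 0)), k = 1),
               "feature counts")
})

test_that("knn tie rules: distance ties by index, vote ties to class 1", {
  # two training points equidistant from the test point
  train <- rbind(c(1, 0), c(-1, 0))
  expect_equal(knn_predict(train, c("B", "A"), rbind(c(0, 0)), k = 1), "B")
  # even k, split vote -> class 1 (first appearing label)
  train2 <- rbind(c(0, 1), c(0, -1))
  expect_equal(knn_predict(train2, c("A", "B"), rbind(c(0, 0)), k = 2), "A")
  expect_equal(knn_predict(train2, c("A", "B"), rbind(c(0, 0)), k = 2,
                           classes = c("B", "A")), "B")
})

test_that("knn_predict matches the brute-force oracle on random instances", {
  for (s in 1:30) {
    set.seed(s)
    n_tr <- sample(5:30, 1)
    n_te <- sample(1:10, 1)
    p <- sample(1:10, 1)
    train <- matrix(rnorm(n_tr * p), n_tr, p)
    test <- matrix(rnorm(n_te * p), n_te, p)
    lab <- sample(c("A", "B"), n_tr, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1] <- setdiff(c("A", "B"), lab[2])
    k <- sample(1:n_tr, 1)
    cls <- unique(lab)
    expect_identical(
      unname(knn_predict(train, lab, test, k = k, classes = cls)),
      unname(oracle_knn(train, lab, test, k, cls)))
  }
})

test_that("duplicating a training sample never changes a k = 1 prediction", {
  set.seed(99)
  train <- matrix(rnorm(40), 10, 4)
  lab <- rep(c("A", "B"), 5)
  test <- matrix(rnorm(20), 5, 4)
  base <- knn_predict(train, lab, test, k = 1, classes = c("A", "B"))
  for (i in c(1, 7, 10)) {
    aug <- knn_predict(rbind(train, train[i, ]), c(lab, lab[i]), test,
                       k = 1, classes = c("A", "B"))
    expect_identical(aug, base)
  }
})

test_that("accuracy is (c/t) * 100", {
  expect_equal(accuracy(c(rep("A", 19), "B"), rep("A", 20)), 95.0)
  expect_equal(accuracy(rep("A", 5), rep("B", 5)), 0.0)
  expect_equal(accuracy(rep("A", 5), rep("A", 5)), 100.0)
  expect_error(accuracy(character(0), character(0)), "nonempty")
})

test_that("cv_fitness: degenerate empty mask, perfect gene, determinism", {
  sep <- separable_dataset()
  fr0 <- cv_fitness(sep$ds, integer(0))
  expect_equal(fr0$mean_accuracy, 0)
  expect_equal(fr0$t_total, 0L)

  fr <- cv_fitness(sep$ds, sep$gene, k = 5, n_folds = 5, seed = 1)
  expect_equal(fr$mean_accuracy, 100.0)
  expect_equal(fr$c_total, 20L)
  expect_equal(fr$t_total, 20L)
  expect_equal(fr$mean_accuracy, mean(fr$fold_accuracies))

  fr2 <- cv_fitness(sep$ds, sep$gene, k = 5, n_folds = 5, seed = 1)
  expect_identical(fr, fr2)

  expect_error(cv_fitness(sep$ds, sep$gene, n_folds = 11), "exceeds")
})

test_that("folds are stratified and exhaustive", {
  ds <- random_dataset(17, max_per_class = 10L)
  folds <- swarmselect:::stratified_folds(ds$labels, 2, seed = 4,
                                          class_names = ds$class_names)
  expect_equal(sort(unique(folds)), 1:2)
  for (f in 1:2) {
    expect_true(all(table(ds$labels[folds == f]) >= 1))
  }
  expect_length(folds, length(ds$labels))
})

test_that("permuted labels give chance-level CV accuracy", {
  g <- generate_dataset(synthetic_spec(100, 30, 30, 10, seed = 2))
  ds <- g$dataset
  for (s in 1:20) {
    set.seed(s)
    perm <- unclass(ds)
    perm$labels <- sample(ds$labels)
    class(perm) <- "ExpressionDataset"
    fr <- cv_fitness(perm, seq_len(100), k = 5, n_folds = 5, seed = s)
    expect_gte(fr$mean_accuracy, 20)
    expect_lte(fr$mean_accuracy, 80)
  }
})

test_that("make_cv_fitness matches cv_fitness and caches by mask", {
  g <- generate_dataset(synthetic_spec(50, 10, 10, 5, seed = 6))
  ds <- g$dataset
  cand <- rank_genes(ds, "t_statistic", 10)$top_m
  fn <- make_cv_fitness(ds, cand, k = 3, n_folds = 3, seed = 9)
  pos <- c(0.9, 0.2, 0.8, 0.1, 0.6, 0.4, 0.3, 0.7, 0.2, 0.55)
  mask <- decode(pos)
  expect_equal(fn(pos),
               cv_fitness(ds, cand[mask], k = 3, n_folds = 3,
                          seed = 9)$mean_accuracy)
  expect_equal(fn(pos + c(0.05, rep(0, 9))), fn(pos))  # same decoded mask
  expect_equal(fn(rep(0, 10)), 0)                      # empty mask
})
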