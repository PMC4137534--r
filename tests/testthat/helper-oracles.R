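# Shared fixtures and independent oracles.  The oracles deliberately use
# different code paths from the package (stats::t.test, per-gene loops,
# explicit all-pairs distance scans) so agreement is meaningful.

tiny_dataset <- function() {
  # 3 genes x 6 samples; gene 1 is the hand-worked example
  m <- rbind(c(1, 2, 3, 4, 5, 6),
             c(2, 2, 2, 2, 2, 2),
             c(5, 1, 3, 0, 4, 2))
  expression_dataset(m, paste0("g", 1:3), paste0("s", 1:6),
                     c("A", "A", "A", "B", "B", "B"))
}

random_dataset <- function(seed, max_genes = 50L, max_per_class = 10L) {
  set.seed(seed)
  ng <- sample(2:max_genes, 1L)
  n1 <- sample(2:max_per_class, 1L)
  n2 <- sample(2:max_per_class, 1L)
  m <- matrix(rnorm(ng * (n1 + n2), sd = runif(1, 0.5, 3)), nrow = ng)
  expression_dataset(m, paste0("g", seq_len(ng)),
                     paste0("s", seq_len(n1 + n2)),
                     c(rep("normal", n1), rep("tumor", n2)))
}

swap_classes <- function(ds) {
  expression_dataset(ds$matrix, ds$gene_ids, ds$sample_ids, ds$labels,
                     class_names = rev(ds$class_names))
}

# per-gene Welch t via stats::t.test (identical formula: unpooled variances)
oracle_t <- function(ds) {
  in1 <- ds$labels == ds$class_names[1L]
  vapply(seq_len(nrow(ds$matrix)), function(g) {
    unname(stats::t.test(ds$matrix[g, in1], ds$matrix[g, !in1])$statistic)
  }, numeric(1L))
}

oracle_snr_sum <- function(ds) {
  in1 <- ds$labels == ds$class_names[1L]
  vapply(seq_len(nrow(ds$matrix)), function(g) {
    x <- ds$matrix[g, in1]; y <- ds$matrix[g, !in1]
    (mean(x) - mean(y)) / (stats::sd(x) + stats::sd(y))
  }, numeric(1L))
}

oracle_f <- function(ds) {
  in1 <- ds$labels == ds$class_names[1L]
  vapply(seq_len(nrow(ds$matrix)), function(g) {
    stats::var(ds$matrix[g, in1]) / stats::var(ds$matrix[g, !in1])
  }, numeric(1L))
}

# brute-force k-NN: explicit per-pair distance loop with the stated tie
# rules (distance ties -> lower training index; vote ties -> classes[1])
oracle_knn <- function(train, train_labels, test, k, classes) {
  apply(test, 1L, function(p) {
    d <- vapply(seq_len(nrow(train)), function(j) {
      sqrt(sum((p - train[j, ])^2))
    }, numeric(1L))
    ord <- order(d, seq_along(d))
    nb <- train_labels[ord[seq_len(k)]]
    n1 <- sum(nb == classes[1L])
    if (n1 >= length(nb) - n1) classes[1L] else classes[2L]
  })
}

# Hill estimator of the tail index from the top k order statistics
hill_index <- function(x, k) {
  xs <- sort(abs(x), decreasing = TRUE)
  1 / mean(log(xs[seq_len(k)] / xs[k + 1L]))
}

# a dataset where one planted gene separates the classes perfectly
separable_dataset <- function(n_genes = 20L, n1 = 10L, n2 = 10L, seed = 3L) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n1 + n2)), nrow = n_genes)
  m[1L, ] <- c(rnorm(n1, mean = 0, sd = 0.1), rnorm(n2, mean = 10, sd = 0.1))
  list(ds = expression_dataset(m, paste0("g", seq_len(n_genes)),
                               paste0("s", seq_len(n1 + n2)),
                               c(rep("normal", n1), rep("tumor", n2))),
       gene = 1L)
}
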