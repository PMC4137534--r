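#' Per-gene, per-class summary statistics
#'
#' Computes, for every gene, the class means, variances (with the unbiased
#' n - 1 denominator) and standard deviations, plus the class sample sizes.
#' Class 1 is `ds$class_names[1]` ("normal" by convention), class 2 the
#' other; all three filter statistics are defined on these quantities.
#'
#' @param ds an [expression_dataset()] with two classes of >= 2 samples each.
#' @return a `ClassStats` list with per-gene vectors `x1bar`, `x2bar`, `v1`,
#'   `v2`, `s1`, `s2` and scalars `n1`, `n2`.
#' @export
class_statistics <- function(ds) {
  problems <- validate_dataset(ds)
  if (length(problems) > 0L) {
    stop("invalid dataset:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  in1 <- ds$labels == ds$class_names[1L]
  in2 <- ds$labels == ds$class_names[2L]
  n1 <- sum(in1)
  n2 <- sum(in2)
  if (n1 < 2L || n2 < 2L) {
    stop("each class needs >= 2 samples for a variance", call. = FALSE)
  }
  m1 <- ds$matrix[, in1, drop = FALSE]
  m2 <- ds$matrix[, in2, drop = FALSE]
  x1bar <- rowMeans(m1)
  x2bar <- rowMeans(m2)
  v1 <- rowSums((m1 - x1bar)^2) / (n1 - 1)
  v2 <- rowSums((m2 - x2bar)^2) / (n2 - 1)
  structure(
    list(x1bar = x1bar, x2bar = x2bar, v1 = v1, v2 = v2,
         s1 = sqrt(v1), s2 = sqrt(v2), n1 = n1, n2 = n2,
         gene_ids = ds$gene_ids),
    class = "ClassStats")
}

#' Per-gene two-sample T-statistic
#'
#' `t = (x1bar - x2bar) / sqrt(v1/n1 + v2/n2)` — the unequal-variance
#' (Welch-style) standardized mean difference.  Degenerate genes where both
#' class variances are zero get score 0 when the means are equal, and a
#' signed infinite sentinel (ranked first under the absolute-value ordering)
#' when they differ; both cases emit a warning.
#'
#' @param stats a `ClassStats` from [class_statistics()].
#' @return numeric vector of per-gene scores.
#' @export
t_statistic <- function(stats) {
  diff <- stats$x1bar - stats$x2bar
  den <- sqrt(stats$v1 / stats$n1 + stats$v2 / stats$n2)
  t <- diff / den
  zero_den <- den == 0
  if (any(zero_den)) {
    t[zero_den & diff == 0] <- 0
    t[zero_den & diff != 0] <- sign(diff[zero_den & diff != 0]) * Inf
    warning(sprintf("%d gene(s) with zero pooled variance in t_statistic",
                    sum(zero_den)), call. = FALSE)
  }
  t
}

#' Per-gene signal-to-noise ratio (prediction strength)
#'
#' In the default `"sum"` mode, `PS = (x1bar - x2bar) / (s1 + s2)` — the
#' Golub-style signal-to-noise ratio.  `"paper"` mode uses the difference of
#' standard deviations in the denominator, `s1 - s2`, exactly as some texts
#' print it; that form divides by zero whenever the class SDs coincide, so
#' its absolute denominator is floored at `eps` and each activation of the
#' guard is reported via a warning.
#'
#' @param stats a `ClassStats` from [class_statistics()].
#' @param denominator_mode `"sum"` (default) or `"paper"`.
#' @param eps floor applied to `|denominator|` (default `1e-12`).
#' @return numeric vector of per-gene scores.
#' @export
snr <- function(stats, denominator_mode = c("sum", "paper"), eps = 1e-12) {
  denominator_mode <- match.arg(denominator_mode)
  diff <- stats$x1bar - stats$x2bar
  den <- if (denominator_mode == "sum") stats$s1 + stats$s2
         else stats$s1 - stats$s2
  guarded <- abs(den) < eps
  if (any(guarded)) {
    warning(sprintf("snr: |denominator| < %g for %d gene(s); floored at %g",
                    eps, sum(guarded), eps), call. = FALSE)
    den[guarded] <- eps * ifelse(den[guarded] < 0, -1, 1)
  }
  ps <- diff / den
  ps[diff == 0] <- 0
  ps
}

#' Per-gene F-test value (between-class variance ratio)
#'
#' `F = v1 / v2`, used purely as a ranking score (smallest first under the
#' default ordering).  A zero class-2 variance with positive class-1
#' variance yields an infinite sentinel that can never enter the top-m under
#' ascending selection; two zero variances yield 1 with a warning.
#'
#' @param stats a `ClassStats` from [class_statistics()].
#' @return numeric vector of per-gene scores.
#' @export
f_test <- function(stats) {
  f <- stats$v1 / stats$v2
  both0 <- stats$v1 == 0 & stats$v2 == 0
  only2 <- stats$v2 == 0 & stats$v1 > 0
  if (any(both0)) {
    f[both0] <- 1
    warning(sprintf("f_test: %d gene(s) with both class variances zero; score 1",
                    sum(both0)), call. = FALSE)
  }
  f[only2] <- Inf
  f
}

#' Select the top-m genes under a ranking statistic
#'
#' T-statistic and signal-to-noise scores are ranked by descending absolute
#' value by default (both signs discriminate); the F-test is ranked
#' ascending, smallest ratio first.  Ties are broken by lower gene index.
#'
#' @param scores numeric vector of per-gene scores.
#' @param method `"t_statistic"`, `"snr"` or `"f_test"`.
#' @param m number of genes to select, `1 <= m <= length(scores)`.
#' @param signed if `TRUE`, rank t/snr by signed score descending instead of
#'   by absolute value.
#' @param f_rank `"ascending"` (default, ratio smallest-first) or
#'   `"two_tailed"` (smallest deviation of the ratio from 1, measured on the
#'   log scale).
#' @return a `GeneRanking` list: `method`, `scores`, `ranked_indices` (a
#'   permutation of gene indices in selection order), `top_m`, `m`.
#' @export
top_m <- function(scores, method = c("t_statistic", "snr", "f_test"), m,
                  signed = FALSE, f_rank = c("ascending", "two_tailed")) {
  method <- match.arg(method)
  f_rank <- match.arg(f_rank)
  m <- as.integer(m)
  if (m < 1L || m > length(scores)) {
    stop(sprintf("m must be in [1, %d], got %d", length(scores), m),
         call. = FALSE)
  }
  key <- if (method == "f_test") {
    if (f_rank == "ascending") scores else abs(log(scores))
  } else {
    if (signed) -scores else -abs(scores)
  }
  ord <- order(key, seq_along(key))   # stable; ties to lower index
  structure(
    list(method = method, scores = scores, ranked_indices = ord,
         top_m = ord[seq_len(m)], m = m),
    class = "GeneRanking")
}

#' Rank a dataset's genes and select the top m
#'
#' Convenience wrapper: [class_statistics()] then the chosen statistic then
#' [top_m()].  The ranking is computed on the full dataset before any
#' cross-validation, matching the two-stage filter/wrapper pipeline; the
#' selection bias this induces is a property of the method, not corrected
#' here.
#'
#' @inheritParams top_m
#' @param ds an [expression_dataset()].
#' @param snr_denominator passed to [snr()] when `method = "snr"`.
#' @return a `GeneRanking` with an additional `gene_ids` field.
#' @export
rank_genes <- function(ds, method = c("t_statistic", "snr", "f_test"), m,
                       signed = FALSE,
                       f_rank = c("ascending", "two_tailed"),
                       snr_denominator = c("sum", "paper")) {
  method <- match.arg(method)
  st <- class_statistics(ds)
  scores <- switch(method,
    t_statistic = t_statistic(st),
    snr = snr(st, denominator_mode = match.arg(snr_denominator)),
    f_test = f_test(st))
  rk <- top_m(scores, method, m, signed = signed,
              f_rank = match.arg(f_rank))
  rk$gene_ids <- ds$gene_ids
  rk
}

#' Tabulate a gene ranking as a data frame
#'
#' One row per gene in selection order: gene_id, method, score, rank.
#' Suitable for writing with [utils::write.table()].
#'
#' @param ranking a `GeneRanking` carrying `gene_ids` (see [rank_genes()]).
#' @return a data frame.
#' @export
ranking_report <- function(ranking) {
  idx <- ranking$ranked_indices
  data.frame(
    gene_id = ranking$gene_ids[idx],
    method = ranking$method,
    score = ranking$scores[idx],
    rank = seq_along(idx),
    stringsAsFactors = FALSE)
}
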