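#' Specification of a synthetic microarray-like dataset
#'
#' Describes the stated world the generator emulates: thousands of genes,
#' tens of samples, two (possibly imbalanced) classes, and a small planted
#' set of differentially expressed genes on an i.i.d. normal background.
#'
#' @param n_genes number of genes (rows).
#' @param n1 class-1 ("normal") sample count, at least 2.
#' @param n2 class-2 ("tumor") sample count, at least 2.
#' @param n_informative number of planted differentially expressed genes.
#' @param effect_size between-class mean shift delta, in units of `noise_sd`.
#'   The shift is applied to class 2, so planted genes have negative
#'   T-statistic and signal-to-noise scores by construction.
#' @param noise_sd within-class standard deviation, must be positive.
#' @param seed integer seed; the same spec always generates the same data.
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_genes, n1, n2, n_informative,
                           effect_size = 2, noise_sd = 1, seed = 1L) {
  spec <- structure(
    list(n_genes = as.integer(n_genes), n1 = as.integer(n1),
         n2 = as.integer(n2), n_informative = as.integer(n_informative),
         effect_size = as.numeric(effect_size),
         noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
    class = "SyntheticSpec")
  if (spec$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (spec$n_informative < 0L || spec$n_informative > spec$n_genes) {
    stop("n_informative must be in [0, n_genes]", call. = FALSE)
  }
  if (spec$n1 < 2L || spec$n2 < 2L) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  if (!is.finite(spec$noise_sd) || spec$noise_sd <= 0) {
    stop("noise_sd must be positive", call. = FALSE)
  }
  spec
}

#' Generate a microarray-like dataset with planted informative genes
#'
#' Background model: every gene gets a baseline mean drawn once from
#' N(7, 2^2) (a log2-intensity-like scale), and expression values are
#' baseline plus i.i.d. N(0, noise_sd^2) noise, identical across classes.
#' A random subset of `n_informative` genes is planted: their class-2
#' ("tumor") values are shifted up by `effect_size * noise_sd`.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `dataset` (an [expression_dataset()], classes
#'   `"normal"` then `"tumor"`) and `planted` (sorted gene row indices).
#' @examples
#' out <- generate_dataset(synthetic_spec(100, 10, 10, 5, seed = 7))
#' dim(out$dataset)   # 100 x 20
#' out$planted
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "SyntheticSpec")) {
    spec <- do.call(synthetic_spec, spec)
  }
  with_seed(spec$seed, {
    n <- spec$n1 + spec$n2
    baseline <- stats::rnorm(spec$n_genes, mean = 7, sd = 2)
    mat <- baseline +
      matrix(stats::rnorm(spec$n_genes * n, sd = spec$noise_sd),
             nrow = spec$n_genes, ncol = n)
    planted <- sort(sample.int(spec$n_genes, spec$n_informative))
    if (spec$n_informative > 0L) {
      tumor_cols <- seq.int(spec$n1 + 1L, n)
      mat[planted, tumor_cols] <- mat[planted, tumor_cols] +
        spec$effect_size * spec$noise_sd
    }
    ds <- expression_dataset(
      mat,
      gene_ids = sprintf("g%0*d", nchar(spec$n_genes), seq_len(spec$n_genes)),
      sample_ids = sprintf("s%0*d", nchar(n), seq_len(n)),
      labels = c(rep("normal", spec$n1), rep("tumor", spec$n2)),
      class_names = c("normal", "tumor"))
    list(dataset = ds, planted = planted)
  })
}

#' Fraction of planted genes recovered by a ranking's top-m set
#'
#' @param ranking a `GeneRanking` from [top_m()] or [rank_genes()].
#' @param planted integer vector of planted gene row indices; must be
#'   nonempty.
#' @return `|top_m intersect planted| / |planted|`, in `[0, 1]`.
#' @export
planted_recovery_rate <- function(ranking, planted) {
  if (length(planted) == 0L) {
    stop("planted gene set is empty", call. = FALSE)
  }
  length(intersect(ranking$top_m, planted)) / length(planted)
}
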