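#' Pipeline configuration
#'
#' Describes a full filter/wrapper grid: which ranking statistics, which
#' optimizers, which top-m sizes, the classifier settings, and optimizer
#' parameter overrides.  Every grid cell derives its own seed from the
#' master seed and the cell key, so removing one grid entry never changes
#' another's numbers.
#'
#' @param stats subset of `c("t_statistic", "snr", "f_test")`.
#' @param algorithms subset of `c("pso", "cs", "sfl", "sfllf")`.
#' @param m_values integer vector of top-m sizes (canonically 10, 50, 100).
#' @param k,n_folds k-NN neighbour count and CV fold count.
#' @param seed master seed.
#' @param snr_denominator,signed_ranking,f_rank ranking options, see
#'   [rank_genes()].
#' @param scale feature scaling mode, see [cv_fitness()].
#' @param optimizer named list of overrides passed to [optimizer_config()]
#'   (e.g. `list(population = 20, generations = 40)`).
#' @param repeats number of independently seeded optimizer repeats per cell;
#'   the headline number per cell is the best over repeats, the mean is also
#'   reported.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(stats = c("t_statistic", "snr", "f_test"),
                            algorithms = c("pso", "cs", "sfl", "sfllf"),
                            m_values = c(10L, 50L, 100L),
                            k = 5L, n_folds = 5L, seed = 1L,
                            snr_denominator = c("sum", "paper"),
                            signed_ranking = FALSE,
                            f_rank = c("ascending", "two_tailed"),
                            scale = c("none", "zscore"),
                            optimizer = list(), repeats = 1L) {
  stats <- match.arg(stats, several.ok = TRUE)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (length(m_values) < 1L) stop("need at least one m value", call. = FALSE)
  structure(
    list(stats = stats, algorithms = algorithms,
         m_values = as.integer(m_values), k = as.integer(k),
         n_folds = as.integer(n_folds), seed = as.integer(seed),
         snr_denominator = match.arg(snr_denominator),
         signed_ranking = isTRUE(signed_ranking),
         f_rank = match.arg(f_rank), scale = match.arg(scale),
         optimizer = optimizer, repeats = as.integer(repeats)),
    class = "PipelineConfig")
}

#' Run the full rank / select / optimize grid on a dataset
#'
#' For each configured statistic and m, ranks the genes on the full dataset
#' and restricts to the top-m candidates; then runs every configured
#' optimizer with cross-validated k-NN accuracy as fitness.  Deterministic
#' given the master seed: each cell's seed is a stable hash of
#' (statistic, algorithm, m) combined with the master seed.
#'
#' @param ds an [expression_dataset()].
#' @param config a [pipeline_config()].
#' @return a `PipelineReport` list with `cells` (a data frame, one row per
#'   grid cell), `traces` (named list of per-generation best-fitness
#'   vectors), `config`, and `created` (timestamp, excluded from the
#'   deterministic report body).
#' @export
run_pipeline <- function(ds, config = pipeline_config()) {
  problems <- validate_dataset(ds)
  if (length(problems) > 0L) {
    stop("invalid dataset:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  n_genes <- nrow(ds$matrix)
  bad_m <- config$m_values[config$m_values > n_genes]
  if (length(bad_m) > 0L) {
    stop(sprintf("m = %d exceeds the dataset's gene count (%d)",
                 bad_m[1L], n_genes), call. = FALSE)
  }
  rows <- list()
  traces <- list()
  for (stat in config$stats) {
    for (m in config$m_values) {
      rk <- rank_genes(ds, stat, m, signed = config$signed_ranking,
                       f_rank = config$f_rank,
                       snr_denominator = config$snr_denominator)
      for (algo in config$algorithms) {
        key <- sprintf("%s|%s|m=%d", stat, algo, m)
        cell_seed <- derive_seed(config$seed, key)
        cell <- tryCatch(
          run_cell(ds, rk, algo, m, cell_seed, config),
          error = function(e) {
            list(error = conditionMessage(e))
          })
        if (!is.null(cell$error)) {
          rows[[key]] <- data.frame(
            statistic = stat, algorithm = algo, m = m,
            best_fitness = NA_real_, mean_fitness = NA_real_,
            n_selected = NA_integer_, genes = "",
            fold_accuracies = "", evaluations = NA_integer_,
            seed = cell_seed, error = cell$error,
            stringsAsFactors = FALSE)
        } else {
          rows[[key]] <- cell$row
          traces[[key]] <- cell$trace
        }
      }
    }
  }
  structure(
    list(cells = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         traces = traces, config = config,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "PipelineReport")
}

run_cell <- function(ds, rk, algo, m, cell_seed, config) {
  candidate_genes <- rk$top_m
  fitness <- make_cv_fitness(ds, candidate_genes, k = config$k,
                             n_folds = config$n_folds, seed = cell_seed,
                             scale = config$scale)
  opt_args <- c(list(algorithm = algo, dim = m), config$optimizer)
  cfg <- do.call(optimizer_config, opt_args)
  runs <- lapply(seq_len(config$repeats), function(r) {
    run_optimizer(cfg, fitness,
                  seed = derive_seed(cell_seed, sprintf("repeat=%d", r)))
  })
  fits <- vapply(runs, function(r) r$best_fitness, numeric(1L))
  best <- runs[[which.max(fits)]]
  sel <- candidate_genes[best$best_mask]
  fr <- cv_fitness(ds, sel, k = config$k, n_folds = config$n_folds,
                   seed = cell_seed, scale = config$scale)
  list(
    row = data.frame(
      statistic = rk$method, algorithm = algo, m = m,
      best_fitness = best$best_fitness, mean_fitness = mean(fits),
      n_selected = length(sel),
      genes = paste(ds$gene_ids[sel], collapse = ";"),
      fold_accuracies = paste(sprintf("%.6g", fr$fold_accuracies),
                              collapse = ";"),
      evaluations = sum(vapply(runs, function(r) r$evaluations,
                               integer(1L))),
      seed = cell_seed, error = NA_character_,
      stringsAsFactors = FALSE),
    trace = best$trace)
}

#' Deterministic text body of a pipeline report
#'
#' Serializes the cell table (and optionally the traces) as tab-delimited
#' lines with no timestamps, so two runs with the same seed are
#' byte-identical.
#'
#' @param report a `PipelineReport`.
#' @param traces include per-generation traces after the cell table.
#' @return character vector of lines.
#' @export
format_pipeline_report <- function(report, traces = FALSE) {
  cells <- report$cells
  header <- paste(names(cells), collapse = "\t")
  body <- vapply(seq_len(nrow(cells)), function(i) {
    paste(vapply(cells[i, ], function(v) {
      if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
    }, character(1L)), collapse = "\t")
  }, character(1L))
  out <- c(header, body)
  if (traces && length(report$traces) > 0L) {
    out <- c(out, "", vapply(names(report$traces), function(k) {
      paste(c(k, sprintf("%.10g", report$traces[[k]])), collapse = "\t")
    }, character(1L)))
  }
  out
}

#' Write a pipeline report as delimited text and a JSON twin
#'
#' @param report a `PipelineReport`.
#' @param path output path for the tab-delimited cell table; the JSON twin
#'   goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(report, path) {
  writeLines(format_pipeline_report(report), path)
  jsonlite::write_json(
    list(cells = report$cells, traces = report$traces,
         created = report$created),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
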