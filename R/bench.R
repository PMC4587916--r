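#' Benchmark configuration
#'
#' Bundles every choice of the replicated study: which datasources and
#' methods to run, how many replicate datasets to subsample and at what
#' size, the noise contamination, the evaluation protocol, and the master
#' seed from which every random stream is derived. Defaults mirror the
#' reference study design: 10 datasets of 150 experiments per datasource,
#' 20% local Gaussian plus 10% global lognormal noise, undirected
#' evaluation on the top 20% of possible connections, and Bonferroni-
#' corrected rank-sum winner flagging at 0.05.
#'
#' @param datasources named list of `grn_datasource` objects.
#' @param methods character vector of registry names (see [grn_methods()]).
#' @param datasets_per_source replicate datasets per datasource.
#' @param experiments_per_dataset rows per dataset.
#' @param noise a [noise_spec()].
#' @param eval an [eval_spec()].
#' @param seed master seed.
#' @param alpha significance level for winner flagging.
#' @param method_params named list of per-method argument lists.
#' @return A `bench_config` object.
#' @export
bench_config <- function(datasources, methods,
                         datasets_per_source = 10L,
                         experiments_per_dataset = 150L,
                         noise = noise_spec(),
                         eval = eval_spec(),
                         seed = 1L,
                         alpha = 0.05,
                         method_params = list()) {
  stopifnot(is.list(datasources), length(datasources) > 0)
  if (is.null(names(datasources)) || any(names(datasources) == ""))
    names(datasources) <- vapply(datasources, function(d) d$name, character(1))
  unknown <- setdiff(methods, grn_methods())
  if (length(unknown))
    abort_param(sprintf("unknown method(s): %s; registered: %s",
                        paste(unknown, collapse = ", "),
                        paste(grn_methods(), collapse = ", ")))
  structure(list(datasources = datasources, methods = methods,
                 datasets_per_source = check_count(datasets_per_source, "datasets_per_source"),
                 experiments_per_dataset = check_count(experiments_per_dataset, "experiments_per_dataset"),
                 noise = noise, eval = eval, seed = as.integer(seed),
                 alpha = check_fraction(alpha, "alpha", 0, 1),
                 method_params = method_params),
            class = "bench_config")
}

run_method_safe <- function(method, expr, params, seed) {
  args <- c(list(expr), params)
  if (method %in% c("genie3", "random", "c3net")) args$seed <- seed
  tryCatch(do.call(grn_infer, c(list(method = method), args)),
           error = function(e) {
             warning(sprintf("method \"%s\" failed: %s", method, conditionMessage(e)),
                     call. = FALSE)
             NULL
           })
}

#' Run a replicated inference benchmark
#'
#' For every datasource: subsamples the configured number of replicate
#' datasets, contaminates each with the configured noise, runs every
#' method, and evaluates it against the datasource's gold standard. A
#' method that errors on a dataset is recorded as a missing cell, not a
#' crash. Everything is reproducible bit-for-bit from the master seed.
#'
#' @param config a [bench_config()].
#' @return A `grn_benchmark` holding the long results tibble
#'   (`datasource`, `method`, `dataset`, `aupr`, `auroc`,
#'   `mean_precision`), the mean/variance summary, winner flags from
#'   [flag_winners()], and aggregated ranks from [aggregate_ranks()].
#' @export
grn_benchmark <- function(config) {
  stopifnot(inherits(config, "bench_config"))
  rows <- list()
  for (src_name in names(config$datasources)) {
    ds <- config$datasources[[src_name]]
    datasets <- grn_subsample(ds, config$experiments_per_dataset,
                              config$datasets_per_source,
                              seed = derive_seed(config$seed, "bench", src_name))
    for (d in seq_along(datasets)) {
      noisy <- grn_add_noise(datasets[[d]], config$noise,
                             seed = derive_seed(config$seed, "bench-noise", src_name, d))
      for (m in config$methods) {
        sc <- run_method_safe(m, noisy$expr, config$method_params[[m]],
                              derive_seed(config$seed, "method", m, src_name, d))
        if (is.null(sc)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            datasource = src_name, method = m, dataset = d,
            aupr = NA_real_, auroc = NA_real_, mean_precision = NA_real_)
          next
        }
        ev <- grn_evaluate(sc, ds$gold, config$eval)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          datasource = src_name, method = m, dataset = d,
          aupr = aupr_top(ev), auroc = auroc_top(ev),
          mean_precision = mean_precision_top(ev))
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$datasource, .data$method) |>
    dplyr::summarise(mean_aupr = mean(.data$aupr, na.rm = TRUE),
                     var_aupr = stats::var(.data$aupr, na.rm = TRUE),
                     mean_auroc = mean(.data$auroc, na.rm = TRUE),
                     mean_precision = mean(.data$mean_precision, na.rm = TRUE),
                     n_ok = sum(!is.na(.data$aupr)),
                     .groups = "drop")
  winners <- flag_winners(results, alpha = config$alpha)
  ranks <- aggregate_ranks(summary)
  structure(list(results = results, summary = summary, winners = winners,
                 ranks = ranks, config = config),
            class = "grn_benchmark")
}

#' @export
print.grn_benchmark <- function(x, ...) {
  cat(sprintf("<grn_benchmark> %d datasource(s) x %d method(s) x %d dataset(s)\n",
              length(unique(x$results$datasource)), length(unique(x$results$method)),
              max(x$results$dataset)))
  print(x$summary, n = 30)
  invisible(x)
}

#' Flag the statistically indistinguishable best methods
#'
#' Within each datasource, the method with the best mean metric is
#' compared with every other method by a two-sided Wilcoxon rank-sum test
#' on the per-dataset values (exact enumeration when both samples have at
#' most 10 observations and no ties; normal approximation with tie
#' correction otherwise). P-values are Bonferroni-corrected over the
#' number of comparisons in the datasource; the winner set is the top
#' method plus every method not significantly different from it.
#'
#' @param results long tibble with columns `datasource`, `method`,
#'   and the metric in `metric_col`.
#' @param alpha significance level (after Bonferroni correction).
#' @param metric_col metric column name (default `"aupr"`).
#' @return Tibble with `datasource`, `method`, `mean_metric`, `p_value`
#'   (raw), `p_adjusted`, and logical `winner`.
#' @export
flag_winners <- function(results, alpha = 0.05, metric_col = "aupr") {
  stopifnot(metric_col %in% names(results))
  out <- list()
  for (src in unique(results$datasource)) {
    sub <- results[results$datasource == src, ]
    vals <- split(sub[[metric_col]], sub$method)
    vals <- lapply(vals, function(v) v[!is.na(v)])
    means <- vapply(vals, mean, numeric(1))
    top <- names(means)[which.max(means)]
    others <- setdiff(names(means), top)
    m <- length(others)
    p_raw <- setNames(rep(NA_real_, length(means)), names(means))
    p_raw[top] <- 1
    for (mm in others) {
      p_raw[mm] <- rank_sum_p(vals[[top]], vals[[mm]])
    }
    p_adj <- setNames(pmin(1, p_raw * max(1, m)), names(p_raw))
    p_adj[top] <- 1
    out[[src]] <- tibble::tibble(
      datasource = src, method = names(means), mean_metric = unname(means),
      p_value = unname(p_raw), p_adjusted = unname(p_adj),
      winner = names(means) == top | unname(p_adj) >= alpha)
  }
  dplyr::bind_rows(out)
}

# Two-sided Wilcoxon/Mann-Whitney rank-sum p-value; exact when both
# samples are small and untied, normal approximation with tie correction
# otherwise. Identical samples give p = 1.
rank_sum_p <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) return(NA_real_)
  if (length(unique(c(x, y))) == 1L) return(1)  # no evidence either way
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 10 && length(y) <= 10 && !has_ties
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value)
  min(1, p)
}

#' Aggregate method ranks across datasources
#'
#' Within each datasource, methods are ranked by mean metric (rank 1 =
#' best, average ranks on ties); the per-method rank vectors across
#' datasources summarize overall standing independently of each
#' datasource's metric scale.
#'
#' @param summary tibble with `datasource`, `method`, and the column in
#'   `metric_col` (as produced by [grn_benchmark()]'s summary).
#' @param metric_col mean-metric column (default `"mean_aupr"`).
#' @return A list with `ranks` (long tibble `datasource`, `method`,
#'   `rank`) and `summary` (per-method five-number summary of ranks:
#'   `min`, `q1`, `median`, `q3`, `max`, `mean_rank`).
#' @export
aggregate_ranks <- function(summary, metric_col = "mean_aupr") {
  stopifnot(metric_col %in% names(summary))
  ranks <- summary |>
    dplyr::group_by(.data$datasource) |>
    dplyr::mutate(rank = rank(-.data[[metric_col]], ties.method = "average",
                              na.last = "keep")) |>
    dplyr::ungroup() |>
    dplyr::select("datasource", "method", "rank")
  rs <- ranks |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(min = min(.data$rank, na.rm = TRUE),
                     q1 = quantile(.data$rank, 0.25, na.rm = TRUE, names = FALSE),
                     median = stats::median(.data$rank, na.rm = TRUE),
                     q3 = quantile(.data$rank, 0.75, na.rm = TRUE, names = FALSE),
                     max = max(.data$rank, na.rm = TRUE),
                     mean_rank = mean(.data$rank, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$median, .data$mean_rank)
  list(ranks = ranks, summary = rs)
}

#' Noise-sensitivity sweep
#'
#' Reruns the benchmark at each local-noise level in `kappas` (default the
#' 0/25/50/75/100 grid) while holding everything else fixed. The
#' subsampled experiment draws are identical across noise levels — only
#' the noise stream varies — so columns are directly comparable.
#'
#' @param config a [bench_config()].
#' @param kappas local-noise percentages to sweep.
#' @return A `grn_sweep` with the long tibble over
#'   (`kappa`, `datasource`, `method`) and the per-level `grn_benchmark`
#'   objects.
#' @export
grn_noise_sweep <- function(config, kappas = c(0, 25, 50, 75, 100)) {
  stopifnot(inherits(config, "bench_config"))
  levels <- lapply(kappas, function(k) {
    cfg <- config
    # the sweep isolates local noise: kappa = 0 is a genuinely noise-free run
    cfg$noise <- noise_spec(kappa_local = k, kappa_global = 0,
                            range_fraction = config$noise$range_fraction,
                            local_type = config$noise$local_type,
                            global_type = config$noise$global_type)
    grn_benchmark(cfg)
  })
  names(levels) <- as.character(kappas)
  grid <- dplyr::bind_rows(lapply(seq_along(kappas), function(i) {
    dplyr::mutate(levels[[i]]$summary, kappa = kappas[i], .before = 1)
  }))
  structure(list(grid = grid, levels = levels, sweep = "noise", values = kappas),
            class = "grn_sweep")
}

#' Sample-size-sensitivity sweep
#'
#' Reruns the benchmark with each dataset size in `n_experiments` (default
#' the 20/50/200/800 grid) at the configured noise. A size exceeding a
#' datasource's experiment count is marked infeasible and skipped; the run
#' continues.
#'
#' @param config a [bench_config()].
#' @param n_experiments dataset sizes to sweep.
#' @return A `grn_sweep` with the long grid over (`n`, `datasource`,
#'   `method`); infeasible cells carry `NA` means and `feasible = FALSE`.
#' @export
grn_experiments_sweep <- function(config, n_experiments = c(20, 50, 200, 800)) {
  stopifnot(inherits(config, "bench_config"))
  levels <- list()
  grid <- list()
  for (n in n_experiments) {
    feas <- vapply(config$datasources, function(d) nrow(d$expr) >= n, logical(1))
    if (!any(feas)) {
      grid[[length(grid) + 1L]] <- tibble::tibble(
        n = n, datasource = names(config$datasources),
        method = NA_character_, mean_aupr = NA_real_, feasible = FALSE)
      next
    }
    cfg <- config
    cfg$datasources <- config$datasources[feas]
    cfg$experiments_per_dataset <- as.integer(n)
    bm <- grn_benchmark(cfg)
    levels[[as.character(n)]] <- bm
    g <- dplyr::mutate(bm$summary, n = n, feasible = TRUE, .before = 1)
    if (any(!feas)) {
      g <- dplyr::bind_rows(g, tibble::tibble(
        n = n, feasible = FALSE, datasource = names(config$datasources)[!feas],
        method = NA_character_, mean_aupr = NA_real_))
    }
    grid[[length(grid) + 1L]] <- g
  }
  structure(list(grid = dplyr::bind_rows(grid), levels = levels,
                 sweep = "experiments", values = n_experiments),
            class = "grn_sweep")
}

#' @export
print.grn_sweep <- function(x, ...) {
  cat(sprintf("<grn_sweep> %s sweep over {%s}\n", x$sweep,
              paste(x$values, collapse = ", ")))
  print(x$grid, n = 40)
  invisible(x)
}

#' @describeIn grn_benchmark long per-dataset results tibble.
#' @param x a `grn_benchmark`.
#' @param ... unused.
#' @export
tidy.grn_benchmark <- function(x, ...) x$results

#' @describeIn grn_benchmark mean/variance summary joined with winner
#'   flags and ranks.
#' @export
glance.grn_benchmark <- function(x, ...) {
  x$summary |>
    dplyr::left_join(dplyr::select(x$winners, "datasource", "method",
                                   "p_adjusted", "winner"),
                     by = c("datasource", "method")) |>
    dplyr::left_join(x$ranks$ranks, by = c("datasource", "method"))
}

#' @describeIn grn_benchmark boxplot of method ranks across datasources
#'   (smaller rank = better).
#' @param object a `grn_benchmark`.
#' @export
autoplot.grn_benchmark <- function(object, ...) {
  rk <- object$ranks$ranks
  ord <- object$ranks$summary$method
  rk$method <- factor(rk$method, levels = ord)
  ggplot2::ggplot(rk, ggplot2::aes(x = .data$method, y = .data$rank)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Rank across datasources (1 = best)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.grn_sweep <- function(object, ...) {
  xlab <- if (object$sweep == "noise") "Local noise κ (%)" else "Experiments per dataset"
  xcol <- if (object$sweep == "noise") "kappa" else "n"
  g <- object$grid[!is.na(object$grid$mean_aupr), ]
  ggplot2::ggplot(g, ggplot2::aes(x = .data[[xcol]], y = .data$mean_aupr,
                                  colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~datasource) +
    ggplot2::labs(x = xlab, y = "Mean AUPR (top edges)") +
    ggplot2::theme_minimal()
}
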