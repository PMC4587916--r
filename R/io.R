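# Round-trippable plain-text writers/readers for every object the pipeline
# exchanges: expression matrices, gold standards (two dialects), score
# matrices, ranked edge lists, metrics, and run manifests.

#' Write / read an expression matrix as TSV
#'
#' Tab-delimited with a header row of gene identifiers; one row per
#' experiment, first column `experiment` holds the row label.
#'
#' @param expr numeric matrix (rows = experiments) or a
#'   `grn_dataset`/`grn_datasource`.
#' @param path output file.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   the matrix with dimnames.
#' @export
write_expression <- function(expr, path) {
  X <- as_expr_matrix(expr)
  df <- data.frame(experiment = rownames(X) %||% paste0("E", seq_len(nrow(X))),
                   X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  X
}

#' Write / read a gold standard
#'
#' Two dialects: a full adjacency TSV (square, header = gene ids, first
#' column the regulator id) and a 2-column `regulator<TAB>target` edge
#' list. The edge-list reader also accepts an optional third weight column
#' (parsed and ignored for truth).
#'
#' @param gold a [gold_standard()].
#' @param path output file.
#' @param genes for `read_gold_edges`: gene universe (required so isolated
#'   genes keep their column).
#' @return Writers return `path` invisibly; readers a [gold_standard()].
#' @export
write_gold_adjacency <- function(gold, path) {
  df <- data.frame(regulator = gold$genes, gold$adjacency, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gold_adjacency
#' @export
read_gold_adjacency <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  gold_standard(A, genes = colnames(A))
}

#' @rdname write_gold_adjacency
#' @export
write_gold_edges <- function(gold, path) {
  idx <- which(gold$adjacency == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(regulator = gold$genes[idx[, 1]], target = gold$genes[idx[, 2]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gold_adjacency
#' @export
read_gold_edges <- function(path, genes = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) abort_param("edge list needs at least regulator and target columns")
  if (ncol(df) >= 3) as.numeric(df[[3]])  # weight column must parse; truth ignores it
  if (is.null(genes)) genes <- sort(unique(c(df[[1]], df[[2]])))
  missing <- setdiff(unique(c(df[[1]], df[[2]])), genes)
  if (length(missing))
    abort_param(sprintf("edge list mentions genes outside the universe: %s",
                        paste(head(missing, 5), collapse = ", ")))
  A <- matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
  A[cbind(match(df[[1]], genes), match(df[[2]], genes))] <- 1L
  gold_standard(A, genes)
}

#' Write a score matrix
#'
#' `write_scores_matrix` writes the full G x G matrix (same layout as the
#' adjacency writer); `write_scores_edges` a ranked edge list with columns
#' `regulator`, `target`, `score`, `rank` (decreasing score, fixed
#' lexicographic tie-break, diagonal omitted).
#'
#' @param scores G x G numeric score matrix.
#' @param path output file.
#' @return `path` invisibly (`read_scores_matrix`: the matrix).
#' @export
write_scores_matrix <- function(scores, path) {
  S <- as.matrix(scores)
  genes <- colnames(S) %||% paste0("G", seq_len(ncol(S)))
  df <- data.frame(regulator = genes, S, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_matrix
#' @export
read_scores_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df[[1]]
  S
}

#' @rdname write_scores_matrix
#' @export
write_scores_edges <- function(scores, path) {
  S <- as.matrix(scores)
  genes <- colnames(S) %||% paste0("G", seq_len(ncol(S)))
  G <- ncol(S)
  idx <- which(diag(G) == 0)
  ord <- idx[order(-S[idx], idx)]
  ri <- (ord - 1L) %% G + 1L
  ci <- (ord - 1L) %/% G + 1L
  df <- data.frame(regulator = genes[ri], target = genes[ci],
                   score = S[ord], rank = seq_along(ord))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write evaluation metrics as JSON
#'
#' @param result a `grn_evaluation`.
#' @param path output file.
#' @param method,datasource,seed optional provenance fields.
#' @return `path` invisibly.
#' @export
write_metrics_json <- function(result, path, method = NA, datasource = NA, seed = NA) {
  stopifnot(inherits(result, "grn_evaluation"))
  obj <- list(method = method, datasource = datasource, seed = seed,
              aupr_top = aupr_top(result), auroc_top = auroc_top(result),
              mean_precision = mean_precision_top(result),
              t = result$t, directed = result$directed,
              top_fraction = result$top_fraction)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write benchmark results
#'
#' Three formats: a long TSV (`datasource`, `method`, `dataset`, metric
#' columns), a wide TSV with per-datasource mean and variance (x 1000)
#' columns per method, and a JSON run manifest carrying the full
#' configuration, seeds, package version and an inventory of the written
#' files with checksums — enough to re-execute the run bit-identically.
#'
#' @param bm a `grn_benchmark`.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_benchmark <- function(bm, dir) {
  stopifnot(inherits(bm, "grn_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long_path <- file.path(dir, "results_long.tsv")
  write.table(bm$results, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  wide <- bm$summary |>
    dplyr::mutate(var_aupr_x1000 = .data$var_aupr * 1000) |>
    dplyr::select("datasource", "method", "mean_aupr", "var_aupr_x1000") |>
    tidyr::pivot_wider(names_from = "method",
                       values_from = c("mean_aupr", "var_aupr_x1000"))
  wide_path <- file.path(dir, "results_wide.tsv")
  write.table(wide, wide_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ranks_path <- file.path(dir, "ranks.tsv")
  write.table(bm$ranks$ranks, ranks_path, sep = "\t", quote = FALSE, row.names = FALSE)
  winners_path <- file.path(dir, "winners.tsv")
  write.table(bm$winners, winners_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(long = long_path, wide = wide_path, ranks = ranks_path,
             winners = winners_path)
  manifest_path <- file.path(dir, "manifest.json")
  write_manifest(config_snapshot(bm$config), paths, manifest_path)
  invisible(c(paths, manifest = manifest_path))
}

config_snapshot <- function(config) {
  list(methods = config$methods,
       datasources = lapply(config$datasources, function(d)
         list(name = d$name, kind = d$kind, seed = d$seed,
              n_experiments = nrow(d$expr), n_genes = ncol(d$expr),
              n_edges = n_edges(d$gold))),
       datasets_per_source = config$datasets_per_source,
       experiments_per_dataset = config$experiments_per_dataset,
       noise = unclass(config$noise),
       eval = unclass(config$eval),
       alpha = config$alpha,
       seed = config$seed)
}

# Manifest written atomically: assembled to a temp file, then renamed.
write_manifest <- function(config, paths, manifest_path) {
  inventory <- lapply(paths, function(p)
    list(file = basename(p), md5 = unname(tools::md5sum(p))))
  names(inventory) <- names(paths)
  obj <- list(package = "grnbench",
              version = as.character(utils::packageVersion("grnbench")),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
              config = config,
              files = inventory)
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, manifest_path)
  invisible(manifest_path)
}
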