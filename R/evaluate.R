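#' Evaluation specification
#'
#' Controls the top-edges scoring protocol: only the best `top_fraction` of
#' all possible connections is evaluated (`G^2 - G` ordered pairs in a
#' directed evaluation, `(G^2 - G)/2` unordered pairs in an undirected
#' one); self-interactions are never considered.
#'
#' @param top_fraction fraction of possible connections evaluated, in
#'   (0, 1]; default 0.20.
#' @param directed logical; if `FALSE` (default) existence of an edge is
#'   evaluated regardless of direction.
#' @return An `eval_spec` object.
#' @export
eval_spec <- function(top_fraction = 0.20, directed = FALSE) {
  top_fraction <- check_fraction(top_fraction, "top_fraction", lo = 1e-9, hi = 1)
  structure(list(top_fraction = top_fraction, directed = isTRUE(directed)),
            class = "eval_spec")
}

#' Score an inferred network against a gold standard
#'
#' Sorts candidate edges by decreasing score (ties broken by a fixed
#' lexicographic edge order, recorded in the result) and accumulates the
#' confusion counts at every rank cutoff `1..t`, with
#' `t = round(top_fraction * n_candidates)`. In the undirected evaluation
#' the candidate universe is the unordered pairs, a pair's score is the
#' larger of its two directed scores, and a pair is true if either
#' direction is a gold edge.
#'
#' @param scores G x G numeric score matrix (higher = more confident,
#'   diagonal ignored).
#' @param gold a [gold_standard()] with the same genes in the same order.
#' @param spec an [eval_spec()].
#' @return A `grn_evaluation` with a per-rank tibble (`rank`, `tp`, `fp`,
#'   `tn`, `fn`, `precision`, `recall`, `fpr`), the totals, and the
#'   degenerate-ordering warning flag. See [aupr_top()], [auroc_top()],
#'   [mean_precision_top()], [tidy.grn_evaluation()],
#'   [glance.grn_evaluation()].
#' @examples
#' gold <- grn_powerlaw_topology(10, 9, seed = 1)
#' ds <- grn_simulate_knockouts(gold, seed = 1)
#' ev <- grn_evaluate(grn_zscore(ds$expr), gold, eval_spec(directed = TRUE))
#' glance(ev)
#' @export
grn_evaluate <- function(scores, gold, spec = eval_spec()) {
  stopifnot(inherits(gold, "gold_standard"), inherits(spec, "eval_spec"))
  S <- as.matrix(scores)
  G <- length(gold$genes)
  if (!all(dim(S) == G)) abort_param("score matrix dimension must match the gold standard")
  if (!is.null(colnames(S)) && !identical(colnames(S), gold$genes))
    abort_param("score matrix gene names must match the gold standard")
  A <- gold$adjacency
  if (spec$directed) {
    idx <- which(diag(G) == 0)              # ordered off-diagonal pairs
    s <- S[idx]
    truth <- A[idx] == 1L
  } else {
    ut <- which(upper.tri(S))
    s <- pmax(S[ut], t(S)[ut])
    truth <- (A[ut] + t(A)[ut]) > 0L
  }
  n_cand <- length(s)
  t_eval <- max(1L, as.integer(floor(spec$top_fraction * n_cand + 0.5)))
  ord <- order(-s, seq_along(s))            # fixed lexicographic tie-break
  degenerate <- length(unique(s)) == 1L
  truth_sorted <- truth[ord][seq_len(t_eval)]
  tp <- cumsum(truth_sorted)
  rank <- seq_len(t_eval)
  fp <- rank - tp
  P <- sum(truth)
  Neg <- n_cand - P
  res <- tibble::tibble(
    rank = rank, tp = tp, fp = fp,
    fn = P - tp, tn = Neg - fp,
    precision = tp / rank,
    recall = if (P > 0) tp / P else NA_real_,
    fpr = if (Neg > 0) fp / Neg else NA_real_)
  structure(list(ranks = res, t = t_eval, n_true = P, n_candidates = n_cand,
                 directed = spec$directed, top_fraction = spec$top_fraction,
                 degenerate = degenerate),
            class = "grn_evaluation")
}

#' @export
print.grn_evaluation <- function(x, ...) {
  cat(sprintf("<grn_evaluation> %s, top %.0f%% (t = %d of %d pairs, %d true)\n",
              if (x$directed) "directed" else "undirected",
              100 * x$top_fraction, x$t, x$n_candidates, x$n_true))
  cat(sprintf("  AUPR %.4f | AUROC %.4f | mean precision %.4f\n",
              aupr_top(x), auroc_top(x), mean_precision_top(x)))
  if (x$degenerate) cat("  warning: constant scores, ordering is the tie-break only\n")
  invisible(x)
}

#' Area under the top-edges precision-recall curve
#'
#' Trapezoid area of precision versus recall over the evaluated cutoffs,
#' starting from recall 0 at the first cutoff's precision, normalized by
#' the recall span the ranking actually covers — so a perfect method scores
#' exactly 1 regardless of the truncation, and a uniformly random ranking
#' scores the gold-standard edge density in expectation. A ranking with no
#' true positive within the cutoffs scores 0.
#'
#' @param result a `grn_evaluation`.
#' @return AUPR in \[0, 1\].
#' @export
aupr_top <- function(result) {
  stopifnot(inherits(result, "grn_evaluation"))
  if (result$n_true == 0) stop("AUPR undefined: the gold standard has no true edges in the candidate universe", call. = FALSE)
  r <- c(0, result$ranks$recall)
  p <- c(result$ranks$precision[1], result$ranks$precision)
  area <- sum(diff(r) * (head(p, -1) + p[-1]) / 2)
  span <- max(r)
  if (span == 0) return(0)
  area / span
}

#' Area under the top-edges ROC curve
#'
#' Trapezoid area of true-positive rate versus false-positive rate over the
#' evaluated cutoffs, normalized by the false-positive-rate span actually
#' covered. When no false positive occurs within the cutoffs (a perfect
#' truncated ranking) the area is 1 by convention.
#'
#' @inheritParams aupr_top
#' @return AUROC in \[0, 1\].
#' @export
auroc_top <- function(result) {
  stopifnot(inherits(result, "grn_evaluation"))
  if (result$n_true == 0) stop("AUROC undefined: no true edges", call. = FALSE)
  tpr <- c(0, result$ranks$recall)
  fpr <- c(0, result$ranks$fpr)
  span <- max(fpr)
  if (!is.finite(span) || span == 0) return(1)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2) / span
}

#' Mean precision over the evaluated cutoffs
#'
#' @inheritParams aupr_top
#' @return Arithmetic mean of precision at ranks `1..t`, in \[0, 1\].
#' @export
mean_precision_top <- function(result) {
  stopifnot(inherits(result, "grn_evaluation"))
  mean(result$ranks$precision)
}

#' @describeIn grn_evaluate per-rank confusion counts and curve points as a
#'   tibble.
#' @param x a `grn_evaluation`.
#' @param ... unused.
#' @export
tidy.grn_evaluation <- function(x, ...) x$ranks

#' @describeIn grn_evaluate one-row tibble of the scalar metrics.
#' @export
glance.grn_evaluation <- function(x, ...) {
  tibble::tibble(aupr = aupr_top(x), auroc = auroc_top(x),
                 mean_precision = mean_precision_top(x),
                 t = x$t, n_true = x$n_true, n_candidates = x$n_candidates,
                 directed = x$directed, degenerate = x$degenerate)
}

#' @describeIn grn_evaluate precision-recall curve of the evaluated span.
#' @param object a `grn_evaluation`.
#' @export
autoplot.grn_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$ranks, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("Top-%.0f%% precision-recall (%s)",
                                  100 * object$top_fraction,
                                  if (object$directed) "directed" else "undirected")) +
    ggplot2::theme_minimal()
}
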