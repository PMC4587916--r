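#' Gold-standard regulatory network
#'
#' A gold standard stores the true regulatory structure used to score
#' inferred networks: an ordered gene set and a binary adjacency matrix in
#' which entry `(i, j) = 1` means gene `i` regulates gene `j`
#' (row = regulator, column = target). Self-loops are never allowed.
#'
#' @param adjacency binary G x G matrix (row = regulator, column = target).
#' @param genes character vector of gene identifiers; defaults to the
#'   adjacency dimnames or `G1..Gn`.
#' @param directed logical; whether edge direction is meaningful.
#' @return An object of class `gold_standard` with fields `genes`,
#'   `adjacency` and `directed`.
#' @export
gold_standard <- function(adjacency, genes = NULL, directed = TRUE) {
  adjacency <- as.matrix(adjacency)
  G <- nrow(adjacency)
  if (ncol(adjacency) != G) abort_param("`adjacency` must be square")
  if (is.null(genes)) genes <- rownames(adjacency)
  if (is.null(genes)) genes <- paste0("G", seq_len(G))
  if (length(genes) != G) abort_param("`genes` length must match adjacency dimension")
  storage.mode(adjacency) <- "integer"
  if (any(is.na(adjacency)) || any(adjacency != 0L & adjacency != 1L))
    abort_param("`adjacency` entries must be 0 or 1")
  if (any(diag(adjacency) != 0L)) abort_param("self-loops are not allowed in a gold standard")
  if (sum(adjacency) < 1L) abort_param("gold standard must contain at least one edge")
  dimnames(adjacency) <- list(genes, genes)
  structure(list(genes = genes, adjacency = adjacency, directed = isTRUE(directed)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> %d genes, %d %s edges\n",
              length(x$genes), sum(x$adjacency),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Number of edges in a gold standard
#' @param gold a [gold_standard()] object.
#' @return integer edge count.
#' @export
n_edges <- function(gold) sum(gold$adjacency)

# A directed graph whose adjacency is strictly upper-triangular in some gene
# ordering is acyclic; generation order is the topological order here.
is_acyclic <- function(gold) {
  A <- gold$adjacency
  # Kahn's algorithm: repeatedly strip zero-in-degree nodes.
  remaining <- rep(TRUE, nrow(A))
  repeat {
    indeg <- colSums(A[remaining, remaining, drop = FALSE])
    src <- which(indeg == 0)
    if (length(src) == 0L) break
    idx <- which(remaining)[src]
    remaining[idx] <- FALSE
    if (!any(remaining)) return(TRUE)
  }
  !any(remaining)
}

#' Generate a scale-free directed acyclic gold standard
#'
#' Draws an out-degree sequence from a discrete power law with exponent
#' `exponent`, assigns the heaviest degrees to the most upstream regulators,
#' wires each gene to downstream targets only (so the graph is acyclic by
#' construction), then trims or augments edges uniformly at random until the
#' requested edge count is met exactly. Hub regulators with many targets,
#' the hallmark of transcriptional networks, arise from the power-law tail.
#'
#' @param n_genes number of genes (>= 3).
#' @param n_edges exact number of directed edges (1 <= E <= G*(G-1)/2 for a
#'   DAG in a fixed topological order).
#' @param seed integer seed; the same `(n_genes, n_edges, exponent, seed)`
#'   always yields a bit-identical gold standard.
#' @param exponent power-law exponent of the out-degree distribution
#'   (default 2.5, in the range reported for transcriptional networks).
#' @return A [gold_standard()] whose genes `G1..Gn` are in topological order.
#' @examples
#' gold <- grn_powerlaw_topology(50, 60, seed = 1)
#' n_edges(gold)
#' @export
grn_powerlaw_topology <- function(n_genes, n_edges, seed, exponent = 2.5) {
  n_genes <- check_count(n_genes, "n_genes", min = 3L)
  n_edges <- check_count(n_edges, "n_edges", min = 1L)
  if (!is.numeric(exponent) || exponent <= 1)
    abort_param("`exponent` must be > 1")
  max_edges <- n_genes * (n_genes - 1L) / 2
  if (n_edges > max_edges)
    abort_param(sprintf("`n_edges` = %d infeasible for an acyclic graph on %d genes (max %d)",
                        n_edges, n_genes, max_edges))
  genes <- paste0("G", seq_len(n_genes))
  A <- with_seed(derive_seed(seed, "topology"), {
    kmax <- n_genes - 1L
    p <- (1:kmax)^(-exponent)
    deg <- sample.int(kmax, n_genes, replace = TRUE, prob = p)
    # heaviest out-degrees upstream: feasible (gene i has n_genes - i
    # downstream slots) and mimics master-regulator hubs
    deg <- sort(deg, decreasing = TRUE)
    A <- matrix(0L, n_genes, n_genes)
    for (i in seq_len(n_genes - 1L)) {
      k <- min(deg[i], n_genes - i)
      if (k > 0L) {
        tgt <- if (n_genes - i == 1L) n_genes else i + sample.int(n_genes - i, k)
        A[i, tgt] <- 1L
      }
    }
    e <- sum(A)
    if (e > n_edges) {
      on_idx <- which(A == 1L)
      A[on_idx[sample.int(length(on_idx), e - n_edges)]] <- 0L
    } else if (e < n_edges) {
      off_idx <- which(upper.tri(A) & A == 0L)
      A[off_idx[sample.int(length(off_idx), n_edges - e)]] <- 1L
    }
    A
  })
  dimnames(A) <- list(genes, genes)
  gold_standard(A, genes, directed = TRUE)
}
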