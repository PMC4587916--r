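#' @rdname grn_simulate_knockouts
#' @export
grn_datasource <- function(name, expr, gold, kind, seed) {
  if (!identical(colnames(expr), gold$genes))
    abort_param("expression columns and gold-standard genes must match")
  if (!all(is.finite(expr))) abort_param("expression values must be finite")
  structure(list(name = name, expr = expr, gold = gold,
                 kind = match.arg(kind, c("knockout", "multifactorial")),
                 seed = as.integer(seed)),
            class = "grn_datasource")
}

#' @export
print.grn_datasource <- function(x, ...) {
  cat(sprintf("<grn_datasource> \"%s\": %d experiments x %d genes (%s), %d true edges\n",
              x$name, nrow(x$expr), ncol(x$expr), x$kind, n_edges(x$gold)))
  invisible(x)
}

# Topological order of an acyclic gold standard (error if cyclic).
topo_order <- function(gold) {
  A <- gold$adjacency
  G <- nrow(A)
  indeg <- colSums(A)
  order <- integer(0)
  active <- rep(TRUE, G)
  queue <- which(indeg == 0 & active)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    active[v] <- FALSE
    order <- c(order, v)
    for (w in which(A[v, ] == 1L)) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) != G)
    stop("gold standard contains a cycle; steady-state simulation requires an acyclic network",
         call. = FALSE)
  order
}

# Signed interaction weights for each gold edge: magnitude uniform in
# `weight_range`, sign + (activation) or - (repression) with equal odds.
draw_weights <- function(gold, weight_range) {
  A <- gold$adjacency
  W <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  idx <- which(A == 1L)
  mag <- runif(length(idx), weight_range[1], weight_range[2])
  sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
  W[idx] <- mag * sgn
  W
}

#' Simulate single-gene knockout experiments
#'
#' Builds a noise-free knockout datasource on an acyclic gold standard:
#' one experiment per gene, in which that gene is clamped to the knockout
#' level (0 on the abundance scale) and every other gene takes the steady
#' state of a linear structural-equation model
#' \deqn{x_j = b_j + \sum_i w_{ij} x_i}
#' evaluated in topological order. Interaction weights have uniform
#' magnitude in `weight_range` with random sign; basal levels are offset so
#' that all unperturbed abundances stay strictly positive, which guarantees
#' that the knocked-out gene is the minimum of its column across
#' experiments (the detection rule knockout-aware methods rely on).
#'
#' @param gold an acyclic [gold_standard()].
#' @param seed integer seed (bit-identical output for identical inputs).
#' @param weight_range magnitude range of interaction weights, default
#'   `c(0.1, 0.35)`: interaction gains well below 1 make indirect influences
#'   decay geometrically with path length, emulating the strong attenuation
#'   of saturating kinetics within a linear model.
#' @param basal_range range of the guaranteed-positive basal component of
#'   each gene's abundance, default `c(1, 2)`.
#' @param knockout_level clamped abundance of the knocked-out gene
#'   (default 0).
#' @param name datasource name.
#' @return A `grn_datasource` of kind `"knockout"` with `G` experiments
#'   (rows named `KO_<gene>`).
#' @examples
#' gold <- grn_powerlaw_topology(20, 25, seed = 1)
#' ds <- grn_simulate_knockouts(gold, seed = 1)
#' dim(ds$expr)
#' @export
grn_simulate_knockouts <- function(gold, seed, weight_range = c(0.1, 0.35),
                                   basal_range = c(1, 2), knockout_level = 0,
                                   name = "knockout") {
  ord <- topo_order(gold)
  G <- length(gold$genes)
  with_seed(derive_seed(seed, "knockout"), {
    W <- draw_weights(gold, weight_range)
    mu0 <- runif(G, basal_range[1], basal_range[2])
    # Wild-type operating point mu solves x = b + W'x; the basal level b is
    # chosen so every gene sits at mu0 plus a positivity margin: the margin
    # is the worst-case deviation any single knockout can induce, computed
    # from the path-product matrix P = sum_k |W|^k (finite: W is nilpotent
    # on a DAG). This keeps all genes on a common abundance scale and every
    # non-knocked-out value >= mu0 > 0.
    P <- solve(diag(G) - abs(W)) - diag(G)
    mu <- numeric(G)
    for (j in ord) {
      anc <- which(P[, j] > 0)
      mu[j] <- mu0[j] + if (length(anc)) max(P[anc, j] * mu[anc]) else 0
    }
    X <- matrix(0, G, G, dimnames = list(paste0("KO_", gold$genes), gold$genes))
    for (k in seq_len(G)) {
      # deviations from the operating point propagate linearly from the
      # clamped gene through the downstream network
      delta <- numeric(G)
      delta[k] <- knockout_level - mu[k]
      for (j in ord) {
        if (j == k) next
        pa <- which(W[, j] != 0)
        if (length(pa)) delta[j] <- sum(W[pa, j] * delta[pa])
      }
      x <- mu + delta
      x[k] <- knockout_level
      X[k, ] <- x
    }
    grn_datasource(name, X, gold, "knockout", seed)
  })
}

#' Simulate multifactorial steady-state experiments
#'
#' Builds a noise-free multifactorial datasource: in each experiment every
#' gene's basal rate is perturbed by an independent multiplicative
#' lognormal factor, then the network relaxes to the steady state of a
#' saturating (Hill-type) regulation function evaluated in topological
#' order. Each regulator acts through a Hill term with coefficient
#' `hill_n` and half-saturation `x_max / 2`, scaled to (0, 2) so that
#' activation can at most double and repression at most silence its
#' target's production; abundances are bounded in `(0, x_max]`. This
#' emulates the all-genes-slightly-perturbed design of multifactorial
#' expression compendia.
#'
#' @inheritParams grn_simulate_knockouts
#' @param n_experiments number of experiments (>= 2).
#' @param spread standard deviation (log scale) of the lognormal basal
#'   perturbation; 0 makes all experiments identical. Default 0.5.
#' @param hill_n Hill coefficient (default 2).
#' @param x_max abundance scale bound (default 2).
#' @return A `grn_datasource` of kind `"multifactorial"` with rows
#'   `E1..En`.
#' @examples
#' gold <- grn_powerlaw_topology(20, 25, seed = 1)
#' ds <- grn_simulate_multifactorial(gold, n_experiments = 50, seed = 1)
#' range(ds$expr)
#' @export
grn_simulate_multifactorial <- function(gold, n_experiments, seed, spread = 0.5,
                                        hill_n = 2, x_max = 2,
                                        weight_range = c(0.5, 1),
                                        name = "multifactorial") {
  n_experiments <- check_count(n_experiments, "n_experiments", min = 2L)
  ord <- topo_order(gold)
  G <- length(gold$genes)
  K <- x_max / 2
  with_seed(derive_seed(seed, "multifactorial"), {
    W <- draw_weights(gold, weight_range)
    s <- runif(G, 0.8, 1.6)  # basal production strength per gene
    X <- matrix(0, n_experiments, G,
                dimnames = list(paste0("E", seq_len(n_experiments)), gold$genes))
    for (k in seq_len(n_experiments)) {
      m <- if (spread > 0) rlnorm(G, meanlog = 0, sdlog = spread) else rep(1, G)
      x <- numeric(G)
      for (j in ord) {
        input <- s[j] * m[j]
        pa <- which(W[, j] != 0)
        for (i in pa) {
          h <- (x[i] / K)^hill_n
          f <- if (W[i, j] > 0) 2 * h / (1 + h) else 2 / (1 + h)
          input <- input * abs(W[i, j]) * f
        }
        x[j] <- x_max * input / (1 + input)
      }
      X[k, ] <- x
    }
    grn_datasource(name, X, gold, "multifactorial", seed)
  })
}
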