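# Inference methods. Common contract: expression in (rows = experiments,
# columns = genes, as matrix or data.frame), G x G score matrix out with
# zero diagonal and higher = more confident. Symmetric methods carry
# attr(x, "symmetric") = TRUE; zscore and genie3 are directed
# (entry (i, j) = confidence that i regulates j).

#' Relevance network scores
#'
#' The simplest information-theoretic method: the score of a pair is its
#' estimated mutual information; thresholding is left to the evaluator.
#'
#' @param expr expression matrix/data.frame (rows = experiments).
#' @param bins MI estimator bins (default `ceiling(sqrt(N))`).
#' @return Symmetric score matrix.
#' @export
grn_relnet <- function(expr, bins = NULL) {
  M <- grn_mi(expr, bins)
  finalize_scores(unclass(M), "relnet", TRUE)
}

#' Context-likelihood-of-relatedness (CLR) scores
#'
#' Normalizes each pair's mutual information against the background of the
#' two genes' MI rows: with row mean \eqn{\mu_i} and standard deviation
#' \eqn{\sigma_i} (over all G entries, G-1 denominator),
#' \eqn{c_i = \max(0, (M_{ij} - \mu_i)/\sigma_i)} and the score is
#' \eqn{\sqrt{c_i^2 + c_j^2}}. Rows with zero MI spread contribute 0.
#'
#' @inheritParams grn_relnet
#' @return Symmetric score matrix.
#' @export
grn_clr <- function(expr, bins = NULL) {
  M <- grn_mi(expr, bins)
  finalize_scores(clr_from_mi(unclass(M)), "clr", TRUE)
}

clr_from_mi <- function(M) {
  G <- nrow(M)
  if (G < 3) abort_param("CLR needs at least 3 genes")
  mu <- rowMeans(M)
  sdv <- sqrt(rowSums((M - mu)^2) / (G - 1))
  Z <- (M - mu) / ifelse(sdv > 0, sdv, Inf)   # zero spread -> contribution 0
  Z[Z < 0] <- 0
  S <- sqrt(Z^2 + t(Z)^2)
  dimnames(S) <- dimnames(M)
  S
}

#' ARACNE scores (data-processing-inequality pruning)
#'
#' Starts from the mutual information matrix and, in every gene triplet,
#' removes the weakest pair — the one whose MI is below the smaller of the
#' other two by more than the tolerance `eps`. Surviving pairs keep their
#' MI as score.
#'
#' @inheritParams grn_relnet
#' @param eps DPI tolerance (default 0, strict pruning).
#' @return Symmetric score matrix.
#' @export
grn_aracne <- function(expr, bins = NULL, eps = 0) {
  M <- grn_mi(expr, bins)
  S <- dpi_prune(unclass(M), eps)
  dimnames(S) <- dimnames(M)
  finalize_scores(S, "aracne", TRUE)
}

#' C3NET scores (conservative causal core)
#'
#' Two steps: (1) zero all pairs whose mutual information falls below the
#' `1 - alpha` quantile of a permutation null (each gene's values permuted
#' independently, pooled off-diagonal MI over `n_perm` permutations);
#' (2) for each gene keep only its single strongest surviving pair. The
#' result is symmetrized by maximum, so at most G pairs are nonzero.
#'
#' @inheritParams grn_relnet
#' @param alpha significance level for the permutation null (default 0.05).
#' @param n_perm number of permutations (default 100).
#' @param seed seed for the permutation stream.
#' @return Symmetric score matrix with at most G nonzero pairs.
#' @export
grn_c3net <- function(expr, bins = NULL, alpha = 0.05, n_perm = 100, seed = 1L) {
  X <- as_expr_matrix(expr)
  N <- nrow(X); G <- ncol(X)
  if (G < 3) abort_param("C3NET needs at least 3 genes")
  B <- if (is.null(bins)) default_bins(N) else check_count(bins, "bins")
  D <- discretize_ef(X, B)
  M <- mi_from_bins(D, B)
  off <- upper.tri(M)
  genes <- colnames(X)
  null_vals <- vapply(seq_len(n_perm), function(b) {
    # per-gene permutation streams keyed by gene id: the pooled null (and
    # hence the threshold) is invariant to the input's column order
    Dp <- D
    for (g in seq_len(G)) {
      Dp[, g] <- with_seed(derive_seed(seed, "c3net", genes[g], b),
                           D[sample.int(N), g])
    }
    mi_from_bins(Dp, B)[off]
  }, numeric(sum(off)))
  thr <- quantile(null_vals, 1 - alpha, names = FALSE, type = 7)
  M[M < thr] <- 0
  diag(M) <- 0
  S <- matrix(0, G, G)
  for (i in seq_len(G)) {
    if (any(M[i, ] > 0)) {
      j <- which.max(M[i, ])
      S[i, j] <- M[i, j]
    }
  }
  S <- pmax(S, t(S))
  dimnames(S) <- list(colnames(X), colnames(X))
  finalize_scores(S, "c3net", TRUE)
}

#' MutRank scores
#'
#' Ranks, for every gene, its absolute Pearson correlation with all other
#' genes (rank 1 = strongest, average ranks on ties); the pair statistic is
#' \eqn{s_{ij} = r_{ij} r_{ji} / 2}. Because small ranks mean strong
#' association, the emitted confidence is `-s` so that higher = better.
#'
#' @inheritParams grn_relnet
#' @return Symmetric score matrix (values are negated mutual ranks).
#' @export
grn_mutrank <- function(expr) {
  X <- as_expr_matrix(expr)
  if (nrow(X) < 3) abort_param("MutRank needs at least 3 experiments")
  C <- abs(safe_cor(X))
  diag(C) <- NA
  G <- ncol(X)
  R <- matrix(0, G, G)
  for (i in seq_len(G)) {
    r <- rank(-C[i, -i], ties.method = "average")
    R[i, -i] <- r
  }
  S <- -(R * t(R)) / 2
  dimnames(S) <- list(colnames(X), colnames(X))
  finalize_scores(S, "mutrank", TRUE)
}

# Pearson correlation with constant genes mapped to 0 instead of NA.
safe_cor <- function(X) {
  C <- suppressWarnings(cor(X))
  C[!is.finite(C)] <- 0
  C
}

#' Zscore knockout scores
#'
#' Assumes interventional (knockout-style) data. The knocked-out gene of
#' experiment k is detected as the gene with the minimum value in that
#' experiment (first index on ties). The effect of detected gene i on gene
#' j is \eqn{z_{ij} = |(x_{jk} - \mu_j)/\sigma_j|} with \eqn{\mu_j,
#' \sigma_j} the mean and standard deviation of gene j over all
#' experiments. A gene detected in several experiments gets the mean of its
#' per-experiment score rows; genes never detected get zero rows.
#'
#' @inheritParams grn_relnet
#' @return Directed score matrix (row = putative knocked-out regulator).
#' @export
grn_zscore <- function(expr) {
  X <- as_expr_matrix(expr)
  N <- nrow(X); G <- ncol(X)
  if (N < 2) abort_param("Zscore needs at least 2 experiments")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  Z <- matrix(0, G, G)
  counts <- integer(G)
  for (k in seq_len(N)) {
    i <- which.min(X[k, ])
    z <- abs((X[k, ] - mu) / ifelse(sdv > 0, sdv, Inf))
    Z[i, ] <- Z[i, ] + z
    counts[i] <- counts[i] + 1L
  }
  nz <- counts > 0
  Z[nz, ] <- Z[nz, , drop = FALSE] / counts[nz]
  dimnames(Z) <- list(colnames(X), colnames(X))
  finalize_scores(Z, "zscore", FALSE)
}

#' MRNET scores (forward minimum-redundancy maximum-relevance)
#'
#' For every target gene, candidate regulators are selected greedily by the
#' MRMR criterion: the next gene maximizes `u = relevance - redundancy`,
#' where relevance is its MI with the target and redundancy the mean MI
#' with the genes already selected. Selection stops when the best `u`
#' drops to 0 or below; each selected gene scores its `u` at selection
#' time. The two directed matrices are symmetrized by maximum.
#'
#' @inheritParams grn_relnet
#' @return Symmetric score matrix.
#' @export
grn_mrnet <- function(expr, bins = NULL) {
  X <- as_expr_matrix(expr)
  # canonical gene order (and MI recomputed in that order) makes greedy
  # tie-breaks bitwise invariant to the input's column order
  ord <- order(colnames(X))
  M <- unclass(grn_mi(X[, ord, drop = FALSE], bins))
  S <- matrix(0, ncol(X), ncol(X))
  S[ord, ord] <- mrmr_forward(M)
  S <- pmax(S, t(S))
  dimnames(S) <- list(colnames(X), colnames(X))
  finalize_scores(S, "mrnet", TRUE)
}

mrmr_forward <- function(M) {
  G <- nrow(M)
  S <- matrix(0, G, G)
  for (t in seq_len(G)) {
    cand <- setdiff(seq_len(G), t)
    rel <- M[cand, t]
    red_sum <- numeric(length(cand))
    selected <- integer(0)
    repeat {
      u <- if (length(selected) == 0) rel else rel - red_sum / length(selected)
      u[match(selected, cand)] <- -Inf
      best <- which.max(u)
      if (u[best] <= 0) break
      g <- cand[best]
      S[g, t] <- u[best]
      selected <- c(selected, g)
      red_sum <- red_sum + M[cand, g]
      if (length(selected) == length(cand)) break
    }
  }
  S
}

#' MRNETB scores (backward elimination with sequential replacement)
#'
#' Per target, starts from all candidate regulators and removes whichever
#' gene most improves the set objective (sum of relevances minus mean
#' pairwise redundancy) until no removal helps; then swaps in-set and
#' out-set genes while any swap improves the objective. Final scores are
#' each retained gene's relevance minus its mean redundancy with the rest
#' of the retained set; symmetrized by maximum.
#'
#' @inheritParams grn_relnet
#' @return Symmetric score matrix.
#' @export
grn_mrnetb <- function(expr, bins = NULL) {
  X <- as_expr_matrix(expr)
  ord <- order(colnames(X))
  M <- unclass(grn_mi(X[, ord, drop = FALSE], bins))
  S <- matrix(0, ncol(X), ncol(X))
  S[ord, ord] <- mrmrb_backward(M)
  S <- pmax(S, t(S))
  dimnames(S) <- list(colnames(X), colnames(X))
  finalize_scores(S, "mrnetb", TRUE)
}

# Set objective: sum(relevance) - mean pairwise redundancy within the set.
mrmrb_objective <- function(M, t, set) {
  if (length(set) == 0) return(0)
  rel <- sum(M[set, t])
  if (length(set) < 2) return(rel)
  red <- (sum(M[set, set]) - sum(diag(M[set, set, drop = FALSE]))) /
    (length(set) * (length(set) - 1))
  rel - red
}

mrmrb_backward <- function(M) {
  G <- nrow(M)
  S <- matrix(0, G, G)
  sets <- vector("list", G)
  for (t in seq_len(G)) {
    cand <- setdiff(seq_len(G), t)
    # backward elimination: walk the full greedy removal trajectory from the
    # complete candidate set down to a single gene, keeping the best-scoring
    # set seen (the first local maximum can be arbitrarily poor)
    cur <- cand
    set <- cur
    obj <- mrmrb_objective(M, t, cur)
    while (length(cur) > 1) {
      objs <- vapply(seq_along(cur),
                     function(r) mrmrb_objective(M, t, cur[-r]), numeric(1))
      best <- which.max(objs)
      cur <- cur[-best]
      if (objs[best] > obj) { set <- cur; obj <- objs[best] }
    }
    # sequential replacement: accept any in/out swap, single addition, or
    # single removal that improves the objective, until a fixed point (each
    # accepted move strictly increases a bounded objective, so this stops)
    repeat {
      out <- setdiff(cand, set)
      improved <- FALSE
      for (r in seq_along(set)) {
        for (g in out) {
          o <- mrmrb_objective(M, t, c(set[-r], g))
          if (o > obj + 1e-15) {
            set <- c(set[-r], g); obj <- o; improved <- TRUE; break
          }
        }
        if (improved) break
      }
      if (!improved && length(out)) {
        for (g in out) {
          o <- mrmrb_objective(M, t, c(set, g))
          if (o > obj + 1e-15) { set <- c(set, g); obj <- o; improved <- TRUE; break }
        }
      }
      if (!improved && length(set) > 1) {
        for (r in seq_along(set)) {
          o <- mrmrb_objective(M, t, set[-r])
          if (o > obj + 1e-15) { set <- set[-r]; obj <- o; improved <- TRUE; break }
        }
      }
      if (!improved) break
    }
    sets[[t]] <- sort(set)
    for (g in set) {
      red <- if (length(set) > 1) mean(M[g, setdiff(set, g)]) else 0
      S[g, t] <- max(0, M[g, t] - red)
    }
  }
  attr(S, "sets") <- sets
  S
}

#' PCIT scores (partial-correlation information-theory pruning)
#'
#' Computes all pairwise Pearson correlations and, for every gene triplet,
#' the first-order partial correlations of each pair given the third gene.
#' The mean of the three |partial|/|marginal| ratios acts as a local
#' tolerance: a pair whose |r| falls below tolerance times both other
#' |r|'s is flagged non-significant in that triplet. Pairs flagged in every
#' triplet they share are zeroed; survivors score |r|.
#'
#' @inheritParams grn_relnet
#' @return Symmetric score matrix.
#' @export
grn_pcit <- function(expr) {
  X <- as_expr_matrix(expr)
  if (nrow(X) < 4) abort_param("PCIT needs at least 4 experiments")
  R <- safe_cor(X)
  S <- pcit_prune(R)
  dimnames(S) <- list(colnames(X), colnames(X))
  finalize_scores(S, "pcit", TRUE)
}

#' Shrinkage partial-correlation scores (GeneNet-style, undirected)
#'
#' Estimates the full-order partial correlation matrix from a
#' shrinkage-regularized correlation matrix (off-diagonal entries shrunk
#' toward zero with an analytic intensity, guaranteeing invertibility at
#' N < G) and scores each pair by |partial correlation|. The subsequent
#' causal-orientation step of the original heuristic is not implemented;
#' the output is undirected.
#'
#' @inheritParams grn_relnet
#' @param lambda optional fixed shrinkage intensity in \[0, 1\]; by default
#'   an analytic estimate from the variance of the correlation estimates.
#' @return Symmetric score matrix.
#' @export
grn_genenet <- function(expr, lambda = NULL) {
  X <- as_expr_matrix(expr)
  N <- nrow(X); G <- ncol(X)
  if (N < 3) abort_param("partial correlation needs at least 3 experiments")
  R <- safe_cor(X)
  if (is.null(lambda)) lambda <- shrinkage_intensity(X, R)
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  Om <- solve(Rs)
  P <- -Om / sqrt(diag(Om) %o% diag(Om))
  S <- abs(P)
  dimnames(S) <- list(colnames(X), colnames(X))
  finalize_scores(S, "genenet", TRUE)
}

# Ledoit-Wolf-style analytic shrinkage of off-diagonal correlations toward
# zero: lambda* = sum Var(r_ij) / sum r_ij^2, clamped to [0, 1].
shrinkage_intensity <- function(X, R) {
  N <- nrow(X)
  Xs <- scale(X)
  Xs[!is.finite(Xs)] <- 0
  num <- 0; den <- 0
  G <- ncol(X)
  W <- array(0, dim = c(G, G))
  # Var(r_ij) via the empirical variance of the products w_kij = x_ki x_kj
  XtX2 <- crossprod(Xs^2) # sum_k x_ki^2 x_kj^2
  S1 <- crossprod(Xs)     # sum_k x_ki x_kj = (N-1) r_ij
  varr <- (N / ((N - 1)^3)) * (XtX2 - S1^2 / N)
  off <- upper.tri(R)
  num <- sum(varr[off])
  den <- sum(R[off]^2)
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

#' Random-forest importance scores (Genie3-style)
#'
#' Solves one regression problem per target gene: a random forest predicts
#' the target from all other genes, and the total variance-reduction
#' (impurity) importance of each predictor is the directed confidence that
#' it regulates the target. Predictors are presented in lexicographic gene
#' order and per-target seeds are derived from the gene identifier, so the
#' output does not depend on the column order of the input.
#'
#' @inheritParams grn_relnet
#' @param n_trees trees per forest (default 500).
#' @param mtry candidate predictors per split (default
#'   `ceiling(sqrt(G - 1))`).
#' @param seed integer seed.
#' @return Directed score matrix (row = regulator, column = target).
#' @export
grn_genie3 <- function(expr, n_trees = 500, mtry = NULL, seed = 1L) {
  X <- as_expr_matrix(expr)
  N <- nrow(X); G <- ncol(X)
  if (G < 2) abort_param("genie3 needs at least 2 genes")
  genes <- colnames(X)
  ord <- order(genes)      # canonical predictor order: column-permutation invariant
  if (is.null(mtry)) mtry <- ceiling(sqrt(G - 1))
  S <- matrix(0, G, G, dimnames = list(genes, genes))
  for (t in seq_len(G)) {
    pred <- ord[ord != t]
    y <- X[, t]
    if (sd(y) == 0) next
    fit <- ranger::ranger(x = X[, pred, drop = FALSE], y = y,
                          num.trees = n_trees, mtry = min(mtry, G - 1L),
                          importance = "impurity", num.threads = 1,
                          seed = derive_seed(seed, "genie3", genes[t]),
                          splitrule = "variance")
    imp <- fit$variable.importance
    S[names(imp), genes[t]] <- pmax(0, imp)
  }
  finalize_scores(S, "genie3", FALSE)
}

#' Random baseline scores
#'
#' Independent uniform scores on every off-diagonal entry; the floor any
#' informative method must beat.
#'
#' @param expr expression matrix (only its gene set is used) or an integer
#'   gene count.
#' @param seed integer seed.
#' @return Directed score matrix of i.i.d. U(0, 1) entries.
#' @export
grn_random <- function(expr, seed = 1L) {
  if (is.numeric(expr) && length(expr) == 1) {
    G <- check_count(expr, "expr")
    genes <- paste0("G", seq_len(G))
  } else {
    X <- as_expr_matrix(expr)
    G <- ncol(X); genes <- colnames(X)
  }
  S <- with_seed(derive_seed(seed, "random"),
                 matrix(runif(G * G), G, G, dimnames = list(genes, genes)))
  finalize_scores(S, "random", FALSE)
}

# ---- method registry -------------------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Method registry
#'
#' All inference methods are dispatched through a registry keyed by short
#' names, so benchmark configurations can name them and user methods can be
#' plugged in. A registered function must accept `(expr, ...)` and return a
#' G x G numeric score matrix (higher = more confident, zero diagonal).
#'
#' @param name registry key.
#' @param fun method function `(expr, ...) -> score matrix`.
#' @return `grn_methods()` returns the sorted registry names;
#'   `grn_register_method()` returns `name` invisibly.
#' @export
grn_register_method <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, fun, envir = the_registry)
  invisible(name)
}

#' @rdname grn_register_method
#' @export
grn_methods <- function() sort(ls(the_registry))

#' Run a registered inference method
#'
#' @param expr expression matrix/data.frame (rows = experiments).
#' @param method registry name (see [grn_methods()]).
#' @param ... passed to the method.
#' @return Score matrix.
#' @export
grn_infer <- function(expr, method, ...) {
  if (!exists(method, envir = the_registry, inherits = FALSE))
    abort_param(sprintf("unknown method \"%s\"; registered: %s",
                        method, paste(grn_methods(), collapse = ", ")))
  fun <- get(method, envir = the_registry)
  fun(expr, ...)
}

register_builtin_methods <- function() {
  grn_register_method("relnet", grn_relnet)
  grn_register_method("clr", grn_clr)
  grn_register_method("aracne", grn_aracne)
  grn_register_method("c3net", grn_c3net)
  grn_register_method("mutrank", grn_mutrank)
  grn_register_method("zscore", function(expr, ...) grn_zscore(expr))
  grn_register_method("mrnet", grn_mrnet)
  grn_register_method("mrnetb", grn_mrnetb)
  grn_register_method("pcit", function(expr, ...) grn_pcit(expr))
  grn_register_method("genenet", grn_genenet)
  grn_register_method("genie3", grn_genie3)
  grn_register_method("random", grn_random)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_methods()
}
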