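# Independent brute-force oracles for the inference formulas and the
# evaluation protocol. These re-derive every quantity from first principles
# (nested loops, exhaustive enumeration) and share no code with the package
# internals they check.

# Plug-in mutual information of two pre-binned vectors, in bits.
oracle_mi_pair <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (x in unique(a)) for (y in unique(b)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  mi
}

# Equal-frequency bins, re-derived (same convention: average-tie ranks).
oracle_bins <- function(v, B) {
  r <- rank(v, ties.method = "average")
  pmin(B, as.integer(ceiling(r / length(v) * B)))
}

oracle_mi_matrix <- function(X, B) {
  G <- ncol(X)
  D <- sapply(seq_len(G), function(g) oracle_bins(X[, g], B))
  M <- matrix(0, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i != j) M[i, j] <- oracle_mi_pair(D[, i], D[, j])
  }
  M
}

# CLR from an MI matrix: literal evaluation of the row-statistics formulas.
oracle_clr <- function(M) {
  G <- nrow(M)
  S <- matrix(0, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i == j) next
    mu_i <- mean(M[i, ]); sd_i <- sqrt(sum((M[i, ] - mu_i)^2) / (G - 1))
    mu_j <- mean(M[j, ]); sd_j <- sqrt(sum((M[j, ] - mu_j)^2) / (G - 1))
    ci <- if (sd_i > 0) max(0, (M[i, j] - mu_i) / sd_i) else 0
    cj <- if (sd_j > 0) max(0, (M[j, i] - mu_j) / sd_j) else 0
    S[i, j] <- sqrt(ci^2 + cj^2)
  }
  S
}

# ARACNE DPI by exhaustive triplet enumeration.
oracle_aracne <- function(M, eps = 0) {
  G <- nrow(M)
  keep <- matrix(TRUE, G, G)
  combs <- utils::combn(G, 3)
  for (c in seq_len(ncol(combs))) {
    i <- combs[1, c]; j <- combs[2, c]; k <- combs[3, c]
    if (M[i, j] < min(M[i, k], M[j, k]) - eps) keep[i, j] <- keep[j, i] <- FALSE
    if (M[i, k] < min(M[i, j], M[j, k]) - eps) keep[i, k] <- keep[k, i] <- FALSE
    if (M[j, k] < min(M[i, j], M[i, k]) - eps) keep[j, k] <- keep[k, j] <- FALSE
  }
  S <- M * keep
  diag(S) <- 0
  S
}

# MutRank: literal ranking of absolute correlations, r_ij * r_ji / 2,
# negated to the higher-is-better convention.
oracle_mutrank <- function(X) {
  G <- ncol(X)
  C <- abs(suppressWarnings(cor(X)))
  C[!is.finite(C)] <- 0
  R <- matrix(0, G, G)
  for (i in seq_len(G)) {
    others <- setdiff(seq_len(G), i)
    R[i, others] <- rank(-C[i, others], ties.method = "average")
  }
  S <- matrix(0, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i != j) S[i, j] <- -(R[i, j] * R[j, i]) / 2
  }
  S
}

# Zscore: literal per-experiment evaluation with argmin knockout detection.
oracle_zscore <- function(X) {
  N <- nrow(X); G <- ncol(X)
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  rows <- vector("list", G)
  for (k in seq_len(N)) {
    i <- which(X[k, ] == min(X[k, ]))[1]
    z <- numeric(G)
    for (j in seq_len(G)) z[j] <- if (sdv[j] > 0) abs((X[k, j] - mu[j]) / sdv[j]) else 0
    rows[[i]] <- rbind(rows[[i]], z)
  }
  S <- matrix(0, G, G)
  for (i in seq_len(G)) if (!is.null(rows[[i]])) S[i, ] <- colMeans(rows[[i]])
  diag(S) <- 0
  S
}

# Forward MRMR selection re-derived step by step from the MI matrix.
oracle_mrnet <- function(M) {
  G <- nrow(M)
  S <- matrix(0, G, G)
  for (t in seq_len(G)) {
    cand <- setdiff(seq_len(G), t)
    sel <- integer(0)
    repeat {
      rem <- setdiff(cand, sel)
      if (!length(rem)) break
      u <- sapply(rem, function(g) {
        red <- if (length(sel)) mean(M[g, sel]) else 0
        M[g, t] - red
      })
      if (max(u) <= 0) break
      g <- rem[which.max(u)]
      S[g, t] <- max(u)
      sel <- c(sel, g)
    }
  }
  pmax(S, t(S))
}

# PCIT: exhaustive-triplet reimplementation of the tolerance rule.
oracle_pcit <- function(X) {
  C <- suppressWarnings(cor(X)); C[!is.finite(C)] <- 0
  G <- ncol(X)
  if (G < 3) { S <- abs(C); diag(S) <- 0; return(S) }
  flagged_everywhere <- matrix(TRUE, G, G)
  in_triplet <- matrix(FALSE, G, G)
  pc <- function(rij, rik, rjk) {
    den <- (1 - rik^2) * (1 - rjk^2)
    (rij - rik * rjk) / sqrt(max(den, 1e-12))
  }
  rat <- function(p, m) if (abs(m) < 1e-12) 1 else min(1, abs(p) / abs(m))
  combs <- utils::combn(G, 3)
  for (c in seq_len(ncol(combs))) {
    i <- combs[1, c]; j <- combs[2, c]; k <- combs[3, c]
    pij <- pc(C[i, j], C[i, k], C[j, k])
    pik <- pc(C[i, k], C[i, j], C[j, k])
    pjk <- pc(C[j, k], C[i, j], C[i, k])
    eps <- (rat(pij, C[i, j]) + rat(pik, C[i, k]) + rat(pjk, C[j, k])) / 3
    pairs <- list(c(i, j, k), c(i, k, j), c(j, k, i))
    rs <- list(c(C[i, j], C[i, k], C[j, k]), c(C[i, k], C[i, j], C[j, k]),
               c(C[j, k], C[i, j], C[i, k]))
    for (q in 1:3) {
      a <- pairs[[q]][1]; b <- pairs[[q]][2]
      in_triplet[a, b] <- in_triplet[b, a] <- TRUE
      flag <- abs(rs[[q]][1]) < eps * abs(rs[[q]][2]) &&
              abs(rs[[q]][1]) < eps * abs(rs[[q]][3])
      if (!flag) flagged_everywhere[a, b] <- flagged_everywhere[b, a] <- FALSE
    }
  }
  S <- abs(C)
  S[in_triplet & flagged_everywhere] <- 0
  diag(S) <- 0
  S
}

# Full-order partial correlation from an invertible correlation matrix.
oracle_partial_cor <- function(R) {
  Om <- solve(R)
  P <- matrix(0, nrow(R), ncol(R))
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R)))
    if (i != j) P[i, j] <- -Om[i, j] / sqrt(Om[i, i] * Om[j, j])
  P
}

# Naive top-t evaluation: explicit enumeration of candidate pairs.
oracle_evaluate <- function(S, A, top_fraction, directed) {
  G <- nrow(S)
  cand <- list()
  if (directed) {
    for (i in seq_len(G)) for (j in seq_len(G)) {
      if (i != j) cand[[length(cand) + 1]] <-
          list(score = S[i, j], true = A[i, j] == 1,
               key = (j - 1) * G + i)  # column-major order = package tie-break
    }
  } else {
    for (i in seq_len(G - 1)) for (j in (i + 1):G) {
      cand[[length(cand) + 1]] <-
        list(score = max(S[i, j], S[j, i]), true = (A[i, j] + A[j, i]) > 0,
             key = (j - 1) * G + i)
    }
  }
  scores <- sapply(cand, `[[`, "score")
  keys <- sapply(cand, `[[`, "key")
  truth <- sapply(cand, `[[`, "true")
  ord <- order(-scores, keys)
  n_cand <- length(cand)
  t_eval <- max(1, floor(top_fraction * n_cand + 0.5))
  P <- sum(truth)
  tp <- cumsum(truth[ord])[seq_len(t_eval)]
  rank <- seq_len(t_eval)
  fp <- rank - tp
  list(t = t_eval, tp = tp, fp = fp,
       precision = tp / rank,
       recall = tp / P,
       fpr = fp / (n_cand - P),
       P = P, n_cand = n_cand)
}

oracle_aupr <- function(ev) {
  r <- c(0, ev$recall); p <- c(ev$precision[1], ev$precision)
  area <- 0
  for (q in 2:length(r)) area <- area + (r[q] - r[q - 1]) * (p[q] + p[q - 1]) / 2
  if (max(r) == 0) 0 else area / max(r)
}

oracle_auroc <- function(ev) {
  tpr <- c(0, ev$recall); fpr <- c(0, ev$fpr)
  if (!all(is.finite(fpr)) || max(fpr) == 0) return(1)
  area <- 0
  for (q in 2:length(fpr)) area <- area + (fpr[q] - fpr[q - 1]) * (tpr[q] + tpr[q - 1]) / 2
  area / max(fpr)
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# choose(n1+n2, n1) group assignments.
oracle_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(all_v), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(all_v) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
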