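# Formula-level checks of every inference method against independent
# brute-force oracles, plus the shared score-matrix contract.

symmetric_methods <- c("relnet", "clr", "aracne", "c3net", "mutrank", "pcit", "genenet")

test_that("CLR matches a literal evaluation of its normalization formulas", {
  for (s in 1:10) {
    M <- random_mi_matrix(5, seed = s)
    expect_equal(unname(grnbench:::clr_from_mi(M)), oracle_clr(M), tolerance = 1e-12)
  }
  # an MI entry equal to its row mean contributes 0 from that side
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 0.5; M[1, 3] <- M[3, 1] <- 0.5; M[2, 3] <- M[3, 2] <- 0.2
  # row 1 mean over (0, .5, .5) is 1/3; entries above it -> positive c
  S <- oracle_clr(M)
  expect_true(all(abs(S - t(S)) < 1e-14))
})

test_that("ARACNE pruning equals exhaustive triplet enumeration", {
  for (s in 1:10) {
    M <- random_mi_matrix(6, seed = 100 + s)
    got <- grnbench:::dpi_prune(M, 0)
    expect_equal(got, oracle_aracne(M, 0), tolerance = 1e-12)
  }
  # canonical triangle: the weakest of the single triplet is removed
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 0.9; M[2, 3] <- M[3, 2] <- 0.5; M[1, 3] <- M[3, 1] <- 0.2
  out <- grnbench:::dpi_prune(M, 0)
  expect_equal(out[1, 3], 0)
  expect_equal(out[1, 2], 0.9)
  expect_equal(out[2, 3], 0.5)
})

test_that("MutRank matches the mutual-rank product formula", {
  for (s in 1:8) {
    X <- random_expr(G = 5, N = 15, seed = 300 + s)
    expect_equal(unname(unclass(grn_mutrank(X))), oracle_mutrank(X),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # two genes: single candidate each, mutual rank product 1*1/2
  X <- random_expr(G = 2, N = 10, seed = 1)
  expect_equal(grn_mutrank(X)[1, 2], -0.5)
})

test_that("Zscore matches per-experiment hand evaluation with argmin detection", {
  X <- matrix(c(0.0, 5.0, 4.0,
                6.0, 0.5, 7.0,
                5.0, 6.0, 1.0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("E", 1:3), paste0("G", 1:3)))
  expect_equal(unname(unclass(grn_zscore(X))), oracle_zscore(X),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (s in 1:8) {
    X <- random_expr(G = 6, N = 12, seed = 400 + s)
    expect_equal(unname(unclass(grn_zscore(X))), oracle_zscore(X),
               tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("Zscore averages rows over repeated detections and zeroes mean-level targets", {
  # gene 1 is the minimum in experiments 1 and 2
  X <- matrix(c(-9, 1.0, 2.0,
                -7, 3.0, 1.0,
                 5, 0.0, 6.0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("E", 1:3), paste0("G", 1:3)))
  Z <- grn_zscore(X)
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  manual <- (abs((X[1, ] - mu) / sdv) + abs((X[2, ] - mu) / sdv)) / 2
  expect_equal(unname(Z[1, -1]), unname(manual[-1]), tolerance = 1e-12)
  # a target sitting exactly at its own mean scores zero
  Y <- matrix(c(0, 5,
                4, 5,
                8, 5), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("E", 1:3), paste0("G", 1:2)))
  expect_equal(grn_zscore(Y)[1, 2], 0)
})

test_that("MRNET forward selection matches exhaustive MRMR recomputation", {
  for (s in 1:10) {
    M <- random_mi_matrix(4, seed = 500 + s)
    got <- grnbench:::mrmr_forward(M)
    expect_equal(pmax(got, t(got)), oracle_mrnet(M), tolerance = 1e-12)
  }
})

test_that("MRNET degenerates to MI at G = 2 and skips redundant genes", {
  X <- random_expr(G = 2, N = 20, seed = 2)
  M <- grn_mi(X)
  expect_equal(grn_mrnet(X)[1, 2], M[1, 2])
  # perfectly redundant duplicate: selected second gene has u <= 0
  M3 <- matrix(0, 3, 3)
  M3[1, 3] <- M3[3, 1] <- 0.8          # gene 1 relevant to target 3
  M3[2, 3] <- M3[3, 2] <- 0.8          # gene 2 equally relevant
  M3[1, 2] <- M3[2, 1] <- 0.9          # but redundant with gene 1
  S <- grnbench:::mrmr_forward(M3)
  # for target 3: first pick scores 0.8, second gene u = 0.8 - 0.9 < 0
  expect_equal(sort(S[, 3])[3], 0.8)
  expect_equal(sum(S[, 3] > 0), 1)
})

test_that("MRNETB reaches at least the forward-selection objective", {
  for (s in 1:10) {
    M <- random_mi_matrix(4, seed = 600 + s)
    fwd <- grnbench:::mrmr_forward(M)
    bwd <- grnbench:::mrmrb_backward(M)
    for (t in 1:4) {
      fset <- which(fwd[, t] > 0)
      bset <- attr(bwd, "sets")[[t]]
      expect_gte(grnbench:::mrmrb_objective(M, t, bset) + 1e-12,
                 grnbench:::mrmrb_objective(M, t, fset))
    }
  }
  # G = 2: identical to mrnet
  X <- random_expr(G = 2, N = 20, seed = 3)
  expect_equal(unclass(grn_mrnetb(X)), unclass(grn_mrnet(X)), ignore_attr = TRUE)
})

test_that("PCIT matches the exhaustive-triplet reimplementation", {
  for (s in 1:10) {
    X <- random_expr(G = 5, N = 30, seed = 700 + s)
    expect_equal(unname(unclass(grn_pcit(X))), oracle_pcit(X),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("PCIT prunes the indirect pair of a moderate Gaussian chain", {
  set.seed(8)
  N <- 5000
  a <- rnorm(N)
  b <- 0.6 * a + rnorm(N) * sqrt(1 - 0.36)
  c <- 0.6 * b + rnorm(N) * sqrt(1 - 0.36)
  X <- cbind(G1 = a, G2 = b, G3 = c)
  S <- grn_pcit(X)
  expect_equal(S[1, 3], 0)
  expect_gt(S[1, 2], 0.5)
  expect_gt(S[2, 3], 0.5)
})

test_that("shrinkage partial correlation matches the inverse-correlation closed form", {
  # 3 genes, large N, lambda = 0: partial correlation from the inverse
  X <- random_expr(G = 3, N = 2000, seed = 5)
  X[, 2] <- X[, 1] * 0.5 + X[, 2]
  X[, 3] <- X[, 2] * 0.5 + X[, 3]
  S <- grn_genenet(X, lambda = 0)
  P <- oracle_partial_cor(cor(X))
  expect_equal(unname(unclass(S)), abs(P), tolerance = 1e-10, ignore_attr = TRUE)
  # independent genes: everything near zero
  Y <- random_expr(G = 10, N = 5000, seed = 6)
  expect_lt(max(unclass(grn_genenet(Y))), 0.08)
})

test_that("C3NET keeps at most G edges and retains row maxima of significant MI", {
  for (s in 1:15) {
    X <- random_expr(G = sample(4:12, 1), N = 25, seed = 800 + s)
    S <- grn_c3net(X, seed = s)
    G <- ncol(X)
    expect_lte(sum(S[upper.tri(S)] > 0), G)
    expect_equal(unclass(S), t(unclass(S)), ignore_attr = TRUE)
  }
  # dominant dependent pair survives across seeds
  for (s in 1:10) {
    set.seed(s)
    z <- rnorm(60)
    X <- cbind(G1 = z, G2 = z + rnorm(60, 0, 0.05),
               G3 = rnorm(60), G4 = rnorm(60))
    S <- grn_c3net(X, alpha = 0.05, seed = s)
    expect_gt(S[1, 2], 0)
    top <- which(S == max(S), arr.ind = TRUE)
    expect_true(all(sort(top[1, ]) == c(1, 2)))
  }
})

test_that("genie3 finds a dominant regressor, is seeded, and beats noise targets", {
  set.seed(31)
  N <- 60
  X <- matrix(rnorm(N * 5), N, 5, dimnames = list(NULL, paste0("G", 1:5)))
  X[, 2] <- X[, 1] + rnorm(N, 0, 0.01)   # G1 essentially determines G2
  S1 <- grn_genie3(X, n_trees = 100, seed = 4)
  expect_gt(S1["G1", "G2"], max(S1[c("G3", "G4", "G5"), "G2"]))
  # pure-noise target: importances far below the dominant-predictor one
  expect_gt(S1["G1", "G2"], 2 * max(S1[-3, "G3"]))
  expect_identical(unclass(S1), unclass(grn_genie3(X, n_trees = 100, seed = 4)))
})

test_that("random baseline is seeded and its precision tracks gold density", {
  S1 <- grn_random(30, seed = 2)
  expect_identical(unclass(S1), unclass(grn_random(30, seed = 2)))
  gold <- random_gold(100, 495, seed = 9, dag = FALSE)
  vals <- sapply(1:50, function(s)
    aupr_top(grn_evaluate(grn_random(100, seed = s), gold,
                          eval_spec(0.2, directed = TRUE))))
  expect_lt(abs(mean(vals) - 0.05) / 0.05, 0.25)
})

test_that("all methods satisfy the score-matrix contract on one dataset", {
  ds <- small_multifactorial_source(G = 12, E = 15, N = 30, seed = 21)
  builtin <- c("aracne", "c3net", "clr", "genenet", "genie3", "mrnet",
               "mrnetb", "mutrank", "pcit", "random", "relnet", "zscore")
  for (m in builtin) {
    S <- switch(m,
                genie3 = grn_infer(ds$expr, m, n_trees = 50, seed = 1),
                grn_infer(ds$expr, m))
    expect_true(is.matrix(S) && all(dim(S) == 12), info = m)
    expect_true(all(is.finite(S)), info = m)
    expect_equal(unname(diag(S)), rep(0, 12), info = m)
    expect_identical(colnames(S), ds$gold$genes, info = m)
    if (m %in% symmetric_methods)
      expect_equal(unclass(S), t(unclass(S)), ignore_attr = TRUE, info = m)
  }
})

test_that("permuting gene columns permutes scores identically", {
  ds <- small_multifactorial_source(G = 8, E = 10, N = 25, seed = 22)
  X <- ds$expr
  perm <- c(3, 1, 5, 2, 8, 6, 4, 7)
  Xp <- X[, perm]
  for (m in c("clr", "mutrank", "zscore", "pcit", "genenet", "mrnet", "genie3")) {
    args <- if (m == "genie3") list(n_trees = 50, seed = 3) else list()
    S <- do.call(grn_infer, c(list(X, m), args))
    Sp <- do.call(grn_infer, c(list(Xp, m), args))
    expect_equal(unclass(Sp), unclass(S)[perm, perm],
                 tolerance = 1e-12, ignore_attr = TRUE, info = m)
  }
})

test_that("the registry dispatches, lists, and rejects unknown names", {
  expect_true(all(c("aracne", "c3net", "clr", "genenet", "genie3", "mutrank",
                    "mrnet", "mrnetb", "pcit", "zscore", "random") %in% grn_methods()))
  expect_error(grn_infer(random_expr(3, 10, 1), "nonesuch"), "unknown method")
  grn_register_method("plugin_test", function(expr, ...) {
    X <- as.matrix(expr)
    S <- abs(cor(X)); diag(S) <- 0; S
  })
  expect_true("plugin_test" %in% grn_methods())
  S <- grn_infer(random_expr(4, 20, 2), "plugin_test")
  expect_equal(dim(S), c(4, 4))
})
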