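make_tiny_bench <- function(methods = c("clr", "random"), seed = 5,
                            datasets = 3, nexp = 25) {
  src1 <- small_multifactorial_source(G = 20, E = 25, N = 60, seed = 31)
  src1$name <- "mfA"
  src2 <- small_multifactorial_source(G = 15, E = 18, N = 60, seed = 32)
  src2$name <- "mfB"
  bench_config(list(mfA = src1, mfB = src2), methods,
               datasets_per_source = datasets, experiments_per_dataset = nexp,
               noise = noise_spec(10, 5), seed = seed)
}

test_that("benchmark grids are complete, reproducible, and summarized", {
  cfg <- make_tiny_bench()
  bm <- grn_benchmark(cfg)
  expect_equal(nrow(bm$results), 2 * 2 * 3)  # sources x methods x datasets
  expect_true(all(!is.na(bm$results$aupr)))
  expect_equal(nrow(bm$summary), 4)
  bm2 <- grn_benchmark(cfg)
  expect_identical(bm$results, bm2$results)
  # informative method beats the random floor on these noise-light sources
  s <- bm$summary
  for (src in c("mfA", "mfB")) {
    expect_gt(s$mean_aupr[s$datasource == src & s$method == "clr"],
              s$mean_aupr[s$datasource == src & s$method == "random"])
  }
})

test_that("random-only benchmark means approximate the gold densities", {
  src <- small_multifactorial_source(G = 20, E = 30, N = 50, seed = 41)
  src$name <- "m"
  cfg <- bench_config(list(m = src), "random", datasets_per_source = 30,
                      experiments_per_dataset = 20, noise = noise_spec(0, 0),
                      seed = 2)
  bm <- grn_benchmark(cfg)
  A <- src$gold$adjacency
  dens <- sum((A + t(A))[upper.tri(A)] > 0) / (20 * 19 / 2)
  expect_lt(abs(bm$summary$mean_aupr - dens) / dens, 0.5)
})

test_that("a failing method becomes missing cells, not a crash", {
  grn_register_method("always_fails", function(expr, ...) stop("boom"))
  src <- small_multifactorial_source(G = 10, E = 12, N = 30, seed = 51)
  src$name <- "m"
  cfg <- bench_config(list(m = src), c("random", "always_fails"),
                      datasets_per_source = 2, experiments_per_dataset = 15,
                      seed = 3)
  bm <- suppressWarnings(grn_benchmark(cfg))
  expect_true(all(is.na(bm$results$aupr[bm$results$method == "always_fails"])))
  expect_true(all(!is.na(bm$results$aupr[bm$results$method == "random"])))
})

test_that("rank-sum p-values match exhaustive permutation enumeration", {
  set.seed(61)
  for (trial in 1:10) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- round(rnorm(n1), 3); y <- round(rnorm(n2, 0.5), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(grnbench:::rank_sum_p(x, y), oracle_ranksum_p(x, y),
                 tolerance = 1e-10)
  }
  # complete separation at n = 10 vs 10: the two extreme assignments
  expect_equal(grnbench:::rank_sum_p(1:10, 11:20), 2 / choose(20, 10),
               tolerance = 1e-12)
  # identical constant samples
  expect_equal(grnbench:::rank_sum_p(rep(1, 5), rep(1, 5)), 1)
})

test_that("winner flags include the top method and its statistical equals", {
  res <- tibble::tibble(
    datasource = "d",
    method = rep(c("a", "b", "c"), each = 10),
    dataset = rep(1:10, 3),
    aupr = c(seq(0.8, 0.9, length.out = 10),    # a: top
             seq(0.79, 0.91, length.out = 10),  # b: indistinguishable
             seq(0.1, 0.2, length.out = 10)))   # c: clearly worse
  fw <- flag_winners(res, alpha = 0.05)
  expect_true(fw$winner[fw$method == "a"])
  expect_true(fw$winner[fw$method == "b"])
  expect_false(fw$winner[fw$method == "c"])
  # identical vectors are always co-flagged
  res2 <- tibble::tibble(datasource = "d", method = rep(c("a", "b"), each = 5),
                         dataset = rep(1:5, 2), aupr = rep(c(1, 2, 3, 4, 5) / 10, 2))
  fw2 <- flag_winners(res2)
  expect_true(all(fw2$winner))
})

test_that("rank aggregation follows the average-tie convention", {
  sm <- tibble::tibble(
    datasource = rep(c("d1", "d2", "d3"), each = 3),
    method = rep(c("a", "b", "c"), 3),
    mean_aupr = c(0.9, 0.5, 0.1,   # d1: a > b > c
                  0.8, 0.8, 0.1,   # d2: a, b tied
                  0.7, 0.2, 0.1))  # d3: a > b > c
  ag <- aggregate_ranks(sm)
  ra <- ag$ranks
  expect_equal(ra$rank[ra$method == "a"], c(1, 1.5, 1))
  expect_equal(ra$rank[ra$method == "b"], c(2, 1.5, 2))
  expect_equal(ra$rank[ra$method == "c"], c(3, 3, 3))
  expect_equal(ag$summary$median[ag$summary$method == "a"], 1)
})

test_that("noise sweep reuses subsample draws and spans the kappa grid", {
  src <- small_multifactorial_source(G = 15, E = 18, N = 50, seed = 71)
  src$name <- "m"
  cfg <- bench_config(list(m = src), c("clr", "random"), datasets_per_source = 2,
                      experiments_per_dataset = 20, seed = 4)
  sw <- grn_noise_sweep(cfg, kappas = c(0, 50))
  expect_equal(sort(unique(sw$grid$kappa)), c(0, 50))
  expect_equal(nrow(sw$grid), 2 * 2)
  # kappa = 0 equals a noise-free benchmark with the same seeds
  cfg0 <- cfg; cfg0$noise <- noise_spec(0, 0)
  bm0 <- grn_benchmark(cfg0)
  expect_identical(sw$levels[["0"]]$results, bm0$results)
})

test_that("experiments sweep marks infeasible sizes and keeps running", {
  src <- small_multifactorial_source(G = 12, E = 15, N = 30, seed = 81)
  src$name <- "m"
  cfg <- bench_config(list(m = src), "random", datasets_per_source = 2, seed = 5)
  sw <- grn_experiments_sweep(cfg, n_experiments = c(10, 100))
  g10 <- sw$grid[sw$grid$n == 10, ]
  g100 <- sw$grid[sw$grid$n == 100, ]
  expect_true(all(g10$feasible))
  expect_true(all(!g100$feasible))
  expect_true(all(!is.na(g10$mean_aupr)))
})

test_that("benchmark tidiers and plots expose the study artifacts", {
  bm <- grn_benchmark(make_tiny_bench(datasets = 2, nexp = 20))
  expect_s3_class(tidy(bm), "tbl_df")
  gl <- glance(bm)
  expect_true(all(c("mean_aupr", "winner", "rank") %in% names(gl)))
  expect_s3_class(autoplot(bm), "ggplot")
})
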