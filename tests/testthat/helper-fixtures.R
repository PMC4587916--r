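# Shared fixture builders: small random instances under fixed seeds.

random_expr <- function(G, N, seed) {
  set.seed(seed)
  X <- matrix(rnorm(N * G), N, G)
  colnames(X) <- paste0("G", seq_len(G))
  rownames(X) <- paste0("E", seq_len(N))
  X
}

random_mi_matrix <- function(G, seed) {
  set.seed(seed)
  M <- matrix(runif(G * G), G, G)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

random_gold <- function(G, E, seed, dag = TRUE) {
  if (dag) return(grn_powerlaw_topology(G, E, seed = seed))
  set.seed(seed)
  A <- matrix(0L, G, G)
  off <- which(diag(G) == 0)
  A[sample(off, E)] <- 1L
  gold_standard(A)
}

small_knockout_source <- function(G = 20, E = 25, seed = 1) {
  grn_simulate_knockouts(grn_powerlaw_topology(G, E, seed = seed), seed = seed)
}

small_multifactorial_source <- function(G = 20, E = 25, N = 40, seed = 1) {
  grn_simulate_multifactorial(grn_powerlaw_topology(G, E, seed = seed),
                              n_experiments = N, seed = seed)
}

tiny_config_yaml <- function(path, seed = 7, methods = c("clr", "random"),
                             genes = 25, edges = 30, experiments = 60,
                             datasets = 2, n_per_dataset = 30) {
  yaml::write_yaml(list(
    seed = seed,
    datasources = list(
      list(name = "mf_small", kind = "multifactorial", genes = genes,
           edges = edges, experiments = experiments)),
    benchmark = list(
      methods = as.list(methods),
      datasets.num = datasets,
      experiments = n_per_dataset,
      local.noise = 20,
      global.noise = 10,
      noiseType = "normal",
      top.fraction = 0.2)), path)
  path
}
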