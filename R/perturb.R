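#' Noise specification
#'
#' Describes the contamination applied to a dataset: a per-gene "local"
#' component whose standard deviation is a percentage `kappa_local` of that
#' gene's standard deviation, and a dataset-wide "global" component whose
#' standard deviation is a percentage `kappa_global` of the mean of the
#' per-gene standard deviations. Each realized percentage is drawn
#' uniformly in a band of half-width `range_fraction` around kappa
#' (default 0.2, i.e. `U(0.8*kappa, 1.2*kappa)` — a 40% total range), so
#' replicate datasets have slightly different signal-to-noise ratios, as
#' across microarray labs. Either component can be Gaussian or zero-mean
#' lognormal.
#'
#' @param kappa_local local noise percentage (>= 0).
#' @param kappa_global global noise percentage (>= 0).
#' @param range_fraction half-width of the uniform band as a fraction of
#'   kappa, in [0, 1).
#' @param local_type,global_type `"normal"` or `"lognormal"`.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(kappa_local = 20, kappa_global = 10, range_fraction = 0.2,
                       local_type = c("normal", "lognormal"),
                       global_type = c("lognormal", "normal")) {
  if (!is.numeric(kappa_local) || kappa_local < 0) abort_param("`kappa_local` must be >= 0")
  if (!is.numeric(kappa_global) || kappa_global < 0) abort_param("`kappa_global` must be >= 0")
  if (!is.numeric(range_fraction) || range_fraction < 0 || range_fraction >= 1)
    abort_param("`range_fraction` must be in [0, 1)")
  structure(list(kappa_local = kappa_local, kappa_global = kappa_global,
                 range_fraction = range_fraction,
                 local_type = match.arg(local_type),
                 global_type = match.arg(global_type)),
            class = "noise_spec")
}

#' Subsample a datasource into replicate datasets
#'
#' Draws `n_datasets` independent without-replacement subsets of
#' `n_experiments` rows from a datasource. An experiment never repeats
#' within one dataset but may appear in several datasets. Deterministic
#' given `seed`; the subsampling stream is independent of the noise stream
#' so noise sweeps can reuse identical draws.
#'
#' @param ds a `grn_datasource`.
#' @param n_experiments rows per dataset (<= the datasource's experiment
#'   count).
#' @param n_datasets number of replicate datasets.
#' @param seed integer seed.
#' @return A list of `grn_dataset` objects with fields `expr`,
#'   `source_name`, `experiment_indices`, `noise` (`NULL` until
#'   [grn_add_noise()]) and `seed`.
#' @export
grn_subsample <- function(ds, n_experiments, n_datasets = 1L, seed = 1L) {
  stopifnot(inherits(ds, "grn_datasource"))
  n_experiments <- check_count(n_experiments, "n_experiments")
  n_datasets <- check_count(n_datasets, "n_datasets")
  N <- nrow(ds$expr)
  if (n_experiments > N)
    abort_param(sprintf("cannot subsample %d experiments from a datasource with %d",
                        n_experiments, N))
  lapply(seq_len(n_datasets), function(d) {
    idx <- with_seed(derive_seed(seed, "subsample", ds$name, d),
                     sample.int(N, n_experiments))
    structure(list(expr = ds$expr[idx, , drop = FALSE],
                   source_name = ds$name,
                   experiment_indices = idx,
                   noise = NULL,
                   seed = as.integer(seed)),
              class = "grn_dataset")
  })
}

#' @export
print.grn_dataset <- function(x, ...) {
  cat(sprintf("<grn_dataset> from \"%s\": %d experiments x %d genes, noise %s\n",
              x$source_name, nrow(x$expr), ncol(x$expr),
              if (is.null(x$noise)) "none"
              else sprintf("local %g%% (%s) + global %g%% (%s)",
                           x$noise$spec$kappa_local, x$noise$spec$local_type,
                           x$noise$spec$kappa_global, x$noise$spec$global_type)))
  invisible(x)
}

#' Per-gene local noise standard deviations
#'
#' Scales each gene's standard deviation `sigma_g` by an independent
#' uniform draw in the band `[ (1-r)*kappa, (1+r)*kappa ] / 100`, giving
#' every gene a similar signal-to-noise ratio while adding mild
#' heterogeneity.
#'
#' @param sigma_g nonnegative per-gene standard deviations.
#' @param kappa local noise percentage.
#' @param range_fraction band half-width fraction (default 0.2).
#' @return Per-gene noise standard deviations (0 for constant genes or
#'   `kappa = 0`).
#' @export
local_noise_sd <- function(sigma_g, kappa, range_fraction = 0.2) {
  if (any(sigma_g < 0)) abort_param("`sigma_g` must be nonnegative")
  if (kappa < 0) abort_param("`kappa` must be >= 0")
  u <- runif(length(sigma_g), (1 - range_fraction) * kappa, (1 + range_fraction) * kappa)
  sigma_g * u / 100
}

# Zero-mean noise draws with a prescribed standard deviation. Lognormal
# draws use meanlog 0 and the sdlog solving the target sd, then subtract
# the distribution mean so contamination does not shift the signal.
draw_noise <- function(n, sd, type) {
  if (sd <= 0) return(numeric(n))
  if (type == "normal") return(rnorm(n, 0, sd))
  y <- (1 + sqrt(1 + 4 * sd^2)) / 2       # y = exp(sdlog^2)
  sl <- sqrt(log(y))
  rlnorm(n, meanlog = 0, sdlog = sl) - sqrt(y)
}

#' Contaminate a dataset with local and global noise
#'
#' Adds the two noise components of a [noise_spec()]: a per-gene zero-mean
#' component with standard deviation from [local_noise_sd()] (computed on
#' the rows actually present in the dataset), and a dataset-wide component
#' with one standard deviation shared by all genes, scaled to
#' `kappa_global`% of the mean per-gene standard deviation. A dataset with
#' both kappas 0 passes through bitwise unchanged.
#'
#' @param dataset a `grn_dataset` (or `grn_datasource`, contaminated in
#'   place as a single dataset).
#' @param spec a [noise_spec()].
#' @param seed integer seed for the noise stream.
#' @return The dataset with contaminated `expr`; `$noise` records the spec
#'   and the realized per-gene local and shared global standard deviations.
#' @export
grn_add_noise <- function(dataset, spec = noise_spec(), seed = 1L) {
  if (inherits(dataset, "grn_datasource")) {
    dataset <- structure(list(expr = dataset$expr, source_name = dataset$name,
                              experiment_indices = seq_len(nrow(dataset$expr)),
                              noise = NULL, seed = as.integer(seed)),
                         class = "grn_dataset")
  }
  stopifnot(inherits(dataset, "grn_dataset"), inherits(spec, "noise_spec"))
  X <- dataset$expr
  N <- nrow(X); G <- ncol(X)
  if (spec$kappa_local == 0 && spec$kappa_global == 0) {
    dataset$noise <- list(spec = spec, local_sd = numeric(G), global_sd = 0)
    return(dataset)
  }
  sigma_g <- apply(X, 2, sd)
  noise_seed <- derive_seed(seed, "noise", dataset$source_name,
                            paste(dataset$experiment_indices, collapse = ","))
  out <- with_seed(noise_seed, {
    lsd <- if (spec$kappa_local > 0)
      local_noise_sd(sigma_g, spec$kappa_local, spec$range_fraction)
    else numeric(G)
    for (g in seq_len(G)) {
      if (lsd[g] > 0) X[, g] <- X[, g] + draw_noise(N, lsd[g], spec$local_type)
    }
    gsd <- 0
    if (spec$kappa_global > 0) {
      gsd <- mean(sigma_g) *
        runif(1, (1 - spec$range_fraction) * spec$kappa_global,
              (1 + spec$range_fraction) * spec$kappa_global) / 100
      if (gsd > 0) X <- X + matrix(draw_noise(N * G, gsd, spec$global_type), N, G)
    }
    list(X = X, lsd = lsd, gsd = gsd)
  })
  dataset$expr <- out$X
  dataset$noise <- list(spec = spec, local_sd = out$lsd, global_sd = out$gsd)
  dataset
}
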