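# Internal helpers: argument checking and deterministic seed derivation.

abort_param <- function(msg) stop(msg, call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    abort_param(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    abort_param(sprintf("`%s` must be a number in [%g, %g]", name, lo, hi))
  as.numeric(x)
}

# Derive a child seed from a master seed and a string label, deterministically
# and platform-independently. Streams keyed by different labels are
# independent in practice; results always fit in a 32-bit signed integer.
derive_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647  # double arithmetic is exact below 2^53
  }
  as.integer(h)
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Coerce the expression argument of inference methods: accepts a numeric
# matrix or data.frame with rows = experiments, columns = genes.
as_expr_matrix <- function(expr) {
  if (inherits(expr, "grn_dataset") || inherits(expr, "grn_datasource"))
    expr <- expr$expr
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!is.matrix(expr) || !is.numeric(expr))
    abort_param("`expr` must be a numeric matrix or data.frame (rows = experiments, columns = genes)")
  if (is.null(colnames(expr))) colnames(expr) <- paste0("G", seq_len(ncol(expr)))
  expr
}

empty_score_matrix <- function(genes, method, symmetric) {
  s <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  attr(s, "method") <- method
  attr(s, "symmetric") <- symmetric
  s
}

finalize_scores <- function(s, method, symmetric) {
  diag(s) <- 0
  s[!is.finite(s)] <- 0
  attr(s, "method") <- method
  attr(s, "symmetric") <- symmetric
  s
}
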