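# Internal helpers shared across modules.

# Draw from Dirichlet(alpha * 1_k) via normalized gammas.
rdirichlet_flat <- function(n, k, alpha) {
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), nrow = n)
  # guard against all-zero rows at tiny alpha
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1 / k
  g / rowSums(g)
}

# Deterministic per-unit seed derivation from a base seed and a counter,
# kept below .Machine$integer.max.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(counter) * 104729) %% 2147483647)
}

# stable ascending order with explicit index tie-break
order_with_index <- function(x) order(x, seq_along(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# single structured log line used by pipeline stages
stage_log <- function(stage, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  msg <- paste0(stage, ": ",
                paste(vapply(list(...), as.character, character(1)),
                      collapse = " "))
  message("[paretocell] ", msg)
  invisible(msg)
}
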