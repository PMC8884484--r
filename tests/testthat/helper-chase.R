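# Shared fixtures, built in code.

# A small well-separated map with deterministic layout.
tiny_map <- function(L = 3, K = 5000, seed = 42) {
  generate_map(L = L, K = K, seed = seed, d_min = 0.1)
}

# A random positive population state (reals) for property tests.
random_state <- function(L, seed, scale = 2000, t = 0L) {
  n <- with_seed_test(seed, matrix(runif(L * L, 0, scale), L, L))
  population_state(n, t)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Independent reference: assemble one origin's kernel column by column
# straight from the model's definition, using only scalar arithmetic.
# Deliberately naive; used to cross-check the vectorized implementation.
reference_kernel <- function(n, beta, k, map, delta, gamma, alpha) {
  L <- nrow(n)
  w <- matrix(0, L, L)
  for (j in seq_len(L)) {
    tot_j <- sum(n[j, ])
    stabil <- if (beta == 0) 1 else (exp(1) / beta)^beta
    pop_j <- if (beta == 0) 1 else stabil * (tot_j / map$K[j])^beta
    stay <- 1 - delta + delta * pop_j * exp(-tot_j / map$K[j])
    raw <- numeric(L)
    for (i in seq_len(L)) {
      if (i == j) next
      tot_i <- sum(n[i, ])
      popf <- if (beta == 0) 1 else (sum(n[i, -k]) + gamma * n[i, k])^beta
      raw[i] <- popf * map$dist[i, j]^(-alpha) * exp(-tot_i / map$K[i])
    }
    if (sum(raw) > 0) {
      w[, j] <- raw / sum(raw) * (1 - stay)
      w[j, j] <- stay
    } else {
      w[j, j] <- 1
    }
  }
  w
}
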