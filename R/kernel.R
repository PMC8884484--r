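#' Mindset schedule: the time-varying agglomeration exponent
#'
#' The agglomeration exponent follows `beta_t = 1 - exp(-t / tau_beta)`:
#' it starts at 0 (migrants weigh only distance and environmental
#' pressure) and rises towards 1 (full weight on agglomeration benefits
#' and social ties), with `tau_beta` setting how fast mindsets change.
#' `tau_beta = 0` is defined as `beta_t` identically 1 for all `t` — the
#' limiting "mindsets already formed" case.
#'
#' @param t Time index (step), vectorized; `>= 0`.
#' @param tau_beta Mindset timescale in steps; `>= 0`.
#' @return `beta_t` in `[0, 1]`, same length as `t`.
#' @examples
#' beta_schedule(0, 60)    # 0
#' beta_schedule(60, 60)   # 1 - exp(-1)
#' beta_schedule(1e6, 0)   # 1
#' @export
beta_schedule <- function(t, tau_beta) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("invalid parameter `t`: must be >= 0", call. = FALSE)
  }
  if (!is.numeric(tau_beta) || length(tau_beta) != 1L ||
      !is.finite(tau_beta) || tau_beta < 0) {
    stop("invalid parameter `tau_beta`: must be a single value >= 0",
         call. = FALSE)
  }
  if (tau_beta == 0) rep(1, length(t)) else 1 - exp(-t / tau_beta)
}

# (e/beta)^beta, with the beta -> 0 limit 1. This stabilizer makes the
# agglomeration-environment product (n/K)^beta exp(-n/K) peak at exactly 1
# (at n = beta*K), so the staying probability stays within [1-delta, 1].
stay_stabilizer <- function(beta) {
  ifelse(beta == 0, 1, (exp(1) / beta)^beta)
}

#' Probability of staying put for one step
#'
#' Diagonal entry of the transition kernel: an individual in city `j`
#' stays with probability
#' `1 - delta + delta * (e/beta)^beta * (n/K)^beta * exp(-n/K)`,
#' where `n` is the city's total population. The `(e/beta)^beta` factor
#' normalizes the peak of `(n/K)^beta exp(-n/K)` to 1 (attained at
#' `n = beta * K`), bounding the result in `[1 - delta, 1]`. At
#' `beta = 0` the expression reduces to `1 - delta + delta * exp(-n/K)`
#' (with the conventions `0^0 = 1` and `(e/0)^0 = 1`).
#'
#' @param n_total Total persons in the city (all origins); `>= 0`.
#'   Vectorized.
#' @param K Characteristic population size; `> 0`.
#' @param beta Agglomeration exponent in `[0, 1]`.
#' @param delta Maximum emigrating fraction per step, in `(0, 1]`.
#' @return Staying probability in `[1 - delta, 1]`.
#' @examples
#' staying_probability(5000, 5000, beta = 1, delta = 0.2)  # 1: n == K
#' staying_probability(0, 5000, beta = 0, delta = 0.2)     # 1
#' @export
staying_probability <- function(n_total, K, beta, delta) {
  if (any(K <= 0)) {
    stop("invalid parameter `K`: must be > 0", call. = FALSE)
  }
  if (any(n_total < 0)) {
    stop("invalid parameter `n_total`: must be >= 0", call. = FALSE)
  }
  if (beta < 0 || beta > 1) {
    stop("invalid parameter `beta`: must be in [0, 1]", call. = FALSE)
  }
  if (delta <= 0 || delta > 1) {
    stop("invalid parameter `delta`: must be in (0, 1]", call. = FALSE)
  }
  x <- n_total / K
  bonus <- if (beta == 0) exp(-x) else stay_stabilizer(beta) * x^beta * exp(-x)
  1 - delta + delta * bonus
}

#' Unnormalized attraction weight of a destination city
#'
#' The off-diagonal factor of the transition kernel for an origin-`k`
#' individual currently in city `j` considering destination `i`:
#' \deqn{(\sum_{x \ne k} n_i^{(x)} + \gamma n_i^{(k)})^{\beta}
#'       \, d_{ij}^{-\alpha} \, e^{-\sum_x n_i^{(x)} / K_i}.}
#' The homophily numerator counts everyone at the destination but weights
#' people of the mover's own origin by `gamma` (`gamma = 1` reduces it to
#' the total destination population). At `beta = 0` the population factor
#' is identically 1 (`0^0 = 1`), so only distance and environmental
#' pressure matter — including for empty destinations.
#'
#' @param i Destination city index (1-based).
#' @param j Source city index; must differ from `i`.
#' @param k Origin-group index.
#' @param state A [population_state()] or bare `L x L` population matrix
#'   (`n[city, origin]`).
#' @param map A [city_map()].
#' @param params A [chase_params()] (only `gamma` and `alpha` are used).
#' @param beta Agglomeration exponent in `[0, 1]`.
#' @return Non-negative unnormalized weight.
#' @examples
#' m <- city_map(rbind(c(0, 0), c(1, 0)), K = 5000)
#' n <- matrix(c(0, 100, 0, 0), 2, 2)  # 100 origin-1 people in city 2
#' attraction_weight(2, 1, 1, n, m, chase_params(gamma = 50), beta = 1)
#' @export
attraction_weight <- function(i, j, k, state, map, params, beta) {
  n <- state_matrix(state)
  if (i == j) {
    stop("`i` and `j` must differ: attraction weights are off-diagonal",
         call. = FALSE)
  }
  if (beta < 0 || beta > 1) {
    stop("invalid parameter `beta`: must be in [0, 1]", call. = FALSE)
  }
  d <- map$dist[i, j]
  if (d == 0) stop("degenerate map: zero distance between distinct cities",
                   call. = FALSE)
  tot <- sum(n[i, ])
  pop_fac <- if (beta == 0) 1 else (tot + (params$gamma - 1) * n[i, k])^beta
  pop_fac * d^(-params$alpha) * exp(-tot / map$K[i])
}

#' Transition kernel for one origin group at one time step
#'
#' Assembles the column-stochastic `L x L` matrix `w` for origin `k` at
#' time `t`: `w[i, j]` is the probability that an origin-`k` individual
#' in city `j` moves to city `i` this step. Diagonal entries come from
#' [staying_probability()]; off-diagonal entries are [attraction_weight()]
#' values normalized per source column by a constant `C` so the column
#' sums to 1. If every off-diagonal raw weight in a column is zero (no
#' admissible destination), the would-be emigrants have nowhere to go and
#' the staying probability is forced to 1.
#'
#' @param state A [population_state()] or bare population matrix.
#' @param t Time index at which the mindset schedule is evaluated.
#' @param k Origin-group index (1-based).
#' @param map A [city_map()].
#' @param params A [chase_params()].
#' @return An object of class `chase_kernel`: list with `w` (the matrix),
#'   `C` (per-column normalization constants; `NA` for degenerate
#'   columns), `beta`, `origin`, and `t`.
#' @examples
#' m <- generate_map(L = 3, seed = 1)
#' s <- initial_state(3, 1000)
#' ker <- transition_kernel(s, t = 0, k = 1, m, chase_params())
#' colSums(ker$w)  # all 1
#' @export
transition_kernel <- function(state, t, k, map, params) {
  n <- state_matrix(state)
  L <- map$L
  if (nrow(n) != L || ncol(n) != L) {
    stop("state/map dimension mismatch", call. = FALSE)
  }
  beta <- beta_schedule(t, params$tau_beta)
  tot <- rowSums(n)
  stay <- staying_probability(tot, map$K, beta, params$delta)

  # raw off-diagonal weights: rows = destinations, columns = sources
  env <- exp(-tot / map$K)
  pop_fac <- if (beta == 0) rep(1, L) else (tot + (params$gamma - 1) * n[, k])^beta
  dinv <- map$dist^(-params$alpha)
  diag(dinv) <- 0
  raw <- (pop_fac * env) * dinv   # raw[i, j] = a_i * d_ij^-alpha

  if (any(!is.finite(raw))) {
    bad <- which(!is.finite(raw), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-finite transition weight at destination i=%d, source j=%d, origin k=%d",
      bad[1], bad[2], k), call. = FALSE)
  }

  s <- colSums(raw)
  C <- ifelse(s > 0, (1 - stay) / s, NA_real_)
  w <- raw * rep(ifelse(s > 0, C, 0), each = L)
  diag(w) <- ifelse(s > 0, stay, 1)
  structure(list(w = w, C = C, beta = beta, origin = k, t = t),
            class = "chase_kernel")
}

# Accept either a population_state or a bare matrix.
state_matrix <- function(state) {
  if (inherits(state, "population_state")) state$n else as.matrix(state)
}

#' @export
print.chase_kernel <- function(x, ...) {
  cat(sprintf("Transition kernel: origin %d, t = %g, beta = %.4f, %dx%d\n",
              x$origin, x$t, x$beta, nrow(x$w), ncol(x$w)))
  invisible(x)
}
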