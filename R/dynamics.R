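#' Population state
#'
#' The system state is an `L x L` matrix `n` with `n[j, x]` the number of
#' people of origin `x` currently living in city `j`, plus a time index
#' `t`. Populations are non-negative reals in deterministic mode and
#' non-negative integers in stochastic mode; with no births or deaths,
#' every origin group's total is conserved over time.
#'
#' @param n `L x L` non-negative matrix (`n[city, origin]`).
#' @param t Non-negative integer time index.
#' @return An object of class `population_state`.
#' @export
population_state <- function(n, t = 0L) {
  n <- as.matrix(n)
  if (nrow(n) != ncol(n)) stop("`n` must be square (L x L)", call. = FALSE)
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("populations must be finite and >= 0", call. = FALSE)
  }
  if (t < 0 || t != floor(t)) {
    stop("`t` must be a non-negative integer", call. = FALSE)
  }
  structure(list(n = unname(n), t = as.integer(t)), class = "population_state")
}

#' Initial state: natives only
#'
#' Every city starts with `n0` of its own natives and nobody else:
#' `n[j, x] = n0` if `j == x`, else 0.
#'
#' @param L Number of cities; `>= 2`.
#' @param n0 Persons per native city; `> 0`.
#' @return A [population_state()] at `t = 0`.
#' @examples
#' s <- initial_state(10, 3000)
#' sum(s$n)  # 30000
#' @export
initial_state <- function(L, n0) {
  if (L < 2L) stop("`L` must be >= 2", call. = FALSE)
  if (n0 <= 0) stop("`n0` must be > 0", call. = FALSE)
  population_state(diag(n0, L), 0L)
}

#' Advance the state one step by expected flow
#'
#' Deterministic update: for each origin `k`, the new distribution is the
#' matrix-vector product `n'[, k] = w_k %*% n[, k]` of that origin's
#' transition kernel with its current distribution. Kernels must have
#' been computed from this state at its time index (synchronous update).
#'
#' @param state A [population_state()].
#' @param kernels List of `L` `chase_kernel` objects, one per origin, in
#'   origin order (e.g. from [transition_kernel()]).
#' @return The updated [population_state()] with `t` incremented.
#' @export
step_deterministic <- function(state, kernels) {
  n <- state_matrix(state)
  L <- nrow(n)
  if (length(kernels) != L) {
    stop("need one kernel per origin group", call. = FALSE)
  }
  n_new <- n
  for (k in seq_len(L)) {
    w <- if (inherits(kernels[[k]], "chase_kernel")) kernels[[k]]$w else kernels[[k]]
    if (!all(dim(w) == L)) stop("kernel/state dimension mismatch", call. = FALSE)
    n_new[, k] <- w %*% n[, k]
  }
  population_state(n_new, (if (inherits(state, "population_state")) state$t else 0L) + 1L)
}

#' Advance the state one step by multinomial sampling
#'
#' Stochastic update: the `n[j, k]` origin-`k` individuals in city `j`
#' are allocated to destinations by one multinomial draw over column `j`
#' of origin `k`'s kernel. Totals are conserved exactly; results are
#' reproducible for a fixed RNG state.
#'
#' @inheritParams step_deterministic
#' @return The updated integer-valued [population_state()].
#' @export
step_stochastic <- function(state, kernels) {
  n <- state_matrix(state)
  L <- nrow(n)
  if (any(n != floor(n))) {
    stop("stochastic mode requires integer populations", call. = FALSE)
  }
  if (length(kernels) != L) {
    stop("need one kernel per origin group", call. = FALSE)
  }
  n_new <- matrix(0, L, L)
  for (k in seq_len(L)) {
    w <- if (inherits(kernels[[k]], "chase_kernel")) kernels[[k]]$w else kernels[[k]]
    for (j in seq_len(L)) {
      if (n[j, k] > 0) {
        n_new[, k] <- n_new[, k] + stats::rmultinom(1, n[j, k], w[, j])[, 1]
      }
    }
  }
  population_state(n_new, (if (inherits(state, "population_state")) state$t else 0L) + 1L)
}

# Vectorized deterministic step over all origins at once. Algebraically
# identical to applying step_deterministic with the L per-origin kernels:
#   inflow_i^(k) = a_i^(k) * sum_j d_ij^-alpha * out_j^(k) / s_j^(k),
# where a_i^(k) is the destination attraction factor, out the emigrant
# mass (1 - stay_j) n_jk and s the per-column raw-weight sum. Columns with
# s = 0 (no admissible destination) keep their would-be emigrants.
step_flow <- function(n, dinv, K, gamma, beta, delta) {
  L <- nrow(n)
  tot <- .rowSums(n, L, L)
  env <- exp(-tot / K)
  if (beta == 0) {
    stay <- 1 - delta + delta * env
    a <- matrix(env, L, L)
  } else {
    stay <- 1 - delta + delta * stay_stabilizer(beta) * (tot / K)^beta * env
    a <- ((tot + (gamma - 1) * n)^beta) * env
  }
  s <- dinv %*% a                    # s[j, k]: raw weight sum out of j for origin k
  out <- (1 - stay) * n
  ratio <- out / s
  z <- s <= 0
  if (any(z)) ratio[z] <- 0
  n_new <- stay * n + a * (dinv %*% ratio)
  if (any(z)) n_new[z] <- n_new[z] + out[z]
  if (any(!is.finite(n_new))) {
    bad <- which(!is.finite(n_new), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite population at city %d, origin %d", bad[1], bad[2]),
         call. = FALSE)
  }
  n_new
}

#' Run a full CHASE simulation
#'
#' Iterates kernel construction and state propagation for
#' `params$steps` time steps from the natives-only initial state, under
#' the mindset schedule `beta_t = 1 - exp(-t / tau_beta)`. The kernel for
#' the step taking `t` to `t + 1` is evaluated at `beta_t` (so the first
#' step uses `beta_0`). Deterministic mode is bit-reproducible; the
#' stochastic mode is reproducible under `params$seed`.
#'
#' @param map A [city_map()].
#' @param params A [chase_params()].
#' @param record `"all"` to keep every state, `"final"` to keep only the
#'   first and last, or a positive integer to keep every that-many-th
#'   state (the final state is always kept).
#' @param progress_every Emit a `message()` with the elapsed step count
#'   every this many steps (`NULL`, the default, is silent).
#' @return An object of class `chase_sim`: list with
#'   \describe{
#'     \item{trajectory}{`L x L x n_recorded` array of states,}
#'     \item{times}{the time indices of the recorded states,}
#'     \item{beta}{the schedule `beta_t` for `t = 0 .. steps`,}
#'     \item{final}{the final `L x L` population matrix,}
#'     \item{map, params}{the inputs.}
#'   }
#' @examples
#' m <- generate_map(seed = 1)
#' sim <- run_chase(m, chase_params(steps = 100))
#' sum(sim$final)  # 30000, conserved
#' @export
run_chase <- function(map, params = chase_params(), record = "all",
                      progress_every = NULL) {
  stopifnot(inherits(map, "city_map"))
  params <- validate_params(params)
  L <- map$L
  steps <- as.integer(params$steps)

  if (identical(record, "all")) {
    thin <- 1L
  } else if (identical(record, "final")) {
    thin <- steps
  } else {
    thin <- as.integer(record)
    if (is.na(thin) || thin < 1L) stop("invalid `record`", call. = FALSE)
  }
  rec_t <- unique(c(seq(0L, steps, by = thin), steps))
  rec_mask <- logical(steps + 1L)
  rec_mask[rec_t + 1L] <- TRUE

  dinv <- map$dist^(-params$alpha)
  diag(dinv) <- 0
  beta_series <- beta_schedule(0:steps, params$tau_beta)

  n <- diag(params$n0, L)
  traj <- array(NA_real_, dim = c(L, L, length(rec_t)))
  traj[, , 1] <- n
  ri <- 2L

  stochastic <- params$mode == "stochastic"
  run_steps <- function() {
    for (t in seq_len(steps) - 1L) {
      beta <- beta_series[t + 1L]
      if (stochastic) {
        st <- population_state(n, t)
        kers <- lapply(seq_len(L), function(k) {
          transition_kernel(st, t, k, map, params)
        })
        n <<- step_stochastic(st, kers)$n
      } else {
        n <<- tryCatch(
          step_flow(n, dinv, map$K, params$gamma, beta, params$delta),
          error = function(e) {
            stop(sprintf("at step t=%d: %s", t, conditionMessage(e)),
                 call. = FALSE)
          })
      }
      if (rec_mask[t + 2L]) {
        traj[, , ri] <<- n
        ri <<- ri + 1L
      }
      if (!is.null(progress_every) && (t + 1L) %% progress_every == 0L) {
        message(sprintf("step %d/%d (beta = %.4f)", t + 1L, steps, beta))
      }
    }
  }
  if (stochastic) with_seed(params$seed, run_steps()) else run_steps()

  structure(list(trajectory = traj, times = rec_t, beta = beta_series,
                 final = n, map = map, params = params),
            class = "chase_sim")
}

#' @export
print.chase_sim <- function(x, ...) {
  tot <- rowSums(x$final)
  cat(sprintf("CHASE simulation: %d cities, %d steps (%s mode)\n",
              x$map$L, as.integer(x$params$steps), x$params$mode))
  cat(sprintf("  total population %.6g; %d cities above epsilon = %g\n",
              sum(tot), sum(tot > x$params$epsilon), x$params$epsilon))
  invisible(x)
}
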