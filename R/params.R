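#' Model parameters for a CHASE simulation
#'
#' Bundles and validates the parameters of the migration model. The
#' defaults are the baseline configuration used throughout the package's
#' experiments: maximum emigrating fraction `delta = 0.2`, distance
#' exponent `alpha = 1` (Zipf's gravity exponent), social-tie weight
#' `gamma = 50`, mindset timescale `tau_beta = 120` steps, `steps = 5000`
#' time steps, and 3,000 natives per city.
#'
#' @param delta Maximum fraction of a city's population that can emigrate
#'   in one time step; in `(0, 1]`. Not everyone who wants to move can.
#' @param alpha Exponent of the distance deterrent `d^-alpha`; `>= 0`.
#' @param gamma Social-tie weight: how much people value others of their
#'   own origin at a candidate destination. `gamma = 1` is neutral (the
#'   homophily numerator reduces to total destination population); `>= 0`.
#' @param tau_beta Timescale (in steps) on which the agglomeration
#'   exponent `beta_t = 1 - exp(-t/tau_beta)` rises from 0 to 1.
#'   `tau_beta = 0` means `beta_t` is identically 1 (mindsets are "fully
#'   formed" from the start); `>= 0`.
#' @param steps Number of time steps `T` to simulate; positive integer.
#' @param n0 Initial native population per city (persons); `> 0`.
#' @param epsilon Extinction threshold (persons): a city whose final total
#'   population is `<= epsilon` counts as not surviving; `>= 0`.
#' @param mode `"deterministic"` for expected-flow propagation with
#'   real-valued populations, or `"stochastic"` for integer agents moved
#'   by multinomial draws.
#' @param seed Integer seed for the stochastic mode (ignored by the
#'   deterministic dynamics); may be `NULL`.
#'
#' @return An object of class `chase_params` (a validated named list).
#' @examples
#' p <- chase_params(tau_beta = 0, steps = 100)
#' p$delta
#' @export
chase_params <- function(delta = 0.2, alpha = 1, gamma = 50, tau_beta = 120,
                         steps = 5000, n0 = 3000, epsilon = 1,
                         mode = c("deterministic", "stochastic"),
                         seed = NULL) {
  mode <- match.arg(mode)
  p <- structure(
    list(delta = delta, alpha = alpha, gamma = gamma, tau_beta = tau_beta,
         steps = steps, n0 = n0, epsilon = epsilon, mode = mode,
         seed = seed),
    class = "chase_params"
  )
  validate_params(p)
}

validate_params <- function(p) {
  chk <- function(ok, key, msg) {
    if (!ok) stop(sprintf("invalid parameter `%s`: %s", key, msg),
                  call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$delta) && p$delta > 0 && p$delta <= 1, "delta",
      "must be in (0, 1]")
  chk(num1(p$alpha) && p$alpha >= 0, "alpha", "must be >= 0")
  chk(num1(p$gamma) && p$gamma >= 0, "gamma", "must be >= 0")
  chk(num1(p$tau_beta) && p$tau_beta >= 0, "tau_beta", "must be >= 0")
  chk(num1(p$steps) && p$steps >= 0 && p$steps == floor(p$steps), "steps",
      "must be a non-negative integer")
  chk(num1(p$n0) && p$n0 > 0, "n0", "must be > 0")
  chk(num1(p$epsilon) && p$epsilon >= 0, "epsilon", "must be >= 0")
  chk(p$mode %in% c("deterministic", "stochastic"), "mode",
      "must be 'deterministic' or 'stochastic'")
  if (!is.null(p$seed)) {
    chk(num1(p$seed) && p$seed == floor(p$seed), "seed",
        "must be a single integer or NULL")
  }
  if (p$mode == "stochastic") {
    chk(num1(p$n0) && p$n0 == floor(p$n0), "n0",
        "must be a whole number of persons in stochastic mode")
  }
  p
}

#' @export
print.chase_params <- function(x, ...) {
  cat("CHASE model parameters\n")
  cat(sprintf("  delta = %g, alpha = %g, gamma = %g, tau_beta = %g\n",
              x$delta, x$alpha, x$gamma, x$tau_beta))
  cat(sprintf("  steps = %d, n0 = %g, epsilon = %g, mode = %s, seed = %s\n",
              as.integer(x$steps), x$n0, x$epsilon, x$mode,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}
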