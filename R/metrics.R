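#' Inverse Simpson diversity index of one city's composition
#'
#' For a city with origin composition `n_1, ..., n_L`, the index is
#' `1 / sum(p_x^2)` with `p_x = n_x / sum(n)`: 1 when everyone shares one
#' origin (completely homogeneous), `L` when all origins are equally
#' represented, and 0 by convention for an empty city.
#'
#' @param composition Non-negative vector of per-origin counts.
#' @return A value in `{0}` or `[1, L]`.
#' @examples
#' simpson_index(c(3000, 0, 0))      # 1
#' simpson_index(rep(10, 10))        # 10
#' simpson_index(numeric(5))         # 0
#' @export
simpson_index <- function(composition) {
  if (!is.numeric(composition) || any(!is.finite(composition)) ||
      any(composition < 0)) {
    stop("invalid input: composition counts must be finite and >= 0",
         call. = FALSE)
  }
  tot <- sum(composition)
  if (tot == 0) return(0)
  p <- composition / tot
  1 / sum(p^2)
}

#' Which cities survive?
#'
#' A city survives if its total population at the assessed state exceeds
#' the extinction threshold `epsilon` (strictly). Deterministic flows
#' never reach exactly zero, so "population greater than 0" is made
#' operational with a cutoff; the default of one whole person is the
#' natural choice (stochastic runs can use `epsilon = 0`).
#'
#' @param state A [population_state()], `chase_sim` (its final state is
#'   used), or bare population matrix.
#' @param epsilon Extinction threshold in persons; `>= 0` (default 1).
#' @return List with `mask` (logical, length `L`) and `count`.
#' @examples
#' surviving_cities(initial_state(10, 3000))$count  # 10
#' @export
surviving_cities <- function(state, epsilon = 1) {
  if (epsilon < 0) stop("`epsilon` must be >= 0", call. = FALSE)
  n <- if (inherits(state, "chase_sim")) state$final else state_matrix(state)
  mask <- rowSums(n) > epsilon
  list(mask = mask, count = sum(mask))
}

#' Five-number boxplot summary with 1.5 IQR whiskers
#'
#' Median and quartiles (linear interpolation between order statistics,
#' `quantile()` type 7), whiskers at the most extreme observations within
#' 1.5 interquartile ranges of the quartiles, and the remaining points
#' flagged as outliers. This is the summary used for the diversity
#' distributions in ensemble experiments.
#'
#' @param values Non-empty numeric sample.
#' @return List with `median`, `q25`, `q75`, `whisker_lo`, `whisker_hi`,
#'   `outliers`, and `n`.
#' @examples
#' boxplot_stats(c(1, 2, 3, 4, 100))$outliers  # 100
#' @export
boxplot_stats <- function(values) {
  if (length(values) == 0 || !is.numeric(values) || any(!is.finite(values))) {
    stop("invalid input: need a non-empty finite numeric sample",
         call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = values[!inside], n = length(values))
}

#' Per-city end-of-run metrics table
#'
#' @param sim A `chase_sim` from [run_chase()], or a population matrix.
#' @param epsilon Extinction threshold; defaults to the run's parameter.
#' @return A data.frame with columns `city_id` (0-based),
#'   `total_population`, `S` (inverse Simpson index), and `surviving`.
#'   Diversity is reported for every city; downstream aggregation pools
#'   only surviving cities.
#' @export
city_metrics <- function(sim, epsilon = NULL) {
  n <- if (inherits(sim, "chase_sim")) sim$final else state_matrix(sim)
  if (is.null(epsilon)) {
    epsilon <- if (inherits(sim, "chase_sim")) sim$params$epsilon else 1
  }
  surv <- surviving_cities(n, epsilon)
  data.frame(
    city_id = seq_len(nrow(n)) - 1L,
    total_population = rowSums(n),
    S = apply(n, 1, simpson_index),
    surviving = surv$mask
  )
}

#' Write the per-city metrics CSV
#'
#' Columns: `city_id,total_population,S,surviving` (0-based ids).
#'
#' @param metrics A data.frame from [city_metrics()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  need <- c("city_id", "total_population", "S", "surviving")
  stopifnot(all(need %in% names(metrics)))
  utils::write.csv(metrics[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
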