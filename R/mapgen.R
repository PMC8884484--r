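#' Construct a city map
#'
#' A city map holds the planar coordinates of `L` cities, their pairwise
#' Euclidean distance matrix, and the characteristic population size
#' `K_j` each city can support (the population that maximizes a city's
#' attractiveness when the agglomeration exponent is 1; environmental
#' pressure enters the model as `exp(-n/K)`, Ricker-style).
#'
#' @param coords Numeric `L x 2` matrix of city coordinates (map units).
#' @param K Characteristic population sizes: a single value recycled to
#'   all cities, or a length-`L` vector; all entries `> 0`.
#' @param dist Optional precomputed distance matrix; recomputed from
#'   `coords` and checked against it if supplied.
#'
#' @return An object of class `city_map` with elements `coords`, `dist`,
#'   `K`, and `L`.
#' @examples
#' m <- city_map(rbind(c(0, 0), c(3, 4)), K = 5000)
#' m$dist[1, 2]  # 5
#' @seealso [generate_map()] for random maps, [read_city_map()]
#' @export
city_map <- function(coords, K, dist = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L) {
    stop("`coords` must be a numeric L x 2 matrix", call. = FALSE)
  }
  L <- nrow(coords)
  if (L < 2L) stop("a map needs at least 2 cities", call. = FALSE)
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  d <- distance_matrix(coords)
  if (!is.null(dist)) {
    dist <- as.matrix(dist)
    if (!isTRUE(all.equal(unname(dist), unname(d), tolerance = 1e-8))) {
      stop("supplied `dist` does not match Euclidean distances recomputed ",
           "from `coords`", call. = FALSE)
    }
  }
  if (length(K) == 1L) K <- rep(K, L)
  if (length(K) != L || !is.numeric(K) || any(!is.finite(K)) || any(K <= 0)) {
    stop("`K` must be positive and of length 1 or L", call. = FALSE)
  }
  structure(list(coords = unname(coords), dist = d, K = as.numeric(K), L = L),
            class = "city_map")
}

#' Euclidean distance matrix of a set of planar points
#'
#' @param coords Numeric `L x 2` matrix of coordinates.
#' @return Symmetric `L x L` matrix with zero diagonal. Duplicate points
#'   are an error: the gravity kernel's `d^-alpha` diverges for
#'   coincident cities.
#' @examples
#' distance_matrix(rbind(c(0, 0), c(3, 4)))
#' @export
distance_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 points", call. = FALSE)
  d <- unname(as.matrix(stats::dist(coords)))
  if (any(d[upper.tri(d)] == 0)) {
    stop("degenerate map: duplicate city coordinates (zero distance)",
         call. = FALSE)
  }
  d
}

#' Generate a random city map
#'
#' Places `L` cities uniformly at random on the unit square, redrawing
#' the whole configuration until every pairwise distance is at least
#' `d_min`. All cities share the same characteristic size `K` (the
#' homogeneous-`K` setting used throughout the experiments). The model's
#' transition kernel is invariant to a global rescaling of distances, so
#' the unit square fixes only the shape of the point pattern, not the
#' dynamics' scale.
#'
#' @param L Number of cities (default 10).
#' @param K Characteristic population size shared by all cities
#'   (default 5000 persons).
#' @param seed Integer seed for reproducible placement; `NULL` uses the
#'   current RNG stream.
#' @param d_min Minimum pairwise separation (map units; default 0.05).
#' @param max_attempts Resampling budget before giving up (default 1000).
#'
#' @return A [city_map()].
#' @examples
#' m <- generate_map(L = 10, seed = 1)
#' min(m$dist[upper.tri(m$dist)]) >= 0.05
#' @export
generate_map <- function(L = 10, K = 5000, seed = NULL, d_min = 0.05,
                         max_attempts = 1000) {
  if (L < 2L) stop("`L` must be >= 2", call. = FALSE)
  if (d_min < 0) stop("`d_min` must be >= 0", call. = FALSE)
  coords <- with_seed(seed, {
    found <- NULL
    for (i in seq_len(max_attempts)) {
      pts <- matrix(stats::runif(2L * L), ncol = 2L)
      if (L < 2L || min(stats::dist(pts)) >= d_min) {
        found <- pts
        break
      }
    }
    found
  })
  if (is.null(coords)) {
    stop(sprintf(
      "map generation failed: no configuration of %d cities with minimum separation %g found in %d attempts",
      L, d_min, max_attempts), call. = FALSE)
  }
  city_map(coords, K)
}

#' Read / write a city map as CSV
#'
#' The on-disk format is a CSV with the exact header
#' `city_id,x,y,K`, one row per city, ids contiguous from 0.
#'
#' @param path File path.
#' @return `read_city_map()` returns a [city_map()]; `write_city_map()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_city_map(generate_map(L = 3, seed = 1), f)
#' read_city_map(f)$L
#' @export
read_city_map <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("city_id", "x", "y", "K")
  if (!identical(names(df), need)) {
    stop(sprintf("map file must have columns %s (got: %s)",
                 paste(need, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  }
  if (!identical(as.integer(df$city_id), seq_len(nrow(df)) - 1L)) {
    stop("`city_id` must be contiguous from 0", call. = FALSE)
  }
  city_map(cbind(df$x, df$y), df$K)
}

#' @rdname read_city_map
#' @param map A [city_map()].
#' @export
write_city_map <- function(map, path) {
  stopifnot(inherits(map, "city_map"))
  df <- data.frame(city_id = seq_len(map$L) - 1L,
                   x = map$coords[, 1], y = map$coords[, 2], K = map$K)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.city_map <- function(x, ...) {
  cat(sprintf("City map: %d cities, K in [%g, %g], min separation %.4g\n",
              x$L, min(x$K), max(x$K), min(x$dist[upper.tri(x$dist)])))
  invisible(x)
}
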