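config_defaults <- function() {
  list(
    delta = 0.2, alpha = 1, gamma = 50, tau_beta = 120, steps = 5000,
    n0 = 3000, epsilon = 1, mode = "deterministic", seed = NULL,
    L = 10, K = 5000, d_min = 0.05, map_file = NULL, map_seed = NULL,
    out_dir = ".", thin = 1
  )
}

#' Load a run configuration
#'
#' Resolves a run configuration from (in increasing precedence) the
#' package defaults, a flat JSON config file, and explicit overrides
#' (e.g. command-line flags). Unknown keys are an error, never silently
#' ignored; invalid values are rejected with the offending key named.
#'
#' Recognized keys: the model parameters (`delta`, `alpha`, `gamma`,
#' `tau_beta`, `steps`, `n0`, `epsilon`, `mode`, `seed`) plus the map
#' source (`L`, `K`, `d_min`, and either `map_file` or `map_seed`) and
#' output control (`out_dir`, `thin`). Defaults: `delta = 0.2`,
#' `alpha = 1`, `gamma = 50`, `tau_beta = 120`, `steps = 5000`,
#' `n0 = 3000`, `L = 10`, `K = 5000`, `epsilon = 1`, deterministic mode.
#'
#' @param path Path to a flat JSON object, or `NULL`.
#' @param overrides Named list of values overriding the file (flags win).
#' @return A `chase_config` list with all defaults resolved.
#' @examples
#' cfg <- load_config(overrides = list(steps = 100))
#' cfg$delta
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  known <- names(cfg)
  apply_layer <- function(cfg, layer, what) {
    if (length(layer) == 0) return(cfg)
    if (is.null(names(layer)) || any(names(layer) == "")) {
      stop(sprintf("%s entries must all be named", what), call. = FALSE)
    }
    unknown <- setdiff(names(layer), known)
    if (length(unknown) > 0) {
      stop(sprintf("unknown configuration key(s) in %s: %s", what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(cfg, as.list(layer))
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                                 call. = FALSE)
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- apply_layer(cfg, file_cfg, sprintf("config file '%s'", path))
  }
  cfg <- apply_layer(cfg, overrides, "overrides")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  # model parameters are validated by the chase_params constructor
  config_to_params(cfg)
  chk <- function(ok, key, msg) {
    if (!ok) stop(sprintf("invalid configuration `%s`: %s", key, msg),
                  call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$L) && cfg$L >= 2 && cfg$L == floor(cfg$L), "L",
      "must be an integer >= 2")
  chk(is.numeric(cfg$K) && all(is.finite(cfg$K)) && all(cfg$K > 0) &&
        length(cfg$K) %in% c(1L, cfg$L), "K",
      "must be positive, of length 1 or L")
  chk(num1(cfg$d_min) && cfg$d_min >= 0, "d_min", "must be >= 0")
  chk(num1(cfg$thin) && cfg$thin >= 1 && cfg$thin == floor(cfg$thin), "thin",
      "must be a positive integer")
  if (!is.null(cfg$map_file)) {
    chk(is.character(cfg$map_file) && length(cfg$map_file) == 1L, "map_file",
        "must be a single path")
  }
  if (!is.null(cfg$map_seed)) {
    chk(num1(cfg$map_seed) && cfg$map_seed == floor(cfg$map_seed), "map_seed",
        "must be a single integer")
  }
  structure(cfg, class = "chase_config")
}

#' @rdname load_config
#' @param cfg A `chase_config`.
#' @return `config_to_params()` returns the embedded [chase_params()];
#'   `config_map()` materializes the configured map (reading `map_file`
#'   if set, otherwise generating one from `map_seed`).
#' @export
config_to_params <- function(cfg) {
  chase_params(delta = cfg$delta, alpha = cfg$alpha, gamma = cfg$gamma,
               tau_beta = cfg$tau_beta, steps = cfg$steps, n0 = cfg$n0,
               epsilon = cfg$epsilon, mode = cfg$mode, seed = cfg$seed)
}

#' @rdname load_config
#' @export
config_map <- function(cfg) {
  if (!is.null(cfg$map_file)) {
    read_city_map(cfg$map_file)
  } else {
    generate_map(L = cfg$L, K = cfg$K, seed = cfg$map_seed,
                 d_min = cfg$d_min)
  }
}

#' Write a simulation's trajectory and sidecar metadata
#'
#' Writes `trajectory.csv` in long format (`t,city_id,origin_id,population`,
#' ids 0-based, optionally thinned) and `run.json` with the resolved
#' parameters, seeds, the mindset schedule `beta_t`, and the final
#' metrics (total population, surviving-city count, per-city diversity).
#' [read_trajectory()] round-trips the populations at stored precision.
#'
#' @param sim A `chase_sim` from [run_chase()].
#' @param dir Output directory (created if needed).
#' @param thin Keep every `thin`-th recorded state (the final state is
#'   always kept).
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(sim, dir, thin = 1) {
  stopifnot(inherits(sim, "chase_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  keep <- sim$times %% thin == 0 | sim$times == max(sim$times)
  times <- sim$times[keep]
  L <- sim$map$L
  df <- data.frame(
    t = rep(times, each = L * L),
    city_id = rep(rep(seq_len(L) - 1L, times = L), length(times)),
    origin_id = rep(rep(seq_len(L) - 1L, each = L), length(times)),
    population = as.vector(sim$trajectory[, , keep])
  )
  csv_path <- file.path(dir, "trajectory.csv")
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)

  met <- city_metrics(sim)
  sidecar <- list(
    params = unclass(sim$params),
    map = list(coords = sim$map$coords, K = sim$map$K, L = L),
    times = times,
    beta = sim$beta,
    final_metrics = list(
      total_population = sum(sim$final),
      count_surviving = sum(met$surviving),
      per_city = met
    )
  )
  json_path <- file.path(dir, "run.json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(c(trajectory = csv_path, sidecar = json_path))
}

#' @rdname write_trajectory
#' @return `read_trajectory()` returns a list with `trajectory` (the
#'   long-format data.frame) and `sidecar` (the parsed JSON metadata).
#' @export
read_trajectory <- function(dir) {
  list(
    trajectory = utils::read.csv(file.path(dir, "trajectory.csv"),
                                 comment.char = "#"),
    sidecar = jsonlite::read_json(file.path(dir, "run.json"),
                                  simplifyVector = TRUE)
  )
}

#' @rdname load_config
#' @param dir Directory in which to record the resolved configuration.
#' @export
write_run_config <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
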