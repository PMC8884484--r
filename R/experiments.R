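#' Legacy effect: same map, different mindset timescales
#'
#' Runs the model once per value of `tau_beta` on a single shared map and
#' compares the final states. A nonzero distance between final states for
#' different `tau_beta` is the legacy effect: how fast migrants' mindsets
#' change alters not only the transient but the long-term outcome.
#'
#' @param map A [city_map()] shared across all runs.
#' @param tau_values Numeric vector of mindset timescales to compare.
#' @param params A [chase_params()]; its `tau_beta` is overridden per run.
#' @param record Trajectory recording, as in [run_chase()].
#' @return An object of class `chase_legacy`: list with `sims` (one
#'   `chase_sim` per tau), `final_totals` (`L x length(tau_values)`
#'   matrix of final per-city totals), `distance` (pairwise max absolute
#'   per-city difference between final totals), and `tau_values`.
#' @examples
#' m <- generate_map(seed = 1)
#' le <- legacy_effect(m, c(0, 120), chase_params(steps = 200))
#' le$distance
#' @export
legacy_effect <- function(map, tau_values, params = chase_params(),
                          record = "all") {
  stopifnot(inherits(map, "city_map"), length(tau_values) >= 1)
  sims <- lapply(tau_values, function(tau) {
    p <- params
    p$tau_beta <- tau
    run_chase(map, validate_params(p), record = record)
  })
  finals <- vapply(sims, function(s) rowSums(s$final), numeric(map$L))
  ntau <- length(tau_values)
  d <- matrix(0, ntau, ntau, dimnames = list(tau_values, tau_values))
  for (a in seq_len(ntau)) {
    for (b in seq_len(ntau)) {
      d[a, b] <- max(abs(finals[, a] - finals[, b]))
    }
  }
  structure(list(sims = sims, final_totals = finals, distance = d,
                 tau_values = tau_values),
            class = "chase_legacy")
}

#' Ensemble sweep over the characteristic population size K
#'
#' For each value of `K`, runs `n_maps` simulations on fresh random maps
#' and averages the number of surviving cities. Each run's map seed is
#' drawn up front from the master seed, so the summary is reproducible
#' and any single run can be replayed from its recorded seed.
#'
#' @param K_values Characteristic sizes to sweep (persons).
#' @param gamma Social-tie weight (default 50).
#' @param tau_beta Mindset timescale (default 120).
#' @param n_maps Random maps (= runs) per K value (default 100).
#' @param master_seed Integer master seed.
#' @param params Base [chase_params()]; `gamma` and `tau_beta` above
#'   override its values.
#' @param L Cities per map (default 10).
#' @param d_min Minimum city separation for map generation.
#' @return An object of class `chase_ensemble`: list with `summary`
#'   (data.frame: `K`, `gamma`, `tau_beta`, `mean_surviving`, `n_runs`),
#'   `runs` (per-run `K`, `replicate`, `seed`, `n_surviving`), and
#'   `master_seed`.
#' @examples
#' ks <- k_sweep(c(4000, 12000), n_maps = 2, master_seed = 1,
#'               params = chase_params(steps = 200))
#' ks$summary
#' @export
k_sweep <- function(K_values, gamma = 50, tau_beta = 120, n_maps = 100,
                    master_seed = 1, params = chase_params(), L = 10,
                    d_min = 0.05) {
  stopifnot(n_maps >= 1, length(K_values) >= 1)
  params$gamma <- gamma
  params$tau_beta <- tau_beta
  params <- validate_params(params)
  seeds <- matrix(derive_seeds(master_seed, length(K_values) * n_maps),
                  nrow = n_maps)
  runs <- do.call(rbind, lapply(seq_along(K_values), function(i) {
    counts <- vapply(seq_len(n_maps), function(r) {
      map <- generate_map(L = L, K = K_values[i], seed = seeds[r, i],
                          d_min = d_min)
      sim <- run_chase(map, params, record = "final")
      surviving_cities(sim$final, params$epsilon)$count
    }, numeric(1))
    data.frame(K = K_values[i], replicate = seq_len(n_maps),
               seed = seeds[, i], n_surviving = counts)
  }))
  summary <- do.call(rbind, lapply(split(runs, runs$K), function(g) {
    data.frame(K = g$K[1], gamma = gamma, tau_beta = tau_beta,
               mean_surviving = mean(g$n_surviving), n_runs = nrow(g))
  }))
  summary <- summary[order(summary$K), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, runs = runs, master_seed = master_seed),
            class = "chase_ensemble")
}

#' Diversity versus social-tie strength, grouped by surviving-city count
#'
#' For every combination of `gamma` and `K`, runs `n_realizations`
#' simulations on fresh random maps; the inverse Simpson indices of all
#' surviving cities are then pooled across runs and `K` values into
#' (`gamma`, surviving-count) cells and summarized as boxplot statistics.
#' Grouping by how many cities survive matters because the surviving
#' count strongly constrains diversity — with a single survivor everyone
#' is in one city and `S` equals the number of origins exactly.
#'
#' @param K_values Characteristic sizes pooled into the ensemble
#'   (default `seq(4000, 12000, by = 1000)`).
#' @param gamma_values Social-tie weights to compare (default
#'   `c(1, 10, 50)`).
#' @param tau_beta Mindset timescale (default 120).
#' @param n_realizations Runs per (`gamma`, `K`) combination.
#' @param master_seed Integer master seed.
#' @inheritParams k_sweep
#' @return An object of class `chase_diversity`: list with `cells`
#'   (data.frame of boxplot statistics per `gamma` and `n_surviving`),
#'   `samples` (named list of the pooled `S` values per cell), `runs`
#'   (per-run records incl. seeds), and `master_seed`. Empty cells are
#'   simply absent.
#' @examples
#' gd <- gamma_diversity(K_values = 5000, gamma_values = c(1, 50),
#'                       n_realizations = 2, master_seed = 1,
#'                       params = chase_params(steps = 200))
#' gd$cells
#' @export
gamma_diversity <- function(K_values = seq(4000, 12000, by = 1000),
                            gamma_values = c(1, 10, 50), tau_beta = 120,
                            n_realizations = 100, master_seed = 1,
                            params = chase_params(), L = 10, d_min = 0.05) {
  stopifnot(n_realizations >= 1)
  params$tau_beta <- tau_beta
  params <- validate_params(params)
  grid <- expand.grid(K = K_values, gamma = gamma_values,
                      replicate = seq_len(n_realizations))
  grid$seed <- derive_seeds(master_seed, nrow(grid))

  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$gamma <- grid$gamma[i]
    map <- generate_map(L = L, K = grid$K[i], seed = grid$seed[i],
                        d_min = d_min)
    sim <- run_chase(map, p, record = "final")
    surv <- surviving_cities(sim$final, p$epsilon)
    S <- apply(sim$final[surv$mask, , drop = FALSE], 1, simpson_index)
    list(n_surviving = surv$count, S = S)
  })
  grid$n_surviving <- vapply(res, `[[`, numeric(1), "n_surviving")

  key <- paste(grid$gamma, grid$n_surviving, sep = "|")
  samples <- lapply(split(seq_len(nrow(grid)), key), function(idx) {
    unlist(lapply(res[idx], `[[`, "S"), use.names = FALSE)
  })
  samples <- samples[vapply(samples, length, integer(1)) > 0]

  cells <- do.call(rbind, lapply(names(samples), function(k) {
    parts <- as.numeric(strsplit(k, "|", fixed = TRUE)[[1]])
    bs <- boxplot_stats(samples[[k]])
    data.frame(gamma = parts[1], n_surviving = parts[2],
               tau_beta = tau_beta,
               n_runs = sum(key == k), n_cities = bs$n,
               S_median = bs$median, S_q25 = bs$q25, S_q75 = bs$q75,
               whisker_lo = bs$whisker_lo, whisker_hi = bs$whisker_hi,
               n_outliers = length(bs$outliers))
  }))
  cells <- cells[order(cells$gamma, cells$n_surviving), ]
  rownames(cells) <- NULL
  structure(list(cells = cells, samples = samples, runs = grid,
                 master_seed = master_seed),
            class = "chase_diversity")
}

#' Write an ensemble summary to JSON and flat CSV
#'
#' The JSON file carries the full nested summary including per-run seeds;
#' the CSV flattens the per-cell statistics with columns
#' `K,gamma,tau_beta,n_surviving,mean_surviving,S_median,S_q25,S_q75,n_runs`
#' (fields that do not apply to the experiment type are empty).
#'
#' @param x A `chase_ensemble` (from [k_sweep()]) or `chase_diversity`
#'   (from [gamma_diversity()]).
#' @param dir Output directory (created if needed).
#' @param name Basename for the two files (default from the class).
#' @return Invisibly, the paths written.
#' @export
write_ensemble <- function(x, dir, name = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(name)) {
    name <- if (inherits(x, "chase_ensemble")) "k_sweep" else "gamma_diversity"
  }
  json_path <- file.path(dir, paste0(name, ".json"))
  csv_path <- file.path(dir, paste0(name, ".csv"))
  flat_cols <- c("K", "gamma", "tau_beta", "n_surviving", "mean_surviving",
                 "S_median", "S_q25", "S_q75", "n_runs")
  if (inherits(x, "chase_ensemble")) {
    flat <- x$summary
    flat$n_surviving <- NA
    flat$S_median <- NA
    flat$S_q25 <- NA
    flat$S_q75 <- NA
  } else if (inherits(x, "chase_diversity")) {
    flat <- x$cells
    flat$K <- NA
    flat$mean_surviving <- NA
  } else {
    stop("`x` must come from k_sweep() or gamma_diversity()", call. = FALSE)
  }
  utils::write.csv(flat[flat_cols], csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(x), json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(c(json = json_path, csv = csv_path))
}
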