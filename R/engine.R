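#' Initialize a simulation state
#'
#' Builds the day-0 condition of the model: a single tumor cell at the grid
#' center, `N_D` inactive DCs and `N_T` inactive T lymphocytes placed at
#' distinct uniformly random empty sites, and all humoral quantities at zero.
#'
#' The default oxygen initial condition (`oxygen_init = "equilibrated"`) is
#' the no-tumor steady state of the boundary-vessel supply: a uniform field
#' at `U_boundary`, representing vascularized tissue that has equilibrated
#' before the tumor is established; hypoxia then develops as the growing
#' tumor consumes oxygen. `oxygen_init = "zero"` instead starts the interior
#' anoxic (concentration zero away from the boundary), so the whole tissue
#' is maximally hypoxic until the diffusive front arrives -- a transient that
#' dominates the early dynamics and is provided for comparison only.
#'
#' @param params Model parameters.
#' @param seed Optional integer seed (calls `set.seed()`); when `NULL` the
#'   current RNG state is used.
#' @param oxygen_init `"equilibrated"` (default) or `"zero"`; see Details.
#' @return A list of class `"tme_state"` combining the lattice, the oxygen
#'   field and the humoral state, plus the step counter `t = 0`.
#' @export
initialize_state <- function(params = default_parameters(), seed = NULL,
                             oxygen_init = c("equilibrated", "zero")) {
  oxygen_init <- match.arg(oxygen_init)
  validate_parameters(params)
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  if (params$N_D + params$N_T + 1 > N * N) {
    stop("grid too small for ", params$N_D, " DCs + ", params$N_T,
         " T cells + 1 tumor cell")
  }
  lat <- new_lattice(N)
  ctr <- N %/% 2L + 1L
  lat$kind[ctr, ctr] <- 1L
  emp <- which(lat$kind == 0L)
  pick <- sample(emp, params$N_D + params$N_T)
  if (params$N_D > 0) lat$kind[pick[seq_len(params$N_D)]] <- 2L
  if (params$N_T > 0) lat$kind[pick[params$N_D + seq_len(params$N_T)]] <- 4L
  U <- if (oxygen_init == "equilibrated") {
    matrix(params$U_boundary, N, N)
  } else {
    new_oxygen_field(N, params$U_boundary)
  }
  state <- c(unclass(lat), list(
    U = U,
    Ad = 0, px = 0, s_raw = 0,
    s_buf = numeric(params$M), s_pos = 1L, S_t = 0,
    t = 0L
  ))
  class(state) <- "tme_state"
  state
}

#' Run one simulation replicate
#'
#' Executes `horizon_days` days of the model (720 steps per day at the
#' default 2-minute step). Each step applies, in order: protocol doses (DC
#' vaccine placement, then the inhibitor boluses with their decay), the
#' oxygen diffusion sweep, the adenosine update driven by the mean oxygen
#' over the tumor neighborhood, and finally the agent phase -- every agent,
#' in a freshly shuffled order, performs its interaction rule and then its
#' movement. Runs are bit-reproducible from `(seed, params, protocol)`.
#'
#' @param params Model parameters.
#' @param protocol A `"tme_protocol"` or `NULL` for no treatment.
#' @param seed Optional integer seed.
#' @param horizon_days Simulated horizon in days (> 0; default 18).
#' @param record_every Recording interval in steps (default 60, i.e. 2 h).
#' @param state Optional pre-built `"tme_state"` to continue from; by default
#'   a fresh state is initialized (consuming the seeded RNG first).
#' @return A list of class `"tme_run"` with elements `trajectory` (a
#'   data.frame with one row per recording point: step, day, tumor site count
#'   and volume in mm^3, per-type immune counts, adenosine, drug levels, mean
#'   tumor-neighborhood oxygen, ambient and effector-averaged cytotoxicity,
#'   the count of effectors within Chebyshev distance 2 of the tumor, and
#'   cumulative division/kill/injection counters) and `state` (the final
#'   `"tme_state"`).
#' @export
run_simulation <- function(params = default_parameters(), protocol = NULL,
                           seed = NULL, horizon_days = 18,
                           record_every = 60L, state = NULL) {
  validate_parameters(params)
  if (horizon_days <= 0) stop("'horizon_days' must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- initialize_state(params)
  sched <- protocol_steps(protocol, params)
  n_steps <- as.integer(round(horizon_days * steps_per_day(params)))
  res <- cpp_simulate(state, params,
                      sched$px_steps, sched$px_amounts,
                      sched$s_steps, sched$s_amounts,
                      sched$dc_steps, sched$dc_counts,
                      n_steps, as.integer(record_every))
  if (res$dc_shortfall > 0) {
    warning("DC vaccine: ", res$dc_shortfall,
            " cells could not be placed (no empty sites)")
  }
  traj <- as.data.frame(res$records)
  traj$day <- traj$step * params$dt_minutes / (24 * 60)
  traj$volume_mm3 <- tumor_volume_mm3(traj$tumor_sites, params)
  traj <- traj[, c("step", "day", "tumor_sites", "volume_mm3",
                   setdiff(names(traj), c("step", "day", "tumor_sites",
                                          "volume_mm3")))]
  out <- list(trajectory = traj, state = structure(res$state,
                                                   class = "tme_state"),
              params = params, protocol = protocol)
  class(out) <- "tme_run"
  out
}

#' Tumor volume from occupied sites
#'
#' Converts a 2D tumor site count into a 3D volume: each site covers
#' `site_area_mm2` (1e-4 mm^2 at 10 um spacing) and the monolayer area is
#' scaled by `volume_factor` (2200) to account for volumetric expansion in
#' three dimensions, giving 0.22 mm^3 per site at the defaults.
#'
#' @param n_sites Number of tumor-occupied sites (vectorized, >= 0).
#' @param params Model parameters.
#' @return Volume in mm^3.
#' @export
tumor_volume_mm3 <- function(n_sites, params = default_parameters()) {
  if (any(n_sites < 0)) stop("'n_sites' must be non-negative")
  n_sites * params$site_area_mm2 * params$volume_factor
}

#' Run and aggregate replicate simulations
#'
#' Runs one replicate per seed and aggregates the recorded series at daily
#' resolution: the mean and the 95% confidence interval of the mean
#' (half-width `1.96 * sd / sqrt(n)`, zero for a single replicate) for each
#' series, plus the two scalar protocol summaries -- the tumor volume
#' averaged over the horizon and the final-day tumor volume.
#'
#' @param params Model parameters.
#' @param protocol A `"tme_protocol"` or `NULL`.
#' @param seeds Integer vector of replicate seeds (replicate `i` runs with
#'   `seeds[i]`).
#' @param horizon_days Simulated horizon in days.
#' @param record_every Recording interval in steps; must divide the number of
#'   steps per day.
#' @return A list of class `"tme_replicates"`: `days`, `series` (a named list
#'   of day x replicate matrices), `mean`/`ci_lo`/`ci_hi` (data.frames at
#'   daily resolution), `per_replicate` (scalar summaries per seed) and
#'   `summary` (means and CI half-widths of the scalar summaries).
#' @export
run_replicates <- function(params = default_parameters(), protocol = NULL,
                           seeds = 1:30, horizon_days = 18,
                           record_every = 60L) {
  if (length(seeds) < 1) stop("at least one seed is required")
  spd <- steps_per_day(params)
  if (spd %% record_every != 0) {
    stop("'record_every' must divide the number of steps per day (", spd, ")")
  }
  runs <- lapply(seeds, function(s) {
    run_simulation(params, protocol, seed = s, horizon_days = horizon_days,
                   record_every = record_every)$trajectory
  })
  daily <- lapply(runs, function(tr) tr[tr$step %% spd == 0, , drop = FALSE])
  days <- daily[[1]]$day
  series_names <- setdiff(names(daily[[1]]), c("step", "day"))
  series <- lapply(series_names, function(nm) {
    matrix(unlist(lapply(daily, `[[`, nm)), nrow = length(days))
  })
  names(series) <- series_names
  n <- length(seeds)
  agg <- function(f) {
    as.data.frame(lapply(series, function(m) apply(m, 1, f)))
  }
  mu <- agg(function(x) mean(x))
  halfw <- agg(function(x) if (length(x) > 1) 1.96 * sd(x) / sqrt(length(x))
               else 0)
  per_rep <- data.frame(
    seed = seeds,
    avg_volume_mm3 = vapply(runs, function(tr) mean(tr$volume_mm3), 0),
    final_volume_mm3 = vapply(runs, function(tr) tr$volume_mm3[nrow(tr)], 0)
  )
  ci <- function(x) if (length(x) > 1) 1.96 * sd(x) / sqrt(length(x)) else 0
  out <- list(
    days = days, series = series, mean = mu,
    ci_lo = mu - halfw, ci_hi = mu + halfw,
    per_replicate = per_rep,
    summary = list(
      n = n,
      avg_volume_mean = mean(per_rep$avg_volume_mm3),
      avg_volume_ci = ci(per_rep$avg_volume_mm3),
      final_volume_mean = mean(per_rep$final_volume_mm3),
      final_volume_ci = ci(per_rep$final_volume_mm3)
    )
  )
  class(out) <- "tme_replicates"
  out
}

#' @export
print.tme_replicates <- function(x, ...) {
  s <- x$summary
  cat("Replicate summary over", s$n, "runs,", max(x$days), "days\n")
  cat(sprintf("  avg tumor volume:    %.2f mm^3 (95%% CI +/- %.2f)\n",
              s$avg_volume_mean, s$avg_volume_ci))
  cat(sprintf("  final tumor volume:  %.2f mm^3 (95%% CI +/- %.2f)\n",
              s$final_volume_mean, s$final_volume_ci))
  invisible(x)
}

#' @export
print.tme_run <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat("Tumor-immune simulation run:", nrow(tr), "recorded points,",
      sprintf("%.1f days\n", last$day))
  cat(sprintf("  final: %d tumor sites (%.2f mm^3), %d effectors, %d Tregs, Ad = %.1f\n",
              last$tumor_sites, last$volume_mm3, last$n_effector,
              last$n_treg, last$adenosine))
  invisible(x)
}

#' @export
print.tme_state <- function(x, ...) {
  counts <- audit_lattice(x)
  cat("Simulation state at step", x$t, "\n")
  cat("  occupancy:", paste(sprintf("%s=%d", names(counts), counts),
                            collapse = ", "), "\n")
  cat(sprintf("  Ad = %.2f, px = %.3f, s_raw = %.1f, S_t = %.2f\n",
              x$Ad, x$px, x$s_raw,
              if (!is.null(x$S_t)) x$S_t else sum(x$s_buf) / length(x$s_buf)))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' @param run A `"tme_run"` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(run, path) {
  utils::write.csv(run$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Write a replicate-experiment summary as JSON
#'
#' Serializes a [run_replicates()] result to JSON: the protocol, the full
#' parameter set, the per-day means and 95% confidence bounds of every
#' recorded series, and the scalar summaries (horizon-averaged and final-day
#' tumor volume).
#'
#' @param replicates A `"tme_replicates"` object.
#' @param path Output JSON path.
#' @param protocol The protocol the experiment used (optional, for record).
#' @param params The parameter set used (optional, for record).
#' @return `path`, invisibly.
#' @export
write_experiment_json <- function(replicates, path, protocol = NULL,
                                  params = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required to write JSON summaries")
  }
  payload <- list(
    protocol = if (is.null(protocol)) NULL else unclass(protocol),
    params = if (is.null(params)) NULL else unclass(params),
    n_replicates = replicates$summary$n,
    days = replicates$days,
    mean = replicates$mean,
    ci_lo = replicates$ci_lo,
    ci_hi = replicates$ci_hi,
    summary = replicates$summary
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}
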