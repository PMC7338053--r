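#' Simulate tracked cisternal maturation events
#'
#' Generates per-event marker/cargo traces sampled the way maturation movies
#' are quantified: a window of Z-stacks every `frame_interval` seconds
#' (default 2 s over slightly more than 90 s) covering the early-to-late
#' transition of one tracked cisterna. Event amplitudes vary (moderate
#' expression, lognormal spread) and multiplicative measurement noise is
#' optional, so downstream normalization and alignment are exercised under
#' realistic scale variation.
#'
#' @param n_events Number of maturation events.
#' @param kinetics A [kinetic_config()]; `mode` selects wild-type or mutant
#'   cargo behaviour.
#' @param seed Integer seed.
#' @param frame_interval Sampling interval in seconds.
#' @param window Numeric length-2: window limits in seconds relative to the
#'   true transition midpoint.
#' @param noise_sd Fractional multiplicative measurement noise (0 = noiseless).
#' @param adaptors Include the adaptor channels (`adaptor_gga2`,
#'   `adaptor_apl2`)?
#' @return A list with `traces` (tibble: event, structure, role, frame,
#'   time_s, value) and `truth` (tibble: event, midpoint_s, departure_s, and
#'   adaptor arrival/departure times when requested).
#' @export
#' @examples
#' ev <- simulate_maturation_events(3, kinetic_config(), seed = 2)
#' dplyr::count(ev$traces, event)
simulate_maturation_events <- function(n_events, kinetics, seed = 1L,
                                       frame_interval = 2,
                                       window = c(-50, 50),
                                       noise_sd = 0,
                                       adaptors = FALSE) {
  stopifnot(inherits(kinetics, "vt_kinetics"), n_events >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  kin <- kinetics
  rel <- seq(window[1], window[2], by = frame_interval)
  out <- vector("list", n_events)
  tru <- vector("list", n_events)
  for (e in seq_len(n_events)) {
    # absolute midpoint placed off the grid so estimation is non-trivial
    m <- 100 + runif(1, 0, frame_interval)
    depart <- m + (1 - kin$transition_midpoint_frac) * kin$cisterna_lifetime
    times <- m + rel - runif(1, 0, frame_interval) # grid not phase-locked to m
    amp <- rlnorm(3, log(100), 0.3) # early, late, cargo amplitudes
    early <- amp[1] * (1 - sigmoid(times, m, kin$marker_tau))
    late <- amp[2] * sigmoid(times, m, kin$marker_tau) *
      (1 - sigmoid(times, depart, kin$marker_tau))
    cargo <- cisterna_cargo_series(times, m, kin, amp[3])
    df <- dplyr::bind_rows(
      tibble::tibble(role = "early_golgi", value = early),
      tibble::tibble(role = "late_golgi", value = late),
      tibble::tibble(role = "cargo", value = cargo)
    )
    tr <- tibble::tibble(event = e, midpoint_s = m, departure_s = depart)
    if (adaptors) {
      gga2 <- amp[2] * sigmoid(times, m, kin$marker_tau) *
        (1 - sigmoid(times, depart, kin$marker_tau))
      apl2 <- amp[2] *
        sigmoid(times, m + kin$adaptor_offset_arrival, kin$marker_tau) *
        (1 - sigmoid(times, depart + kin$adaptor_offset_departure, kin$marker_tau))
      df <- dplyr::bind_rows(df,
        tibble::tibble(role = "adaptor_gga2", value = gga2),
        tibble::tibble(role = "adaptor_apl2", value = apl2))
      tr$apl2_arrival_s <- m + kin$adaptor_offset_arrival
      tr$apl2_departure_s <- depart + kin$adaptor_offset_departure
    }
    nrole <- length(unique(df$role))
    df <- df |>
      dplyr::mutate(event = e,
                    structure = sprintf("cis_%03d", e),
                    frame = rep(seq_along(times), nrole),
                    time_s = rep(times, nrole))
    if (noise_sd > 0) {
      df <- df |>
        dplyr::group_by(.data$role) |>
        dplyr::mutate(value = pmax(0, .data$value +
          rnorm(dplyr::n(), 0, noise_sd * max(.data$value)))) |>
        dplyr::ungroup()
    }
    out[[e]] <- df
    tru[[e]] <- tr
  }
  list(
    traces = dplyr::bind_rows(out) |>
      dplyr::select("event", "structure", "role", "frame", "time_s", "value"),
    truth = dplyr::bind_rows(tru)
  )
}

#' Simulate whole-cell vacuolar delivery
#'
#' Emulates the 60-minute delivery experiment: per cell, cargo released from
#' ER aggregates transits the Golgi and loads onto PVE compartments at a
#' lognormally distributed loading time (`load_time_meanlog`,
#' `load_time_sdlog` of the kinetics), after which the PVE arm releases it to
#' the vacuole by continuous leak plus kiss-and-run bursts. Vacuolar cargo is
#' sampled once per minute. In `vps10_null` mode no cargo is sorted to the
#' PVE arm and the vacuole trace stays at (noise-level) zero.
#'
#' @param n_cells Number of cells.
#' @param kinetics A [kinetic_config()].
#' @param seed Integer seed.
#' @param frame_interval Sampling interval (s); default 60.
#' @param duration Movie duration (s); default 3600.
#' @param cargo_total True cargo content per cell (a.u.).
#' @param noise_sd Fractional multiplicative measurement noise on the sampled
#'   vacuole trace.
#' @return A list with `traces` (tibble: cell, structure, role, frame, time_s,
#'   value; vacuolar cargo per cell) and `truth` (per-cell load time, plus
#'   `late_tail_prob`, the true probability that a cell's loading time
#'   exceeds 15 min under the configured mixture).
#' @export
simulate_cell_population <- function(n_cells, kinetics, seed = 1L,
                                     frame_interval = 60, duration = 3600,
                                     cargo_total = 100, noise_sd = 0) {
  stopifnot(inherits(kinetics, "vt_kinetics"), n_cells >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  kin <- kinetics
  times <- seq(0, duration, by = frame_interval)
  n <- length(times)
  out <- vector("list", n_cells)
  loads <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    t_load <- rlnorm(1, kin$load_time_meanlog, kin$load_time_sdlog)
    loads[i] <- t_load
    if (kin$mode == "vps10_null") {
      vac <- rep(0, n)
    } else {
      # Golgi pool empties into the PVE over ~2 min around t_load
      golgi <- cargo_total * (1 - sigmoid(times, t_load, 30))
      inflow <- c(0, pmax(0, -diff(golgi)))
      ch <- pve_chain(times, 0, inflow, leak = kin$pve_leak_rate,
                      burst_rate = kin$burst_rate, kin = kin, active = TRUE)
      vac <- cumsum(ch$delivered)
    }
    if (noise_sd > 0) {
      vac <- pmax(0, vac + rnorm(n, 0, noise_sd * cargo_total))
    }
    out[[i]] <- tibble::tibble(
      cell = i, structure = sprintf("cell_%03d", i), role = "cargo",
      frame = seq_len(n), time_s = times, value = vac
    )
  }
  list(
    traces = dplyr::bind_rows(out),
    truth = list(
      load_time_s = loads,
      late_tail_prob = stats::plnorm(900, kin$load_time_meanlog,
                                     kin$load_time_sdlog, lower.tail = FALSE),
      cargo_total = cargo_total
    )
  )
}

#' Simulate PVE-to-vacuole transfer movies
#'
#' Emulates the photobleached 10-minute PVE transfer experiment: each movie is
#' one cell whose PVE compartment(s) start loaded with cargo (everything
#' outside the PVE having been bleached) and transfer it to the vacuole by
#' continuous release plus kiss-and-run bursts.
#'
#' @param n_movies Number of movies (cells).
#' @param kinetics A [kinetic_config()].
#' @param seed Integer seed.
#' @param n_pve PVE compartments per cell.
#' @param frame_interval Stack interval (s); default 5.
#' @param duration Movie duration (s); default 600.
#' @param cargo_pve Initial cargo per PVE (a.u.).
#' @param noise_sd Fractional multiplicative measurement noise.
#' @param quiescent_prob Overrides the kinetics' quiescent probability (the
#'   published analysis selected delivery-active compartments).
#' @return A list with `traces` (tibble: movie, structure, class, role, frame,
#'   time_s, value; PVE and vacuole cargo) and `truth` (realized burst
#'   schedule per movie/PVE).
#' @export
simulate_burst_movies <- function(n_movies, kinetics, seed = 1L, n_pve = 1,
                                  frame_interval = 5, duration = 600,
                                  cargo_pve = 100, noise_sd = 0,
                                  quiescent_prob = NULL) {
  stopifnot(inherits(kinetics, "vt_kinetics"), n_movies >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  kin <- kinetics
  if (!is.null(quiescent_prob)) kin$quiescent_prob <- quiescent_prob
  times <- seq(0, duration, by = frame_interval)
  n <- length(times)
  traces <- list()
  sched <- list()
  activity <- list()
  for (mvi in seq_len(n_movies)) {
    vac <- numeric(n)
    for (p in seq_len(n_pve)) {
      active <- runif(1) >= kin$quiescent_prob
      ch <- pve_chain(times, cargo_pve, numeric(n), leak = kin$pve_leak_rate,
                      burst_rate = kin$burst_rate, kin = kin, active = active)
      vac <- vac + cumsum(ch$delivered)
      sid <- sprintf("m%03d_pve_%02d", mvi, p)
      traces[[length(traces) + 1L]] <- tibble::tibble(
        movie = mvi, structure = sid, class = "pve", role = "cargo",
        frame = seq_len(n), time_s = times, value = ch$series
      )
      if (nrow(ch$bursts)) {
        sched[[length(sched) + 1L]] <- ch$bursts |>
          dplyr::mutate(movie = mvi, structure = sid, .before = 1)
      }
      activity[[length(activity) + 1L]] <- tibble::tibble(
        movie = mvi, structure = sid, active = active
      )
    }
    traces[[length(traces) + 1L]] <- tibble::tibble(
      movie = mvi, structure = sprintf("m%03d_vacuole", mvi), class = "vacuole",
      role = "cargo", frame = seq_len(n), time_s = times, value = vac
    )
  }
  tr <- dplyr::bind_rows(traces)
  if (noise_sd > 0) {
    tr <- tr |>
      dplyr::group_by(.data$structure) |>
      dplyr::mutate(value = pmax(0, .data$value +
        rnorm(dplyr::n(), 0, noise_sd * max(.data$value)))) |>
      dplyr::ungroup()
  }
  list(
    traces = tr,
    truth = list(
      activity = dplyr::bind_rows(activity),
      burst_schedule = if (length(sched)) dplyr::bind_rows(sched) else
        tibble::tibble(movie = integer(), structure = character(),
                       time_s = numeric(), frame = integer(),
                       fraction = numeric(), transferred = numeric()),
      duration_s = duration, cargo_pve = cargo_pve
    )
  )
}
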