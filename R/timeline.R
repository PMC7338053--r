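#' @importFrom rlang .data
#' @importFrom stats rnorm rpois runif rlnorm median sd setNames
NULL

sigmoid <- function(t, center, tau) 1 / (1 + exp(-(t - center) / tau))

# Truncated-normal sampler by rejection; support is narrow relative to the
# parent so rejection is cheap and exactly respects the bounds.
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x > lower & x < upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Process one PVE compartment over the frame grid: continuous release at
# `leak`, plus instantaneous Poisson-scheduled bursts, plus external inflow
# credited at the start of each interval. Returns the remaining-cargo series
# (length = length(times)), the per-frame amount delivered to the vacuole, and
# the realized burst schedule. Bookkeeping is exact: series[k] =
# series[k-1] + inflow[k] - delivered[k].
pve_chain <- function(times, r0, inflow, leak, burst_rate, kin, active = TRUE) {
  n <- length(times)
  series <- numeric(n)
  delivered <- numeric(n)
  series[1] <- r0
  bursts <- list()
  if (!active) {
    leak <- 0
    burst_rate <- 0
  }
  for (k in seq_len(n)[-1]) {
    t0 <- times[k - 1]
    t1 <- times[k]
    r <- series[k - 1] + inflow[k]
    r_start <- r
    n_ev <- if (burst_rate > 0) rpois(1, burst_rate * (t1 - t0)) else 0L
    if (n_ev > 0) {
      tb <- sort(runif(n_ev, t0, t1))
      fr <- rtruncnorm1(n_ev, kin$burst_fraction_mean, kin$burst_fraction_sd,
                        kin$burst_fraction_range[1], kin$burst_fraction_range[2])
      tcur <- t0
      for (i in seq_len(n_ev)) {
        r <- r * exp(-leak * (tb[i] - tcur))
        amt <- r * fr[i]
        bursts[[length(bursts) + 1L]] <- tibble::tibble(
          time_s = tb[i], frame = k, fraction = fr[i], transferred = amt
        )
        r <- r - amt
        tcur <- tb[i]
      }
      r <- r * exp(-leak * (t1 - tcur))
    } else {
      r <- r * exp(-leak * (t1 - t0))
    }
    series[k] <- r
    delivered[k] <- r_start - r
  }
  list(
    series = series,
    delivered = delivered,
    bursts = if (length(bursts)) dplyr::bind_rows(bursts) else
      tibble::tibble(time_s = numeric(), frame = integer(),
                     fraction = numeric(), transferred = numeric())
  )
}

# Multiplicative AR(1) fluctuation for the PVE marker: exp of a stationary
# AR(1) in log space, so the signal fluctuates but never reaches zero.
ar1_fluct <- function(n, rho, sd) {
  if (sd <= 0) return(rep(1, n))
  a <- numeric(n)
  a[1] <- rnorm(1, 0, sd / sqrt(1 - rho^2))
  for (k in seq_len(n)[-1]) a[k] <- rho * a[k - 1] + rnorm(1, 0, sd)
  exp(a)
}

place_compartments <- function(optics, kin, n_cisternae, n_pve) {
  lx <- optics$n_x * optics$voxel_xy / 1000
  ly <- optics$n_y * optics$voxel_xy / 1000
  lz <- optics$n_z * optics$voxel_z
  vac_c <- c(x = lx / 2, y = ly / 2, z = lz / 2)
  rows <- list(tibble::tibble(
    id = "vacuole", class = "vacuole",
    x_um = unname(vac_c["x"]), y_um = unname(vac_c["y"]),
    z_um = unname(vac_c["z"]), radius_um = kin$vacuole_radius
  ))
  # PVE compartments sit on the vacuole surface (within one PVE radius of it),
  # spread in the equatorial plane.
  if (n_pve > 0) {
    ang <- runif(n_pve, 0, 2 * pi)
    d <- kin$vacuole_radius + runif(n_pve, 0, 1) * kin$pve_radius
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("pve_%02d", seq_len(n_pve)), class = "pve",
      x_um = unname(vac_c["x"]) + d * cos(ang),
      y_um = unname(vac_c["y"]) + d * sin(ang),
      z_um = unname(vac_c["z"]),
      radius_um = kin$pve_radius
    )
  }
  if (n_cisternae > 0) {
    # cytoplasmic positions clear of the vacuole and of the field border
    # (border margin = the 4-sigma PSF support used by the renderer)
    margin <- max(4 * optics$psf_sigma_xy / 1000, 0.3)
    margin_z <- min(4 * optics$psf_sigma_z, lz * 0.45)
    xs <- ys <- zs <- numeric(n_cisternae)
    for (i in seq_len(n_cisternae)) {
      repeat {
        p <- c(runif(1, margin, lx - margin), runif(1, margin, ly - margin),
               runif(1, margin_z, lz - margin_z))
        if (sqrt(sum((p - vac_c)^2)) > kin$vacuole_radius + 0.5) break
      }
      xs[i] <- p[1]; ys[i] <- p[2]; zs[i] <- p[3]
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("cis_%02d", seq_len(n_cisternae)), class = "cisterna",
      x_um = xs, y_um = ys, z_um = zs, radius_um = kin$cisterna_radius
    )
  }
  dplyr::bind_rows(rows)
}

cisterna_cargo_series <- function(times, midpoint, kin, c0) {
  switch(kin$mode,
    wildtype = ,
    apl4_null = c0 * ifelse(times < midpoint, 1,
                            exp(-kin$cargo_exit_rate * (times - midpoint))),
    gga_null = rep(c0, length(times)),
    vps10_null = {
      # transient AP-1-driven recycling overshoot around the transition,
      # then persistence (secretory-cargo-like behaviour)
      bump <- (kin$cargo_overshoot - 1) * exp(-((times - midpoint - 10)^2) / (2 * 15^2))
      c0 * (1 + bump)
    }
  )
}

#' Simulate compartment kinetics for one cell
#'
#' Generates per-compartment true fluorescence time series for a single cell:
#' maturing Golgi cisternae (early marker decays as the late marker rises,
#' crossing at the transition midpoint, with maturation-coupled cargo exit),
#' PVE compartments that release cargo to the vacuole continuously and in
#' stochastic kiss-and-run bursts, and the vacuole that receives everything a
#' PVE delivers in the same frame. Cargo leaving cisternae is credited to the
#' PVE compartments (split equally), so in the vacuole-directed modes the
#' summed cargo over all compartments is conserved frame by frame.
#'
#' @param kinetics A [kinetic_config()].
#' @param optics An [optics_config()]; supplies the frame grid and field size.
#' @param n_cisternae,n_pve Numbers of Golgi cisternae and PVE compartments.
#' @param seed Integer seed; the run is fully reproducible given
#'   `(kinetics, optics, n_cisternae, n_pve, seed)`.
#' @param cargo_cisterna,cargo_pve Initial cargo content (a.u.) per cisterna /
#'   per PVE compartment.
#' @param marker_amp Marker channel amplitude (a.u.).
#' @param adaptors If `TRUE`, cisternae also carry the clathrin adaptor
#'   channels (`adaptor_gga2`, `adaptor_apl2`) with the configured timing
#'   offsets.
#'
#' @return A list of class `"vt_timeline"` with elements `times`,
#'   `compartments` (tibble: id, class, position, radius, quiescent flag),
#'   `signals` (tibble: frame, time_s, id, class, role, value), `truth`
#'   (burst schedule, transition midpoints, adaptor times, conserved cargo
#'   total), and the two configs.
#' @export
#' @examples
#' tl <- simulate_timeline(kinetic_config(), optics_config(n_frames = 20),
#'                         n_cisternae = 1, n_pve = 1, seed = 7)
#' dplyr::count(tl$signals, role)
simulate_timeline <- function(kinetics, optics, n_cisternae = 2, n_pve = 1,
                              seed = 1L, cargo_cisterna = 100, cargo_pve = 100,
                              marker_amp = 100, adaptors = FALSE) {
  stopifnot(inherits(kinetics, "vt_kinetics"), inherits(optics, "vt_optics"))
  if (n_pve < 0 || n_cisternae < 0) stop("counts must be >= 0", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  kin <- kinetics
  n <- optics$n_frames
  times <- (seq_len(n) - 1) * optics$frame_interval
  comp <- place_compartments(optics, kin, n_cisternae, n_pve)
  comp$quiescent <- FALSE
  if (n_pve > 0) {
    is_pve <- comp$class == "pve"
    comp$quiescent[is_pve] <- runif(sum(is_pve)) < kin$quiescent_prob
  }

  sig <- list()
  midpoints <- list()
  adap <- list()

  # --- cisternae ------------------------------------------------------------
  cis_ids <- comp$id[comp$class == "cisterna"]
  cis_exit <- numeric(n) # summed per-frame cargo leaving cisternae
  duration <- times[n]
  for (j in seq_along(cis_ids)) {
    m <- runif(1, 0.2 * duration, 0.8 * duration)
    birth <- m - kin$transition_midpoint_frac * kin$cisterna_lifetime
    depart <- m + (1 - kin$transition_midpoint_frac) * kin$cisterna_lifetime
    early <- marker_amp * (1 - sigmoid(times, m, kin$marker_tau))
    late <- marker_amp * sigmoid(times, m, kin$marker_tau) *
      (1 - sigmoid(times, depart, kin$marker_tau))
    cargo <- cisterna_cargo_series(times, m, kin, cargo_cisterna)
    dec <- pmax(0, -diff(cargo))
    cis_exit[-1] <- cis_exit[-1] + dec
    rows <- list(
      tibble::tibble(role = "early_golgi", value = early),
      tibble::tibble(role = "late_golgi", value = late),
      tibble::tibble(role = "cargo", value = cargo)
    )
    if (adaptors) {
      gga2 <- marker_amp * sigmoid(times, m, kin$marker_tau) *
        (1 - sigmoid(times, depart, kin$marker_tau))
      apl2 <- marker_amp *
        sigmoid(times, m + kin$adaptor_offset_arrival, kin$marker_tau) *
        (1 - sigmoid(times, depart + kin$adaptor_offset_departure, kin$marker_tau))
      rows <- c(rows, list(
        tibble::tibble(role = "adaptor_gga2", value = gga2),
        tibble::tibble(role = "adaptor_apl2", value = apl2)
      ))
      adap[[length(adap) + 1L]] <- tibble::tibble(
        id = cis_ids[j],
        adaptor = c("adaptor_gga2", "adaptor_apl2"),
        arrival_s = c(m, m + kin$adaptor_offset_arrival),
        departure_s = c(depart, depart + kin$adaptor_offset_departure)
      )
    }
    sig[[length(sig) + 1L]] <- dplyr::bind_rows(rows) |>
      dplyr::mutate(frame = rep(seq_len(n), length(rows)),
                    time_s = rep(times, length(rows)),
                    id = cis_ids[j], class = "cisterna")
    midpoints[[length(midpoints) + 1L]] <- tibble::tibble(
      id = cis_ids[j], birth_s = birth, midpoint_s = m, departure_s = depart
    )
  }
  # In vps10_null mode the receptor is absent: nothing is handed to the
  # PVE/vacuole arm (the cargo is eventually secreted instead).
  if (kin$mode == "vps10_null") cis_exit[] <- 0

  # --- PVE compartments and the vacuole --------------------------------------
  pve_ids <- comp$id[comp$class == "pve"]
  vac_cargo <- numeric(n)
  burst_sched <- list()
  for (j in seq_along(pve_ids)) {
    inflow <- cis_exit / max(1, length(pve_ids))
    ch <- pve_chain(times, cargo_pve, inflow,
                    leak = kin$pve_leak_rate, burst_rate = kin$burst_rate,
                    kin = kin, active = !comp$quiescent[comp$id == pve_ids[j]])
    vac_cargo <- vac_cargo + cumsum(ch$delivered)
    marker <- marker_amp * ar1_fluct(n, kin$vps8_ar_rho, kin$vps8_ar_sd)
    sig[[length(sig) + 1L]] <- dplyr::bind_rows(
      tibble::tibble(role = "pve", value = marker),
      tibble::tibble(role = "cargo", value = ch$series)
    ) |>
      dplyr::mutate(frame = rep(seq_len(n), 2), time_s = rep(times, 2),
                    id = pve_ids[j], class = "pve")
    if (nrow(ch$bursts)) {
      burst_sched[[length(burst_sched) + 1L]] <-
        dplyr::mutate(ch$bursts, id = pve_ids[j], .before = 1)
    }
  }
  if (n_pve == 0) vac_cargo <- cumsum(cis_exit)
  sig[[length(sig) + 1L]] <- dplyr::bind_rows(
    tibble::tibble(role = "vacuole", value = rep(marker_amp, n)),
    tibble::tibble(role = "cargo", value = vac_cargo)
  ) |>
    dplyr::mutate(frame = rep(seq_len(n), 2), time_s = rep(times, 2),
                  id = "vacuole", class = "vacuole")

  signals <- dplyr::bind_rows(sig) |>
    dplyr::select("frame", "time_s", "id", "class", "role", "value")
  cargo0 <- signals |>
    dplyr::filter(.data$role == "cargo", .data$frame == 1L) |>
    dplyr::pull("value") |>
    sum()

  truth <- list(
    burst_schedule = if (length(burst_sched)) dplyr::bind_rows(burst_sched) else
      tibble::tibble(id = character(), time_s = numeric(), frame = integer(),
                     fraction = numeric(), transferred = numeric()),
    midpoints = if (length(midpoints)) dplyr::bind_rows(midpoints) else
      tibble::tibble(id = character(), birth_s = numeric(),
                     midpoint_s = numeric(), departure_s = numeric()),
    adaptors = if (length(adap)) dplyr::bind_rows(adap) else
      tibble::tibble(id = character(), adaptor = character(),
                     arrival_s = numeric(), departure_s = numeric()),
    conserved_total_cargo = cargo0,
    quiescent = setNames(comp$quiescent, comp$id),
    seed = as.integer(seed)
  )
  structure(list(times = times, compartments = comp, signals = signals,
                 truth = truth, kinetics = kin, optics = optics),
            class = "vt_timeline")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.vt_timeline <- function(x, ...) {
  cat("<vt_timeline> ", length(x$times), " frames (",
      x$times[length(x$times)], " s), ",
      nrow(x$compartments), " compartments [",
      paste(sprintf("%s:%d", names(table(x$compartments$class)),
                    as.integer(table(x$compartments$class))), collapse = ", "),
      "], mode=", x$kinetics$mode, "\n", sep = "")
  invisible(x)
}

#' Photobleach everything except the PVE compartments
#'
#' Emulates the pre-acquisition photobleach used before PVE-to-vacuole
#' transfer movies: a bleach region covering all fluorescent structures except
#' the PVE compartments. At `at_frame` the cargo signal of every non-PVE
#' compartment (including the vacuole interior) is multiplied by
#' `1 - efficiency`. PVE cargo and all marker channels are untouched, and
#' cargo arriving in the vacuole after the bleach is not bleached (the
#' vacuole's post-bleach increments are preserved unscaled).
#'
#' @param timeline A `vt_timeline`.
#' @param efficiency Bleach efficiency in \[0, 1\].
#' @param at_frame Frame index (1-based) at which the bleach is applied.
#' @return The modified `vt_timeline`.
#' @export
apply_photobleach <- function(timeline, efficiency, at_frame) {
  stopifnot(inherits(timeline, "vt_timeline"))
  if (!is.numeric(efficiency) || efficiency < 0 || efficiency > 1) {
    stop("`efficiency` must lie in [0, 1]", call. = FALSE)
  }
  n <- length(timeline$times)
  if (at_frame < 1 || at_frame > n) stop("`at_frame` out of range", call. = FALSE)
  if (efficiency == 0) return(timeline)
  keep <- 1 - efficiency
  sig <- timeline$signals
  bleach_one <- function(value, cls) {
    if (cls == "vacuole") {
      inc <- c(0, pmax(0, diff(value)))
      out <- value
      idx <- seq(at_frame, n)
      out[idx] <- value[at_frame] * keep +
        cumsum(c(0, inc[idx][-1]))
      out
    } else {
      out <- value
      out[seq(at_frame, n)] <- out[seq(at_frame, n)] * keep
      out
    }
  }
  sig <- sig |>
    dplyr::group_by(.data$id, .data$role) |>
    dplyr::group_modify(function(df, key) {
      cls <- df$class[1]
      if (key$role == "cargo" && cls != "pve") {
        df$value <- bleach_one(df$value[order(df$frame)], cls)[order(order(df$frame))]
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("frame", "time_s", "id", "class", "role", "value") |>
    dplyr::arrange(.data$id, .data$role, .data$frame)
  timeline$signals <- sig
  timeline$truth$bleach <- list(efficiency = efficiency, at_frame = at_frame)
  timeline
}

#' Ground-truth signals in trace form
#'
#' Returns the simulator's true per-compartment fluorescence series as a tidy
#' trace table, the same shape produced by [extract_traces()] from a rendered
#' movie, so analyses can run either on truth or on measurements.
#'
#' @param timeline A `vt_timeline`.
#' @param noise_sd Optional multiplicative Gaussian measurement noise
#'   (fractional SD) added to the true values, floored at 0.
#' @return A tibble with columns `structure`, `class`, `role`, `frame`,
#'   `time_s`, `value`.
#' @export
timeline_traces <- function(timeline, noise_sd = 0) {
  stopifnot(inherits(timeline, "vt_timeline"))
  tr <- timeline$signals |>
    dplyr::transmute(structure = .data$id, class = .data$class,
                     role = .data$role, frame = .data$frame,
                     time_s = .data$time_s, value = .data$value)
  if (noise_sd > 0) {
    scale_ref <- tr |>
      dplyr::group_by(.data$structure, .data$role) |>
      dplyr::mutate(value = pmax(0, .data$value +
                                   rnorm(dplyr::n(), 0, noise_sd * max(.data$value)))) |>
      dplyr::ungroup()
    tr <- scale_ref
  }
  tr
}
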