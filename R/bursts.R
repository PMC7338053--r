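#' Resample a cargo trace at fixed interval boundaries
#'
#' Burst scoring examines the remaining-cargo series at fixed boundaries
#' (10 s by default). Each boundary takes the value of the frame nearest in
#' time, ties resolved toward the earlier frame.
#'
#' @param trace A data frame with `time_s` and `value` columns (one
#'   structure), or a numeric vector with times in `times`.
#' @param interval Boundary spacing in seconds.
#' @param times Frame times when `trace` is a numeric vector.
#' @return A tibble with `time_s` (boundary times) and `value`.
#' @export
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 600, 5), value = 100 * exp(-seq(0, 600, 5) / 400))
#' nrow(remaining_series(tr, 10))  # 61 boundaries over 10 min
remaining_series <- function(trace, interval = 10, times = NULL) {
  if (is.numeric(trace) && is.null(dim(trace))) {
    trace <- tibble::tibble(time_s = times, value = trace)
  }
  stopifnot(is.data.frame(trace), all(c("time_s", "value") %in% names(trace)))
  tt <- trace$time_s
  if (length(tt) < 2) stop("trace too short to resample", call. = FALSE)
  dt <- median(diff(sort(tt)))
  if (dt > interval + 1e-9) {
    stop("trace sampling (", dt, " s) is coarser than the scoring interval (",
         interval, " s)", call. = FALSE)
  }
  span <- range(tt)
  if (diff(span) < 2 * interval) {
    stop("trace span must cover at least two intervals", call. = FALSE)
  }
  bounds <- seq(span[1], span[2] + 1e-9, by = interval)
  idx <- vapply(bounds, function(b) {
    d <- abs(tt - b)
    which(d == min(d))[1] # ties toward the earlier frame
  }, integer(1))
  tibble::tibble(time_s = bounds, value = trace$value[idx])
}

#' Score kiss-and-run transfer bursts on a remaining-cargo series
#'
#' Scans consecutive interval boundaries of a PVE remaining-cargo series and
#' scores an interval as a burst when more than `threshold` (default 15%) of
#' the cargo remaining at the start of the interval is lost within it.
#' Intervals in which the series increases (noise, homotypic fusion) score a
#' fraction of 0. A floor guard suppresses calls once the compartment is
#' nearly empty (`remaining_before <= floor_frac * initial`). Consecutive
#' qualifying intervals are scored as separate bursts.
#'
#' @param remaining A tibble from [remaining_series()] (columns `time_s`,
#'   `value`) or a numeric series (then `interval` spacing is assumed).
#' @param threshold Burst threshold on the per-interval fraction.
#' @param floor_frac Floor guard as a fraction of the initial remaining cargo.
#' @param interval Spacing used when `remaining` is a bare numeric vector.
#' @return A tibble of class `"vt_burst_table"`, one row per interval:
#'   `index`, `t_start`, `t_end`, `remaining_before`, `transferred`,
#'   `fraction`, `is_burst`.
#' @export
#' @examples
#' detect_bursts(c(100, 100, 40, 40), interval = 10)
detect_bursts <- function(remaining, threshold = 0.15, floor_frac = 0.02,
                          interval = 10) {
  if (is.numeric(remaining) && is.null(dim(remaining))) {
    remaining <- tibble::tibble(
      time_s = (seq_along(remaining) - 1) * interval, value = remaining
    )
  }
  stopifnot(is.data.frame(remaining),
            all(c("time_s", "value") %in% names(remaining)))
  r <- remaining$value
  tt <- remaining$time_s
  if (length(r) < 2) stop("series must have at least two boundaries", call. = FALSE)
  if (r[1] <= 0) stop("initial remaining cargo must be positive", call. = FALSE)
  before <- r[-length(r)]
  after <- r[-1]
  transferred <- pmax(0, before - after)
  fraction <- ifelse(before > 0, transferred / before, 0)
  is_burst <- fraction > threshold & before > floor_frac * r[1]
  out <- tibble::tibble(
    index = seq_along(before),
    t_start = tt[-length(tt)], t_end = tt[-1],
    remaining_before = before, transferred = transferred,
    fraction = fraction, is_burst = is_burst
  )
  class(out) <- c("vt_burst_table", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "floor_frac") <- floor_frac
  attr(out, "final_remaining") <- r[length(r)]
  out
}

#' Summarize burst frequency and transfer fractions
#'
#' Collapses a burst table into the headline kiss-and-run statistics: burst
#' frequency (events per minute of movie), mean fraction of remaining cargo
#' transferred per burst, and the share of the movie's total net transfer
#' that occurred in burst intervals. When the matching vacuole cargo trace is
#' supplied, every burst interval is cross-checked for a corresponding
#' vacuole increase of at least half the PVE decrease, and discordant bursts
#' are counted in `n_unmatched`.
#'
#' @param table A `vt_burst_table` from [detect_bursts()].
#' @param vac_trace Optional vacuole cargo trace (`time_s`, `value`) on a grid
#'   at least as fine as the burst intervals.
#' @param denominator `"net_transfer"` (default: burst transfer relative to
#'   the total net decrease over the movie) or `"initial"` (relative to the
#'   initial remaining cargo).
#' @return A one-row tibble of class `"vt_burst_summary"`: `n_bursts`,
#'   `duration_min`, `frequency_per_min`, `mean_fraction_per_burst`,
#'   `total_fraction_in_bursts`, `n_unmatched`.
#' @export
summarize_bursts <- function(table, vac_trace = NULL,
                             denominator = c("net_transfer", "initial")) {
  stopifnot(inherits(table, "vt_burst_table"))
  denominator <- match.arg(denominator)
  duration_min <- (max(table$t_end) - min(table$t_start)) / 60
  bursts <- table[table$is_burst, ]
  n_bursts <- nrow(bursts)
  r_last <- attr(table, "final_remaining")
  if (is.null(r_last)) {
    r_last <- table$remaining_before[nrow(table)] - table$transferred[nrow(table)]
  }
  net_dec <- table$remaining_before[1] - r_last
  if (n_bursts > 0 && net_dec <= 0) {
    stop("bursts scored but no net decrease over the movie: inconsistent series",
         call. = FALSE)
  }
  denom <- if (denominator == "net_transfer") net_dec else
    table$remaining_before[1]
  total_fraction <- if (n_bursts == 0) {
    if (denom > 0) 0 else NA_real_
  } else {
    min(1, max(0, sum(bursts$transferred) / denom))
  }
  n_unmatched <- NA_integer_
  if (!is.null(vac_trace) && n_bursts > 0) {
    stopifnot(all(c("time_s", "value") %in% names(vac_trace)))
    vfun <- stats::approxfun(vac_trace$time_s, vac_trace$value, rule = 2)
    vac_inc <- vfun(bursts$t_end) - vfun(bursts$t_start)
    n_unmatched <- sum(vac_inc < 0.5 * bursts$transferred)
  }
  out <- tibble::tibble(
    n_bursts = n_bursts,
    duration_min = duration_min,
    frequency_per_min = n_bursts / duration_min,
    mean_fraction_per_burst = if (n_bursts) mean(bursts$fraction) else NA_real_,
    total_fraction_in_bursts = total_fraction,
    n_unmatched = n_unmatched
  )
  class(out) <- c("vt_burst_summary", class(out))
  out
}

#' Identify delivery-active PVE compartments
#'
#' A PVE compartment is considered delivery-active over a movie when its net
#' cargo transfer exceeds `min_net_frac` of its initial cargo; quiescent
#' compartments are excluded from burst statistics the way the published
#' analysis restricted itself to compartments active throughout the imaging
#' period.
#'
#' @param traces Tidy trace tibble (`structure`, `time_s`, `value`), PVE cargo
#'   traces.
#' @param min_net_frac Minimum net fractional transfer to call a compartment
#'   active.
#' @return Character vector of active structure ids.
#' @export
active_pve <- function(traces, min_net_frac = 0.1) {
  stopifnot(all(c("structure", "time_s", "value") %in% names(traces)))
  traces |>
    dplyr::group_by(.data$structure) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::summarise(
      net = dplyr::first(.data$value) - dplyr::last(.data$value),
      init = dplyr::first(.data$value), .groups = "drop"
    ) |>
    dplyr::filter(.data$init > 0, .data$net > min_net_frac * .data$init) |>
    dplyr::pull("structure")
}

#' Burst statistics across a set of movies
#'
#' Runs [remaining_series()], [detect_bursts()] and [summarize_bursts()] over
#' every active PVE cargo trace in a movie set and pools the results, both
#' per-burst (every burst weighted equally) and per-movie (each movie's
#' summary weighted equally).
#'
#' @param traces Tidy trace tibble with `structure`, `class`, `time_s`,
#'   `value`; PVE cargo traces are rows with `class == "pve"`.
#' @param interval,threshold,floor_frac Passed to the per-trace scoring.
#' @param min_net_frac Activity filter, see [active_pve()].
#' @return A list with `per_structure` (tibble of per-PVE summaries),
#'   `tables` (named list of burst tables) and `pooled` (one-row tibble:
#'   pooled frequency, per-burst and per-movie mean fractions, pooled burst
#'   share of transfer).
#' @export
burst_analysis <- function(traces, interval = 10, threshold = 0.15,
                           floor_frac = 0.02, min_net_frac = 0.1) {
  pve <- traces |> dplyr::filter(.data$class == "pve")
  act <- active_pve(pve, min_net_frac)
  pve <- pve |> dplyr::filter(.data$structure %in% act)
  if (!nrow(pve)) {
    stop("no active PVE cargo traces to analyze", call. = FALSE)
  }
  ids <- unique(pve$structure)
  tables <- list()
  sums <- list()
  for (sid in ids) {
    tr <- pve |> dplyr::filter(.data$structure == sid) |>
      dplyr::arrange(.data$time_s)
    rem <- remaining_series(tr, interval)
    tab <- detect_bursts(rem, threshold, floor_frac)
    tables[[sid]] <- tab
    sums[[sid]] <- summarize_bursts(tab) |>
      dplyr::mutate(structure = sid, .before = 1)
  }
  per <- dplyr::bind_rows(sums)
  all_bursts <- dplyr::bind_rows(lapply(tables, function(t) t[t$is_burst, ]))
  pooled <- tibble::tibble(
    n_structures = length(ids),
    n_bursts = sum(per$n_bursts),
    total_duration_min = sum(per$duration_min),
    frequency_per_min = sum(per$n_bursts) / sum(per$duration_min),
    mean_fraction_per_burst = if (nrow(all_bursts)) mean(all_bursts$fraction)
      else NA_real_,
    mean_fraction_per_movie = mean(per$mean_fraction_per_burst, na.rm = TRUE),
    total_fraction_in_bursts = {
      net <- vapply(tables, function(t) {
        t$remaining_before[1] - attr(t, "final_remaining")
      }, numeric(1))
      min(1, max(0, sum(all_bursts$transferred) / sum(net)))
    }
  )
  list(per_structure = per, tables = tables, pooled = pooled)
}
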