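trace_values <- function(trace) {
  if (is.data.frame(trace)) {
    stopifnot("value" %in% names(trace))
    trace$value
  } else {
    as.numeric(trace)
  }
}

trace_rescale <- function(trace, values) {
  if (is.data.frame(trace)) {
    trace$value <- values
    trace
  } else {
    values
  }
}

#' Normalize a trace to the mean of its three highest values
#'
#' Golgi marker traces are normalized to the average of the three highest
#' values measured; on noisy data this is more stable than dividing by the
#' single maximum. The operation is scale-invariant and idempotent.
#'
#' @param trace A numeric vector or a data frame with a `value` column.
#' @return The trace with `value` divided by the mean of its three largest
#'   values.
#' @export
#' @examples
#' normalize_top3(c(1, 2, 3, 4, 5))
normalize_top3 <- function(trace) {
  v <- trace_values(trace)
  if (length(v) < 3) stop("trace must have at least 3 values", call. = FALSE)
  top <- mean(sort(v, decreasing = TRUE)[1:3])
  if (top <= 0) stop("cannot normalize an all-zero trace", call. = FALSE)
  trace_rescale(trace, v / top)
}

#' Normalize a trace to its first or last six values
#'
#' For midpoint-aligned averaging, the reference level of each trace is the
#' mean of its first six values (cargo and the early marker, which start at
#' plateau) or its last six values (the late marker, which ends at plateau).
#'
#' @param trace A numeric vector or a data frame with a `value` column,
#'   ordered in time.
#' @param anchor `"head"` (first six values) or `"tail"` (last six).
#' @return The normalized trace.
#' @export
#' @examples
#' normalize_endpoint6(1:12, "head")  # divide by mean(1:6) = 3.5
normalize_endpoint6 <- function(trace, anchor = c("head", "tail")) {
  anchor <- match.arg(anchor)
  v <- trace_values(trace)
  if (length(v) < 6) stop("trace must have at least 6 values", call. = FALSE)
  ref <- if (anchor == "head") mean(v[1:6]) else mean(v[(length(v) - 5):length(v)])
  if (ref <= 0) stop("anchor-window mean must be positive", call. = FALSE)
  trace_rescale(trace, v / ref)
}

#' Transition midpoint of a maturation event
#'
#' The midpoint of the early-to-late transition is the time at which the
#' normalized late-marker trace first rises above the normalized early-marker
#' trace, linearly interpolated between the bracketing frames. When multiple
#' crossings exist (noise), the one nearest the late trace's half-maximum
#' time is taken.
#'
#' @param early,late Data frames with `time_s` and `value` (top3-normalized),
#'   on a common time grid.
#' @return The crossing time in seconds.
#' @export
#' @examples
#' t <- seq(0, 60, 2)
#' early <- tibble::tibble(time_s = t, value = 1 - t / 60)
#' late <- tibble::tibble(time_s = t, value = t / 60)
#' transition_midpoint(early, late)  # 30
transition_midpoint <- function(early, late) {
  stopifnot(all(c("time_s", "value") %in% names(early)),
            all(c("time_s", "value") %in% names(late)))
  tt <- intersect(early$time_s, late$time_s)
  if (length(tt) < 2) stop("traces must share a time grid", call. = FALSE)
  tt <- sort(tt)
  e <- early$value[match(tt, early$time_s)]
  l <- late$value[match(tt, late$time_s)]
  d <- l - e
  # indices i where the late trace crosses above the early trace in (i, i+1]
  up <- which(d[-length(d)] < 0 & d[-1] >= 0)
  if (d[1] >= 0 && all(d >= 0)) {
    stop("late trace never below early trace: not a maturation event",
         call. = FALSE)
  }
  if (!length(up)) {
    stop("no early-to-late crossing found: not a maturation event",
         call. = FALSE)
  }
  cross_t <- vapply(up, function(i) {
    if (d[i + 1] == d[i]) return(mean(tt[i:(i + 1)]))
    tt[i] + (0 - d[i]) / (d[i + 1] - d[i]) * (tt[i + 1] - tt[i])
  }, numeric(1))
  if (length(cross_t) == 1L) return(cross_t)
  half <- max(l) / 2
  ih <- which(l >= half)[1]
  t_half <- if (is.na(ih)) tt[which.max(l)] else tt[ih]
  cross_t[which.min(abs(cross_t - t_half))]
}

#' Align maturation events at their midpoints and average
#'
#' Re-indexes every event's traces to time relative to its transition
#' midpoint, snaps them to a common grid (`grid_interval`, nearest grid point
#' with ties toward earlier times), and averages per grid point and role.
#' Grid points to which fewer than `min_contrib` of the events contribute are
#' dropped.
#'
#' @param events Tidy tibble of normalized event traces with columns `event`,
#'   `role`, `time_s`, `value`.
#' @param midpoints Tibble with `event` and `midpoint_s`.
#' @param roles Roles to average; default all present.
#' @param grid_interval Grid spacing in seconds.
#' @param min_contrib Minimum fraction of events contributing at a grid point.
#' @return A tibble of class `"vt_aligned"`: `rel_time_s`, `role`, `mean`,
#'   `sem`, `n`. `sem` is `NA` where fewer than two events contribute.
#' @export
align_and_average <- function(events, midpoints, roles = NULL,
                              grid_interval = 2, min_contrib = 0.5) {
  stopifnot(all(c("event", "role", "time_s", "value") %in% names(events)),
            all(c("event", "midpoint_s") %in% names(midpoints)))
  if (!nrow(events)) stop("no events to average", call. = FALSE)
  if (is.null(roles)) roles <- unique(events$role)
  n_events <- length(unique(events$event))
  snapped <- events |>
    dplyr::filter(.data$role %in% roles) |>
    dplyr::inner_join(midpoints[, c("event", "midpoint_s")], by = "event") |>
    dplyr::mutate(rel = .data$time_s - .data$midpoint_s,
                  # nearest grid point, ties toward earlier time
                  grid = ifelse(
                    (.data$rel / grid_interval) %% 1 == 0.5,
                    floor(.data$rel / grid_interval) * grid_interval,
                    round(.data$rel / grid_interval) * grid_interval
                  )) |>
    dplyr::group_by(.data$event, .data$role, .data$grid) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  out <- snapped |>
    dplyr::group_by(.data$role, rel_time_s = .data$grid) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() >= 2) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= min_contrib * n_events) |>
    dplyr::arrange(.data$role, .data$rel_time_s)
  attr(out, "n_events") <- n_events
  class(out) <- c("vt_aligned", class(out))
  out
}

sustained_crossing <- function(tt, v, level, persist = 2L) {
  above <- v > level
  n <- length(v)
  arrival <- NA_real_
  for (i in seq_len(n - persist + 1L)) {
    if (all(above[i:(i + persist - 1L)])) {
      if (i == 1L) {
        arrival <- tt[1]
      } else {
        arrival <- tt[i - 1] + (level - v[i - 1]) / (v[i] - v[i - 1]) *
          (tt[i] - tt[i - 1])
      }
      break
    }
  }
  departure <- NA_real_
  for (i in rev(seq_len(n - persist + 1L))) {
    j <- i + persist - 1L
    if (all(!above[i:j])) {
      if (i == 1L) {
        departure <- tt[1]
      } else {
        departure <- tt[i - 1] + (level - v[i - 1]) / (v[i] - v[i - 1]) *
          (tt[i] - tt[i - 1])
      }
    } else if (!is.na(departure)) {
      break
    }
  }
  c(arrival = arrival, departure = departure)
}

#' Arrival and departure offsets of adaptor traces
#'
#' Measures when each trace arrives at and departs from a cisterna relative
#' to a reference trace. Arrival is the first time the (top3-normalized)
#' trace exceeds `level` and stays above it for at least two consecutive
#' frames, linearly interpolated at the crossing; departure is the last such
#' sustained fall below `level`. Offsets are `other - reference`; traces that
#' never cross report `NA`.
#'
#' @param reference Data frame with `time_s`, `value` (top3-normalized).
#' @param others Named list of data frames like `reference`, or a tidy tibble
#'   with a `role` column.
#' @param level Crossing level in (0, 1); default half-maximum.
#' @return A tibble: `role`, `arrival_s`, `departure_s`, `arrival_offset_s`,
#'   `departure_offset_s`.
#' @export
adaptor_timing <- function(reference, others, level = 0.5) {
  stopifnot(level > 0, level < 1)
  if (is.data.frame(others) && "role" %in% names(others)) {
    others <- split(others[, c("time_s", "value")], others$role)
  }
  ref <- sustained_crossing(reference$time_s, reference$value, level)
  rows <- purrr::imap(others, function(tr, nm) {
    x <- sustained_crossing(tr$time_s, tr$value, level)
    tibble::tibble(
      role = nm,
      arrival_s = x[["arrival"]], departure_s = x[["departure"]],
      arrival_offset_s = x[["arrival"]] - ref[["arrival"]],
      departure_offset_s = x[["departure"]] - ref[["departure"]]
    )
  })
  dplyr::bind_rows(rows)
}

#' Assemble and analyze maturation events from traces
#'
#' Convenience pipeline: takes tidy event traces (one tracked cisterna per
#' event with early and late marker channels plus cargo), estimates each
#' event's transition midpoint from the top3-normalized markers, keeps events
#' whose window covers `required_window` around the midpoint, applies the
#' endpoint normalization (head anchor for cargo and the early marker, tail
#' anchor for the late marker), and returns the midpoint-aligned average.
#'
#' @param traces Tidy tibble: `event`, `role`, `time_s`, `value`.
#' @param early_role,late_role,cargo_role Channel-role names.
#' @param required_window Events must cover `[required_window[1],
#'   required_window[2]]` (s) around the estimated midpoint.
#' @param grid_interval Averaging grid spacing (s).
#' @return A list with `midpoints` (tibble: event, midpoint_s), `normalized`
#'   (tidy normalized traces) and `average` (a `vt_aligned` tibble).
#' @export
maturation_analysis <- function(traces, early_role = "early_golgi",
                                late_role = "late_golgi",
                                cargo_role = "cargo",
                                required_window = c(-40, 45),
                                grid_interval = 2) {
  stopifnot(all(c("event", "role", "time_s", "value") %in% names(traces)))
  evs <- unique(traces$event)
  mids <- list()
  keep <- list()
  for (e in evs) {
    tr <- traces |> dplyr::filter(.data$event == e)
    early <- tr |> dplyr::filter(.data$role == early_role) |>
      dplyr::arrange(.data$time_s)
    late <- tr |> dplyr::filter(.data$role == late_role) |>
      dplyr::arrange(.data$time_s)
    if (!nrow(early) || !nrow(late)) next
    m <- tryCatch(
      transition_midpoint(normalize_top3(early), normalize_top3(late)),
      error = function(err) NA_real_
    )
    if (is.na(m)) next
    span <- range(tr$time_s)
    if (span[1] > m + required_window[1] || span[2] < m + required_window[2]) next
    mids[[length(mids) + 1L]] <- tibble::tibble(event = e, midpoint_s = m)
    norm <- tr |>
      dplyr::group_by(.data$role) |>
      dplyr::arrange(.data$time_s, .by_group = TRUE) |>
      dplyr::group_modify(function(df, key) {
        anchor <- if (key$role == late_role) "tail" else "head"
        df$value <- normalize_endpoint6(df$value, anchor)
        df
      }) |>
      dplyr::ungroup()
    keep[[length(keep) + 1L]] <- norm
  }
  if (!length(mids)) stop("no usable maturation events found", call. = FALSE)
  midpoints <- dplyr::bind_rows(mids)
  normalized <- dplyr::bind_rows(keep)
  avg <- align_and_average(normalized, midpoints, grid_interval = grid_interval)
  list(midpoints = midpoints, normalized = normalized, average = avg)
}
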