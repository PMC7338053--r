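#' Per-cell vacuolar accumulation records
#'
#' Assembles one delivery record per cell from vacuolar cargo traces: the
#' trace itself, its final value (mean of the last three frames, robust to
#' single-frame noise), and whether the cell is scorable for first
#' appearance. Cells whose trace is shorter than `min_frames` are excluded
#' (and reported in the `excluded` attribute); cells whose final value does
#' not exceed `noise_floor_k` times the background noise floor are kept but
#' flagged unscorable.
#'
#' @param traces Tidy tibble with `structure` (or `cell`), `time_s`, `value`:
#'   cargo fluorescence inside the vacuole mask, one trace per cell.
#' @param min_frames Minimum trace length in frames.
#' @param noise_floor Background noise floor (a.u.); cells with
#'   `final_value < noise_floor_k * noise_floor` are unscorable.
#' @param noise_floor_k Multiplier on the noise floor.
#' @return A tibble of class `"vt_delivery"`: `cell`, `n_frames`,
#'   `final_value`, `scorable`.
#' @export
vacuole_accumulation <- function(traces, min_frames = 10, noise_floor = 0,
                                 noise_floor_k = 3) {
  if (!"structure" %in% names(traces) && "cell" %in% names(traces)) {
    traces$structure <- traces$cell
  }
  stopifnot(all(c("structure", "time_s", "value") %in% names(traces)))
  rec <- traces |>
    dplyr::group_by(cell = .data$structure) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      final_value = mean(utils::tail(.data$value, 3)),
      .groups = "drop"
    )
  excluded <- rec$cell[rec$n_frames < min_frames]
  if (length(excluded)) {
    message("excluding ", length(excluded), " cell(s) with traces shorter than ",
            min_frames, " frames")
  }
  rec <- rec |> dplyr::filter(.data$n_frames >= min_frames) |>
    dplyr::mutate(scorable = .data$final_value > noise_floor_k * noise_floor &
                    .data$final_value > 0)
  attr(rec, "excluded") <- excluded
  class(rec) <- c("vt_delivery", class(rec))
  rec
}

#' First appearance of cargo in the vacuole
#'
#' Appearance is scored as the first sampled time point at which the vacuolar
#' cargo fluorescence reaches at least `frac` (default 5%) of its final
#' value.
#'
#' @param trace Data frame with `time_s` and `value` for one cell, ordered or
#'   orderable by time.
#' @param final_value The cell's final value; by default the mean of the last
#'   three frames.
#' @param frac Threshold fraction of the final value.
#' @return Appearance time in seconds (a sampled frame time), or `NA` if the
#'   threshold is never reached.
#' @export
#' @examples
#' tr <- tibble::tibble(time_s = 0:5 * 60, value = c(0, 0, 4, 6, 50, 100))
#' first_appearance(tr, final_value = 100)  # 180 s: first frame >= 5
first_appearance <- function(trace, final_value = NULL, frac = 0.05) {
  stopifnot(all(c("time_s", "value") %in% names(trace)), frac >= 0)
  o <- order(trace$time_s)
  tt <- trace$time_s[o]
  v <- trace$value[o]
  if (is.null(final_value)) final_value <- mean(utils::tail(v, 3))
  if (final_value <= 0) stop("final value must be positive to score appearance",
                             call. = FALSE)
  hit <- which(v >= frac * final_value)
  if (!length(hit)) return(NA_real_)
  tt[hit[1]]
}

#' Population delivery statistics
#'
#' Computes the population mean +/- SEM vacuolar accumulation curve across
#' cells, the histogram of first-appearance times in 5-minute bins, and the
#' fraction of scorable cells whose cargo first appears later than
#' `late_cutoff` (15 min by default).
#'
#' @param traces Tidy per-cell vacuole cargo traces (`structure`/`cell`,
#'   `time_s`, `value`).
#' @param frac Appearance threshold fraction, see [first_appearance()].
#' @param late_cutoff Late-appearance cutoff in seconds.
#' @param bin_width Histogram bin width in seconds.
#' @param noise_floor,noise_floor_k Passed to [vacuole_accumulation()].
#' @return A list with `records` (per-cell tibble including
#'   `appearance_time_s`), `curve` (tibble: `time_s`, `mean`, `sem`, `n`),
#'   `histogram` (tibble: `bin_start_s`, `bin_end_s`, `n`) and
#'   `late_fraction` (scalar).
#' @export
population_average <- function(traces, frac = 0.05, late_cutoff = 900,
                               bin_width = 300, noise_floor = 0,
                               noise_floor_k = 3) {
  if (!"structure" %in% names(traces) && "cell" %in% names(traces)) {
    traces$structure <- traces$cell
  }
  rec <- vacuole_accumulation(traces, noise_floor = noise_floor,
                              noise_floor_k = noise_floor_k)
  if (nrow(rec) < 2) stop("need at least two cells", call. = FALSE)
  app <- vapply(rec$cell, function(id) {
    if (!rec$scorable[rec$cell == id]) return(NA_real_)
    tr <- traces |> dplyr::filter(.data$structure == id)
    first_appearance(tr, final_value = rec$final_value[rec$cell == id],
                     frac = frac)
  }, numeric(1))
  rec$appearance_time_s <- app
  curve <- traces |>
    dplyr::filter(.data$structure %in% rec$cell) |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() >= 2) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(), .groups = "drop"
    )
  scored <- app[!is.na(app)]
  hist_tbl <- if (length(scored)) {
    brks <- seq(0, max(scored) + bin_width, by = bin_width)
    cnt <- table(cut(scored, brks, right = TRUE, include.lowest = TRUE))
    tibble::tibble(
      bin_start_s = brks[-length(brks)], bin_end_s = brks[-1],
      n = as.integer(cnt)
    )
  } else {
    tibble::tibble(bin_start_s = numeric(), bin_end_s = numeric(), n = integer())
  }
  late_fraction <- if (length(scored)) mean(scored > late_cutoff) else NA_real_
  list(records = rec, curve = curve, histogram = hist_tbl,
       late_fraction = late_fraction)
}
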