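#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a midpoint-aligned maturation average
#'
#' @param x A `vt_aligned`.
#' @param ... Unused.
#' @return A tibble with one row per (role, rel_time_s): `role`,
#'   `rel_time_s`, `mean`, `sem`, `n`.
#' @exportS3Method generics::tidy
tidy.vt_aligned <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("role", "rel_time_s", "mean", "sem", "n")])
}

#' One-row summary of a maturation average
#'
#' @param x A `vt_aligned`.
#' @param ... Unused.
#' @return A tibble: `n_events`, `n_roles`, `rel_time_min_s`,
#'   `rel_time_max_s`.
#' @exportS3Method generics::glance
glance.vt_aligned <- function(x, ...) {
  tibble::tibble(
    n_events = attr(x, "n_events"),
    n_roles = length(unique(x$role)),
    rel_time_min_s = min(x$rel_time_s),
    rel_time_max_s = max(x$rel_time_s)
  )
}

#' Tidy a burst table
#'
#' @param x A `vt_burst_table`.
#' @param ... Unused.
#' @return The interval table as a plain tibble.
#' @exportS3Method generics::tidy
tidy.vt_burst_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a burst table
#'
#' @param x A `vt_burst_table`.
#' @param ... Passed to [summarize_bursts()].
#' @return The [summarize_bursts()] row.
#' @exportS3Method generics::glance
glance.vt_burst_table <- function(x, ...) {
  summarize_bursts(x, ...)
}

#' Tidy per-cell delivery records
#'
#' @param x A `vt_delivery`.
#' @param ... Unused.
#' @return The per-cell record table as a plain tibble.
#' @exportS3Method generics::tidy
tidy.vt_delivery <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
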