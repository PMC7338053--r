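sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a movie to multi-page 16-bit TIFF with a JSON sidecar
#'
#' Intensities are stored as 16-bit unsigned integers in OME page order
#' (T, then C, then Z; axes TCZYX). Channel roles, frame times, voxel
#' geometry and the array shape go to a structured-text JSON sidecar next to
#' the TIFF (`<path>.json`), along with the simulator ground truth when one
#' is supplied. Integer-valued intensities in \[0, 65535\] round-trip
#' bit-exactly.
#'
#' @param movie A `vt_movie`.
#' @param path Output TIFF path.
#' @param truth Optional ground-truth list (e.g. `timeline$truth`) to embed in
#'   the sidecar.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, truth = NULL) {
  stopifnot(inherits(movie, "vt_movie"))
  d <- dim(movie$data)
  vals <- round(movie$data)
  if (any(vals < 0) || any(vals > 65535)) {
    stop("intensities must lie in [0, 65535] for 16-bit storage", call. = FALSE)
  }
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 1L
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      for (z in seq_len(d[3])) {
        pages[[i]] <- vals[t, c, z, , ] / 65535
        i <- i + 1L
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    axes = "TCZYX",
    shape = as.integer(d),
    roles = as.list(stats::setNames(movie$roles, seq_along(movie$roles))),
    times_s = movie$times,
    voxel = list(xy_nm = unname(movie$voxel[["xy_nm"]]),
                 z_um = unname(movie$voxel[["z_um"]]))
  )
  if (!is.null(truth)) meta$ground_truth <- truth_to_json(truth)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

truth_to_json <- function(truth) {
  out <- truth
  for (nm in names(out)) {
    if (is.data.frame(out[[nm]])) out[[nm]] <- as.data.frame(out[[nm]])
  }
  out
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it. A sidecar
#'   without a channel-role map is a hard error.
#' @return A `vt_movie`; any embedded ground truth is attached as attribute
#'   `"ground_truth"`.
#' @export
read_movie <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing metadata sidecar: ", sc, call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$roles) || !length(meta$roles)) {
    stop("movie metadata lacks the channel-role map", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$shape)
  if (length(pages) != d[1] * d[2] * d[3]) {
    stop("page count does not match declared shape", call. = FALSE)
  }
  data <- array(0, dim = d)
  i <- 1L
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      for (z in seq_len(d[3])) {
        data[t, c, z, , ] <- pages[[i]]
        i <- i + 1L
      }
    }
  }
  roles <- unlist(meta$roles, use.names = FALSE)
  mv <- movie(data, roles, meta$times_s,
              c(xy_nm = meta$voxel$xy_nm, z_um = meta$voxel$z_um))
  if (!is.null(meta$ground_truth)) attr(mv, "ground_truth") <- meta$ground_truth
  mv
}
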