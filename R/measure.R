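frame_volume <- function(movie, role, frame) {
  ci <- channel_index(movie, role)
  vol <- movie$data[frame, ci, , , ]
  dim(vol) <- dim(movie$data)[3:5]
  vol
}

#' Measure fluorescence of one channel inside a structure mask
#'
#' Sums the measured channel's voxels inside the mask and subtracts
#' `voxel count x background`, where the background estimate is the median of
#' the voxels outside all masks of that frame (pass them via `all_masks`).
#' The result is floored at 0. The background policy is scale-equivariant, so
#' measurements scale linearly with image intensity.
#'
#' @param movie A `vt_movie`.
#' @param role Channel role to measure.
#' @param mask A `vt_mask` from [segment_structures()].
#' @param all_masks All masks of the frame (defaults to just `mask`),
#'   excluded from the background region.
#' @param background `"median_outside"` (default) or `"none"`.
#' @return Background-subtracted integrated intensity (a.u., >= 0).
#' @export
measure_in_mask <- function(movie, role, mask, all_masks = list(mask),
                            background = c("median_outside", "none")) {
  stopifnot(inherits(movie, "vt_movie"), inherits(mask, "vt_mask"))
  background <- match.arg(background)
  if (!sum(mask$voxels)) stop("mask is empty", call. = FALSE)
  vol <- frame_volume(movie, role, mask$frame)
  total <- sum(vol[mask$voxels])
  bg <- 0
  if (background == "median_outside") {
    outside <- !Reduce(`|`, lapply(all_masks, function(m) m$voxels))
    bg <- if (any(outside)) median(vol[outside]) else 0
  }
  out <- max(0, total - sum(mask$voxels) * bg)
  if (!is.null(mask$overlap_n) && mask$overlap_n > 0 &&
      any(mask$density_region)) {
    dens <- median(vol[mask$density_region])
    out <- max(0, out - mask$overlap_n * max(0, dens - bg))
  }
  if (!is.null(mask$rescale)) out <- out * mask$rescale
  out
}

#' Extract per-structure fluorescence traces from a movie
#'
#' Segments the mask-defining channel in every frame, links the masks into
#' tracks, and measures each requested channel inside each tracked mask:
#' the published measurement rule of selecting a marker signal in a 3-D
#' volume and measuring another channel's fluorescence within that volume.
#' A frame where a tracked structure is missing ends that trace's span.
#'
#' @param movie A `vt_movie`.
#' @param mask_role Channel role used to define the masks.
#' @param measure_roles Channel roles to measure inside the masks.
#' @param policy,k,min_voxels,smooth_sigma,dilate Passed to
#'   [segment_structures()].
#' @param max_disp_um,min_frames Passed to [link_structures()].
#' @param background Background policy, see [measure_in_mask()].
#' @param exclude_roles Optional roles whose segmented volumes are subtracted
#'   from every mask before measuring, to keep the fluorescence of adjacent
#'   marker-defined structures (e.g. a PVE compartment sitting on the vacuole
#'   surface) out of each other's measurement volumes.
#' @param exclude_erode Erosion passes applied to the exclusion volume before
#'   subtraction, so only the excluded structures' cores are removed.
#' @param exclude_dilate Dilation passes applied to the excluded structures'
#'   masks before subtraction (use this to remove a punctum's full PSF
#'   support from a surrounding mask); ignored when `exclude_erode > 0`.
#' @param rescale_excluded For volume-filling masks (the vacuole lumen):
#'   after exclusion, scale the measurement by `full voxels / kept voxels`,
#'   i.e. treat the measured channel as a uniform luminal density and
#'   integrate it over the full mask volume. Only meaningful when the
#'   measured signal fills the mask.
#' @param exclude_subtract Instead of removing the overlap voxels from each
#'   mask, keep them and subtract the excluded structures' estimated signal
#'   density (median over their non-overlapping voxels) times the overlap
#'   volume. Use this for a punctum attached to a volume-filling structure:
#'   the punctum keeps its full PSF support while the neighbour's luminal
#'   contribution is compensated.
#' @return A tidy tibble: `structure` (track id as
#'   `"<mask_role>_<track>"`), `class` (= `mask_role`), `role`, `frame`,
#'   `time_s`, `value`. Empty when no structures are found.
#' @export
extract_traces <- function(movie, mask_role, measure_roles,
                           policy = "otsu", k = 3, min_voxels = 10,
                           smooth_sigma = c(0.7, 1, 1), dilate = 0,
                           max_disp_um = 0.5, min_frames = 3,
                           background = "median_outside",
                           exclude_roles = NULL, exclude_erode = 0,
                           exclude_dilate = 0, rescale_excluded = FALSE,
                           exclude_subtract = FALSE) {
  stopifnot(inherits(movie, "vt_movie"))
  n_t <- dim(movie$data)[1]
  masks_per_frame <- lapply(seq_len(n_t), function(f) {
    masks <- segment_structures(movie, mask_role, f, policy = policy, k = k,
                                min_voxels = min_voxels,
                                smooth_sigma = smooth_sigma, dilate = dilate)
    if (length(masks) && length(exclude_roles)) {
      excl <- NULL
      for (er in exclude_roles) {
        ms <- segment_structures(movie, er, f, policy = policy, k = k,
                                 min_voxels = min_voxels,
                                 smooth_sigma = smooth_sigma,
                                 dilate = exclude_dilate)
        if (length(ms)) {
          u <- Reduce(`|`, lapply(ms, function(m) m$voxels))
          excl <- if (is.null(excl)) u else excl | u
        }
      }
      if (!is.null(excl)) {
        if (exclude_erode > 0) excl <- binary_morph3d(excl, exclude_erode, "erode")
        if (exclude_subtract) {
          role_union <- Reduce(`|`, lapply(masks, function(m) m$voxels))
          masks <- lapply(masks, function(m) {
            m$overlap_n <- sum(m$voxels & excl)
            m$density_region <- excl & !role_union
            m
          })
        } else {
          masks <- lapply(masks, function(m) {
            n_full <- sum(m$voxels)
            m$voxels <- m$voxels & !excl
            m$n_voxels <- sum(m$voxels)
            if (rescale_excluded && m$n_voxels > 0) {
              m$rescale <- n_full / m$n_voxels
            }
            m
          })
          masks <- masks[vapply(masks, function(m) m$n_voxels > 0, logical(1))]
        }
      }
    }
    masks
  })
  links <- link_structures(masks_per_frame, max_disp_um = max_disp_um,
                           min_frames = min_frames)
  if (!nrow(links)) {
    return(tibble::tibble(structure = character(), class = character(),
                          role = character(), frame = integer(),
                          time_s = numeric(), value = numeric()))
  }
  rows <- list()
  for (r in seq_len(nrow(links))) {
    f <- links$frame[r]
    m <- masks_per_frame[[f]][[links$label[r]]]
    for (role in measure_roles) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        structure = sprintf("%s_%02d", mask_role, links$track[r]),
        class = mask_role, role = role, frame = f,
        time_s = movie$times[f],
        value = measure_in_mask(movie, role, m,
                                all_masks = masks_per_frame[[f]],
                                background = background)
      )
    }
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$structure, .data$role,
                                           .data$frame)
}

#' Fraction of compartments containing detectable cargo
#'
#' A compartment contains detectable cargo at a frame when its in-mask mean
#' cargo intensity exceeds the background mean by more than `detect_k`
#' background standard deviations (an automated stand-in for manual
#' presence/absence scoring; the threshold is a declared choice, not a
#' published criterion). Returns detected/total per marker class per frame;
#' frames with no compartments of a class are reported as missing (`NA`),
#' not 0.
#'
#' @param movie A `vt_movie`.
#' @param class_roles Marker roles whose masks define the compartment classes.
#' @param cargo_role Channel measured inside the masks.
#' @param detect_k Detection threshold in background SDs.
#' @param frames Frames to score (default all).
#' @param ... Passed to [segment_structures()].
#' @return A tibble: `class`, `frame`, `time_s`, `n_total`, `n_detected`,
#'   `fraction`.
#' @export
fraction_compartments_with_cargo <- function(movie, class_roles,
                                             cargo_role = "cargo",
                                             detect_k = 3, frames = NULL,
                                             ...) {
  stopifnot(inherits(movie, "vt_movie"))
  if (is.null(frames)) frames <- seq_len(dim(movie$data)[1])
  rows <- list()
  for (cls in class_roles) {
    for (f in frames) {
      masks <- segment_structures(movie, cls, f, ...)
      cargo <- frame_volume(movie, cargo_role, f)
      if (!length(masks)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          class = cls, frame = f, time_s = movie$times[f],
          n_total = 0L, n_detected = NA_integer_, fraction = NA_real_
        )
        next
      }
      outside <- !Reduce(`|`, lapply(masks, function(m) m$voxels))
      bg_mean <- mean(cargo[outside])
      bg_sd <- sd(cargo[outside])
      thr <- bg_mean + detect_k * max(bg_sd, 0)
      det <- vapply(masks, function(m) mean(cargo[m$voxels]) > thr, logical(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        class = cls, frame = f, time_s = movie$times[f],
        n_total = length(masks), n_detected = sum(det),
        fraction = mean(det)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Distribution of whole-cell cargo across compartment classes
#'
#' Computes, at one frame, the percentage of the whole-cell cargo
#' fluorescence lying inside each marker class's union mask. Voxels claimed
#' by several classes are resolved by the order of `class_roles` (first
#' listed wins). Percentages plus the unassigned remainder sum to 100
#' exactly.
#'
#' @param movie A `vt_movie`.
#' @param class_roles Marker roles, in priority order.
#' @param frame Frame index.
#' @param cargo_role Channel whose fluorescence is apportioned.
#' @param ... Passed to [segment_structures()].
#' @return A tibble: `class` (the roles plus `"unassigned"`), `percent`.
#' @export
cargo_distribution_by_class <- function(movie, class_roles, frame,
                                        cargo_role = "cargo", ...) {
  stopifnot(inherits(movie, "vt_movie"))
  cargo <- frame_volume(movie, cargo_role, frame)
  total <- sum(cargo)
  if (total <= 0) stop("whole-cell cargo total is zero", call. = FALSE)
  claimed <- array(FALSE, dim = dim(cargo))
  pct <- numeric(length(class_roles))
  for (i in seq_along(class_roles)) {
    masks <- segment_structures(movie, class_roles[i], frame, ...)
    u <- if (length(masks)) Reduce(`|`, lapply(masks, function(m) m$voxels))
      else array(FALSE, dim = dim(cargo))
    u <- u & !claimed
    pct[i] <- 100 * sum(cargo[u]) / total
    claimed <- claimed | u
  }
  una <- 100 - sum(pct)
  tibble::tibble(class = c(class_roles, "unassigned"),
                 percent = c(pct, una))
}
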