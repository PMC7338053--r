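# Separable 3-D Gaussian smoothing (sigma in voxels per axis, zero-padded).
gauss_smooth3d <- function(arr, sigma = c(0.7, 1, 1)) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  d <- dim(arr)
  smooth_axis <- function(a, axis, s) {
    if (s <= 0) return(a)
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k <- k / sum(k)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
    }
    ap <- array(out, dim = dp)
    aperm(ap, order(perm))
  }
  arr <- smooth_axis(arr, 1L, sigma[1])
  arr <- smooth_axis(arr, 2L, sigma[2])
  smooth_axis(arr, 3L, sigma[3])
}

# Label a logical 3-D array into 26-connected components via the foreground
# voxel adjacency graph (igraph does the component search).
label3d_26 <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, dim = d)
  if (!length(fg)) return(lab)
  idx_of <- integer(length(mask))
  idx_of[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # half the offsets suffice (undirected edges)
  keep <- apply(offsets, 1, function(o) {
    o[1] > 0 || (o[1] == 0 && o[2] > 0) || (o[1] == 0 && o[2] == 0 && o[3] > 0)
  })
  offsets <- offsets[keep, , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    nb <- cbind(co[, 1] + o[1], co[, 2] + o[2], co[, 3] + o[3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    hit <- mask[lin]
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <- cbind(which(ok)[hit], idx_of[lin[hit]])
  }
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(fg)
  }
  # relabel deterministically by first (smallest linear index) voxel
  first_vox <- tapply(fg, memb, min)
  ord <- rank(first_vox)
  lab[fg] <- as.integer(ord[match(memb, as.integer(names(first_vox)))])
  lab
}

# Binary 3-D dilation / erosion with a 26-neighbour structuring element,
# iterated. Implemented as shift-OR / shift-AND over the offset cube.
binary_morph3d <- function(mask, iter, op = c("dilate", "erode")) {
  op <- match.arg(op)
  if (iter <= 0) return(mask)
  d <- dim(mask)
  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  for (it in seq_len(iter)) {
    acc <- if (op == "dilate") array(FALSE, d) else array(TRUE, d)
    for (r in seq_len(nrow(offsets))) {
      o <- offsets[r, ]
      zs <- pmin(pmax(seq_len(d[1]) + o[1], 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + o[2], 1L), d[2])
      xs <- pmin(pmax(seq_len(d[3]) + o[3], 1L), d[3])
      shifted <- mask[zs, ys, xs]
      acc <- if (op == "dilate") acc | shifted else acc & shifted
    }
    mask <- acc
  }
  mask
}

channel_index <- function(movie, role) {
  ci <- match(role, movie$roles)
  if (is.na(ci)) stop("channel role `", role, "` not present in movie",
                      call. = FALSE)
  ci
}

#' Segment marker-labeled structures in one frame
#'
#' Thresholds a Gaussian-smoothed marker channel and returns the 3-D
#' 26-connected components above a voxel-count minimum as structure masks.
#' For the vacuole membrane role the shell components are closed and filled
#' slice-wise so the mask includes the lumen (the measured cargo is luminal).
#'
#' @param movie A `vt_movie`.
#' @param role Channel role that defines the masks.
#' @param frame Frame index.
#' @param policy Threshold policy: `"otsu"` (default) or `"mean_k_sigma"`.
#' @param k Multiplier for the `mean_k_sigma` policy.
#' @param min_voxels Minimum component size in voxels.
#' @param smooth_sigma Gaussian smoothing sigmas in voxels (Z, Y, X).
#' @param dilate Number of 26-neighbour dilation passes applied to each
#'   component, to include the PSF tails of punctate structures in the
#'   measurement volume.
#' @param fill_lumen Close and fill masks slice-wise; defaults to `TRUE` for
#'   `role == "vacuole"`.
#' @return A list of masks, each a list with `frame`, `label`, `class`
#'   (the defining role), `voxels` (logical Z x Y x X), `n_voxels`,
#'   `centroid_um` (named x/y/z). An empty list when nothing is found.
#' @export
segment_structures <- function(movie, role, frame,
                               policy = c("otsu", "mean_k_sigma"), k = 3,
                               min_voxels = 10, smooth_sigma = c(0.7, 1, 1),
                               dilate = 0,
                               fill_lumen = identical(role, "vacuole")) {
  stopifnot(inherits(movie, "vt_movie"))
  policy <- match.arg(policy)
  ci <- channel_index(movie, role)
  vol <- movie$data[frame, ci, , , ]
  dim(vol) <- dim(movie$data)[3:5]
  sm <- gauss_smooth3d(vol, smooth_sigma)
  mx <- max(sm)
  if (mx <= 0) return(list())
  thr <- switch(policy,
    # flatten: otsu() thresholds 2-D frames, and the volume is one sample
    otsu = EBImage::otsu(EBImage::Image(matrix(sm / mx, ncol = 1L)),
                         range = c(0, 1), levels = 256) * mx,
    mean_k_sigma = mean(sm) + k * sd(sm)
  )
  fgmask <- sm > thr
  if (!any(fgmask)) return(list())
  if (fill_lumen) {
    brush <- EBImage::makeBrush(5, "disc")
    for (z in seq_len(dim(fgmask)[1])) {
      sl <- fgmask[z, , ]
      if (!any(sl)) next
      sl <- EBImage::closing(EBImage::Image(sl * 1), brush)
      sl <- EBImage::fillHull(sl)
      fgmask[z, , ] <- EBImage::imageData(sl) > 0.5
    }
  }
  lab <- label3d_26(fgmask)
  ids <- sort(unique(lab[lab > 0]))
  out <- list()
  for (li in ids) {
    vox <- lab == li
    if (sum(vox) < min_voxels) next
    if (dilate > 0) vox <- binary_morph3d(vox, dilate, "dilate")
    nv <- sum(vox)
    co <- arrayInd(which(vox), dim(vox))
    centroid <- c(
      x = (mean(co[, 3]) - 0.5) * movie$voxel[["xy_nm"]] / 1000,
      y = (mean(co[, 2]) - 0.5) * movie$voxel[["xy_nm"]] / 1000,
      z = (mean(co[, 1]) - 0.5) * movie$voxel[["z_um"]]
    )
    out[[length(out) + 1L]] <- structure(
      list(frame = frame, label = length(out) + 1L, class = role,
           voxels = vox, n_voxels = nv, centroid_um = centroid),
      class = "vt_mask"
    )
  }
  out
}

#' Link per-frame structure masks into tracks
#'
#' Greedy nearest-centroid matching between consecutive frames with a maximum
#' physical displacement per frame interval. Unmatched masks start new
#' tracks; tracks shorter than `min_frames` are discarded. Ties are broken by
#' smaller centroid distance, then larger voxel overlap, then lower label, so
#' linking is deterministic and invariant to input label order.
#'
#' @param masks_per_frame List over frames; each element the mask list for
#'   that frame from [segment_structures()] (one role).
#' @param max_disp_um Maximum centroid displacement between consecutive
#'   frames, in um.
#' @param min_frames Minimum track duration in frames.
#' @return A tibble: `track`, `frame`, `label` (index into that frame's mask
#'   list).
#' @export
link_structures <- function(masks_per_frame, max_disp_um = 0.5,
                            min_frames = 1) {
  n_frames <- length(masks_per_frame)
  tracks <- list() # each: list(frames=int vec, labels=int vec, last_centroid)
  for (f in seq_len(n_frames)) {
    masks <- masks_per_frame[[f]]
    if (!length(masks)) next
    open_idx <- which(vapply(tracks, function(tr)
      tr$frames[length(tr$frames)] == f - 1L, logical(1)))
    cents <- t(vapply(masks, function(m) m$centroid_um, numeric(3)))
    assigned_mask <- rep(FALSE, length(masks))
    if (length(open_idx)) {
      prev_c <- t(vapply(tracks[open_idx], function(tr) tr$last_centroid,
                         numeric(3)))
      cand <- expand.grid(ti = seq_along(open_idx), mi = seq_along(masks))
      cand$dist <- sqrt(rowSums((prev_c[cand$ti, , drop = FALSE] -
                                   cents[cand$mi, , drop = FALSE])^2))
      cand <- cand[cand$dist <= max_disp_um, , drop = FALSE]
      if (nrow(cand)) {
        cand$overlap <- mapply(function(ti, mi) {
          pm <- tracks[[open_idx[ti]]]$last_voxels
          if (is.null(pm)) 0L else sum(pm & masks[[mi]]$voxels)
        }, cand$ti, cand$mi)
        cand <- cand[order(cand$dist, -cand$overlap, cand$mi), , drop = FALSE]
        used_t <- rep(FALSE, length(open_idx))
        for (r in seq_len(nrow(cand))) {
          ti <- cand$ti[r]; mi <- cand$mi[r]
          if (used_t[ti] || assigned_mask[mi]) next
          tr <- tracks[[open_idx[ti]]]
          tr$frames <- c(tr$frames, f)
          tr$labels <- c(tr$labels, mi)
          tr$last_centroid <- cents[mi, ]
          tr$last_voxels <- masks[[mi]]$voxels
          tracks[[open_idx[ti]]] <- tr
          used_t[ti] <- TRUE
          assigned_mask[mi] <- TRUE
        }
      }
    }
    for (mi in which(!assigned_mask)) {
      tracks[[length(tracks) + 1L]] <- list(
        frames = f, labels = mi, last_centroid = cents[mi, ],
        last_voxels = masks[[mi]]$voxels
      )
    }
  }
  keep <- vapply(tracks, function(tr) length(tr$frames) >= min_frames,
                 logical(1))
  tracks <- tracks[keep]
  if (!length(tracks)) {
    return(tibble::tibble(track = integer(), frame = integer(),
                          label = integer()))
  }
  dplyr::bind_rows(lapply(seq_along(tracks), function(i) {
    tibble::tibble(track = i, frame = tracks[[i]]$frames,
                   label = tracks[[i]]$labels)
  }))
}
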