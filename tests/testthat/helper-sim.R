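# Shared builders for small, fast simulation fixtures.

small_optics <- function(n_frames = 20, frame_interval = 5, ...) {
  optics_config(n_z = 12, n_y = 48, n_x = 48, n_frames = n_frames,
                frame_interval = frame_interval, ...)
}

small_kinetics <- function(...) {
  kinetic_config(vacuole_radius = 0.8, ...)
}

# Hand-built mask for linking tests: a small cube at a voxel position.
toy_mask <- function(frame, label, zc, yc, xc, dims = c(12, 48, 48),
                     half = 1L, voxel = c(xy_nm = 70, z_um = 0.28)) {
  vox <- array(FALSE, dims)
  vox[max(1, zc - half):min(dims[1], zc + half),
      max(1, yc - half):min(dims[2], yc + half),
      max(1, xc - half):min(dims[3], xc + half)] <- TRUE
  co <- arrayInd(which(vox), dims)
  structure(list(
    frame = frame, label = label, class = "toy", voxels = vox,
    n_voxels = sum(vox),
    centroid_um = c(x = (mean(co[, 3]) - 0.5) * voxel[["xy_nm"]] / 1000,
                    y = (mean(co[, 2]) - 0.5) * voxel[["xy_nm"]] / 1000,
                    z = (mean(co[, 1]) - 0.5) * voxel[["z_um"]])
  ), class = "vt_mask")
}

# Independent brute-force re-derivation of burst scoring, written as a plain
# loop over intervals (the oracle detect_bursts() is checked against).
brute_force_bursts <- function(r, times, threshold = 0.15, floor_frac = 0.02) {
  out <- data.frame(index = integer(), fraction = numeric(),
                    is_burst = logical())
  for (i in 2:length(r)) {
    drop <- r[i - 1] - r[i]
    if (drop < 0) drop <- 0
    frac <- if (r[i - 1] > 0) drop / r[i - 1] else 0
    burst <- (frac > threshold) && (r[i - 1] > floor_frac * r[1])
    out <- rbind(out, data.frame(index = i - 1L, fraction = frac,
                                 is_burst = burst))
  }
  out
}

# Brute-force 26-connected flood fill from a seed voxel over a thresholded
# volume; independent oracle for the component labeling.
flood_fill26 <- function(fg, seed_idx) {
  d <- dim(fg)
  visited <- array(FALSE, d)
  stack <- list(seed_idx)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (visited[p[1], p[2], p[3]]) next
    visited[p[1], p[2], p[3]] <- TRUE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      q <- p + c(dz, dy, dx)
      if (any(q < 1) || any(q > d)) next
      if (fg[q[1], q[2], q[3]] && !visited[q[1], q[2], q[3]]) {
        stack[[length(stack) + 1L]] <- q
      }
    }
  }
  visited
}

cargo_sum_by_frame <- function(timeline) {
  sig <- timeline$signals
  sig <- sig[sig$role == "cargo", ]
  tapply(sig$value, sig$frame, sum)
}
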