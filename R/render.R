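role_channel_order <- c("cargo", "early_golgi", "late_golgi", "pve",
                        "vacuole", "adaptor_gga2", "adaptor_apl2")

# Normalized (sum 1) separable anisotropic 3-D Gaussian kernel over the full
# field, for a sub-resolution punctum at (zc, yc, xc) voxel coordinates.
point_kernel <- function(nz, ny, nx, zc, yc, xc, sz, sxy) {
  reach <- 4
  if (zc - reach * sz < 0.5 || zc + reach * sz > nz + 0.5 ||
      yc - reach * sxy < 0.5 || yc + reach * sxy > ny + 0.5 ||
      xc - reach * sxy < 0.5 || xc + reach * sxy > nx + 0.5) {
    stop("structure Gaussian support exceeds the imaging field", call. = FALSE)
  }
  gz <- exp(-0.5 * ((seq_len(nz) - zc) / sz)^2)
  gy <- exp(-0.5 * ((seq_len(ny) - yc) / sxy)^2)
  gx <- exp(-0.5 * ((seq_len(nx) - xc) / sxy)^2)
  k <- gz %o% gy %o% gx
  k / sum(k)
}

# Radial kernels for the vacuole: a spherical membrane shell (Gaussian cross
# section of SD shell_sigma um) and a filled lumen with a soft edge.
vacuole_kernels <- function(optics, center_um, radius_um, shell_sigma = 0.1) {
  nz <- optics$n_z; ny <- optics$n_y; nx <- optics$n_x
  zc <- (seq_len(nz) - 0.5) * optics$voxel_z
  yc <- (seq_len(ny) - 0.5) * optics$voxel_xy / 1000
  xc <- (seq_len(nx) - 0.5) * optics$voxel_xy / 1000
  lims <- c(nz * optics$voxel_z, ny * optics$voxel_xy / 1000,
            nx * optics$voxel_xy / 1000)
  if (any(center_um[c("z", "y", "x")] - radius_um - 4 * shell_sigma < 0) ||
      any(center_um[c("z", "y", "x")] + radius_um + 4 * shell_sigma > lims)) {
    stop("vacuole support exceeds the imaging field", call. = FALSE)
  }
  dz2 <- (zc - center_um[["z"]])^2
  dy2 <- (yc - center_um[["y"]])^2
  dx2 <- (xc - center_um[["x"]])^2
  d <- sqrt(outer(outer(dz2, dy2, "+"), dx2, "+"))
  shell <- exp(-0.5 * ((d - radius_um) / shell_sigma)^2)
  lumen <- 1 / (1 + exp((d - radius_um) / 0.05))
  list(shell = shell / sum(shell), lumen = lumen / sum(lumen))
}

#' Render a compartment timeline into a 4D multi-channel movie
#'
#' Forward imaging model: each punctate compartment (cisterna, PVE) is
#' rendered as an anisotropic 3-D Gaussian at the PSF width whose integrated
#' intensity equals `photon_gain * true_signal`; the vacuole membrane marker
#' is rendered as a spherical shell and luminal vacuole cargo as a filled
#' sphere, likewise integrating to `photon_gain * true_signal`. With
#' `noise = TRUE`, voxel values are Poisson-distributed about the noiseless
#' image plus Gaussian read noise, clipped at 0; with `noise = FALSE`
#' rendering is linear in the true signal.
#'
#' @param timeline A `vt_timeline` from [simulate_timeline()].
#' @param optics Optics to render with; defaults to the timeline's.
#' @param noise Apply the photon + read-noise model?
#' @param seed Seed for the noise draw; defaults to `optics$seed`.
#' @return A list of class `"vt_movie"`: `data` (numeric array
#'   T x C x Z x Y x X), `roles` (character vector, channel index to role),
#'   `times` (s), `voxel` (named: `xy_nm`, `z_um`).
#' @export
render_movie <- function(timeline, optics = timeline$optics, noise = FALSE,
                         seed = NULL) {
  stopifnot(inherits(timeline, "vt_timeline"), inherits(optics, "vt_optics"))
  n_t <- optics$n_frames
  if (length(timeline$times) != n_t) {
    stop("timeline frame count does not match optics$n_frames", call. = FALSE)
  }
  roles <- intersect(role_channel_order, unique(timeline$signals$role))
  n_c <- length(roles)
  nz <- optics$n_z; ny <- optics$n_y; nx <- optics$n_x
  sxy <- optics$psf_sigma_xy / optics$voxel_xy
  sz <- optics$psf_sigma_z / optics$voxel_z

  comp <- timeline$compartments
  kernels <- vector("list", nrow(comp))
  names(kernels) <- comp$id
  for (i in seq_len(nrow(comp))) {
    ctr <- c(x = comp$x_um[i], y = comp$y_um[i], z = comp$z_um[i])
    if (comp$class[i] == "vacuole") {
      kernels[[i]] <- vacuole_kernels(optics, ctr, comp$radius_um[i])
    } else {
      kernels[[i]] <- point_kernel(
        nz, ny, nx,
        zc = ctr[["z"]] / optics$voxel_z + 0.5,
        yc = ctr[["y"]] / (optics$voxel_xy / 1000) + 0.5,
        xc = ctr[["x"]] / (optics$voxel_xy / 1000) + 0.5,
        sz = sz, sxy = sxy
      )
    }
  }

  sig <- timeline$signals
  data <- array(0, dim = c(n_t, n_c, nz, ny, nx))
  vals <- array(0, dim = c(nz, ny, nx))
  for (ci in seq_along(roles)) {
    sub <- sig[sig$role == roles[ci], ]
    by_id <- split(sub, sub$id)
    for (t in seq_len(n_t)) {
      vals[] <- optics$background
      for (id in names(by_id)) {
        v <- by_id[[id]]$value[match(t, by_id[[id]]$frame)]
        if (is.na(v) || v <= 0) next
        k <- kernels[[id]]
        if (comp$class[match(id, comp$id)] == "vacuole") {
          k <- if (roles[ci] == "vacuole") k$shell else k$lumen
        }
        vals <- vals + optics$photon_gain * v * k
      }
      data[t, ci, , , ] <- vals
    }
  }
  if (noise) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed %||% optics$seed))
    n_vox <- length(data)
    data[] <- pmax(0, rpois(n_vox, data) +
                     round(rnorm(n_vox, 0, optics$read_noise_sd)))
  }
  structure(list(data = data, roles = roles, times = timeline$times,
                 voxel = c(xy_nm = optics$voxel_xy, z_um = optics$voxel_z)),
            class = "vt_movie")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vt_movie <- function(x, ...) {
  d <- dim(x$data)
  cat("<vt_movie> T=", d[1], " C=", d[2], " Z=", d[3], " Y=", d[4],
      " X=", d[5], "; channels: ", paste(x$roles, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Construct a movie object from an array
#'
#' @param data Numeric array T x C x Z x Y x X, non-negative intensities.
#' @param roles Character vector mapping channel index to role name.
#' @param times Frame times in seconds, strictly increasing.
#' @param voxel Named numeric: `xy_nm`, `z_um`.
#' @return A `vt_movie`.
#' @export
movie <- function(data, roles, times, voxel) {
  stopifnot(length(dim(data)) == 5, length(roles) == dim(data)[2],
            length(times) == dim(data)[1])
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing",
                                  call. = FALSE)
  if (anyDuplicated(roles)) stop("channel roles must be unique", call. = FALSE)
  structure(list(data = data, roles = as.character(roles),
                 times = as.numeric(times),
                 voxel = c(xy_nm = unname(voxel[["xy_nm"]]),
                           z_um = unname(voxel[["z_um"]]))),
            class = "vt_movie")
}
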