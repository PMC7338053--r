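#' Acquisition geometry and detector settings
#'
#' Describes a confocal 4D acquisition: voxel pitch, Z sampling, frame timing,
#' the Gaussian approximation to the point-spread function, and a linear
#' photon-counting detector model. Defaults correspond to live-cell yeast
#' imaging on a point-scanning confocal with a 1.4 NA / 63x objective:
#' 60-80 nm XY pixels, 0.25-0.30 um Z steps and 20-30 optical sections.
#'
#' @param voxel_xy XY pixel size in nm.
#' @param voxel_z Z step in um.
#' @param n_z Number of optical sections.
#' @param frame_interval Time between Z-stacks in seconds.
#' @param n_frames Number of Z-stacks (time points).
#' @param n_y,n_x Lateral field size in voxels.
#' @param psf_sigma_xy Lateral Gaussian PSF sigma in nm.
#' @param psf_sigma_z Axial Gaussian PSF sigma in um.
#' @param photon_gain Expected detected photons per unit of true signal.
#' @param read_noise_sd Gaussian read-noise standard deviation in counts.
#' @param background Flat background offset in counts per voxel.
#' @param seed Integer seed used by stochastic rendering when none is given
#'   explicitly.
#'
#' @return A list with class `"vt_optics"`.
#' @export
#' @examples
#' op <- optics_config(n_z = 12, n_y = 48, n_x = 48, n_frames = 10)
#' op$frame_interval
optics_config <- function(voxel_xy = 70,
                          voxel_z = 0.28,
                          n_z = 24,
                          frame_interval = 2,
                          n_frames = 46,
                          n_y = 64,
                          n_x = 64,
                          psf_sigma_xy = 120,
                          psf_sigma_z = 0.35,
                          photon_gain = 10,
                          read_noise_sd = 2,
                          background = 0,
                          seed = 1L) {
  cfg <- list(
    voxel_xy = voxel_xy, voxel_z = voxel_z, n_z = as.integer(n_z),
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    n_y = as.integer(n_y), n_x = as.integer(n_x),
    psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
    photon_gain = photon_gain, read_noise_sd = read_noise_sd,
    background = background, seed = as.integer(seed)
  )
  for (f in c("voxel_xy", "voxel_z", "n_z", "frame_interval", "n_frames",
              "n_y", "n_x", "psf_sigma_xy", "psf_sigma_z", "photon_gain")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      stop("optics_config: `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (read_noise_sd < 0 || background < 0) {
    stop("optics_config: noise and background must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "vt_optics")
}

#' Compartment kinetics for the traffic simulator
#'
#' Parameterizes the compartment-level kinetic model: cisternal maturation
#' (early marker decays as the late marker rises, crossing at the transition
#' midpoint), maturation-coupled cargo exit, clathrin-adaptor timing offsets,
#' continuous PVE-to-vacuole cargo release, and stochastic kiss-and-run
#' transfer bursts.
#'
#' @details
#' `mode` selects the sorting genotype being emulated:
#' \describe{
#'   \item{`wildtype`}{cargo held in the cisterna until the early-to-late
#'     transition midpoint, then exits exponentially at `cargo_exit_rate`.}
#'   \item{`vps10_null`}{no sorting receptor: cargo rises transiently by
#'     `cargo_overshoot` around the transition (intra-Golgi recycling) and
#'     persists like a secretory cargo; no cargo reaches the PVE/vacuole arm.}
#'   \item{`apl4_null`}{AP-1 inactive: cargo exit is unchanged from wildtype.}
#'   \item{`gga_null`}{GGAs inactive: cargo exit is abolished
#'     (`cargo_exit_rate` is forced to 0) and marker transitions are shallower.}
#' }
#'
#' Kiss-and-run bursts occur on each delivery-active PVE compartment as a
#' Poisson process of intensity `burst_rate`; each burst transfers a fraction
#' of the remaining cargo drawn from a normal distribution with mean
#' `burst_fraction_mean` and SD `burst_fraction_sd`, truncated to
#' `burst_fraction_range`. A PVE compartment is delivery-inactive (quiescent)
#' with probability `quiescent_prob`.
#'
#' @param mode One of `"wildtype"`, `"vps10_null"`, `"apl4_null"`, `"gga_null"`.
#' @param cisterna_lifetime Cisterna lifetime in seconds.
#' @param transition_midpoint_frac Position of the early-to-late transition
#'   within the lifetime, in (0, 1).
#' @param marker_tau Time constant (s) of the logistic marker transitions.
#' @param cargo_exit_rate Exponential cargo exit rate (1/s) after the midpoint.
#' @param cargo_overshoot Peak transient rise factor of cisternal cargo in
#'   `vps10_null` mode (>= 1).
#' @param pve_leak_rate Continuous PVE-to-vacuole release rate (1/s).
#' @param burst_rate Poisson intensity of kiss-and-run bursts (1/s).
#' @param burst_fraction_mean,burst_fraction_sd Mean and SD of the fraction of
#'   remaining cargo transferred per burst.
#' @param burst_fraction_range Truncation support of the per-burst fraction.
#' @param quiescent_prob Probability that a PVE compartment is
#'   delivery-inactive for the whole movie.
#' @param adaptor_offset_arrival,adaptor_offset_departure AP-1 (Apl2) arrival
#'   and departure lags (s) relative to Sec7/Gga2.
#' @param load_time_meanlog,load_time_sdlog Lognormal parameters (log-seconds)
#'   of the per-cell PVE loading time used by delivery simulations.
#' @param vps8_ar_rho,vps8_ar_sd AR(1) coefficient and innovation SD of the
#'   multiplicative fluctuation of the PVE (Vps8) marker signal.
#' @param vacuole_radius Vacuole radius in um.
#' @param pve_radius,cisterna_radius Compartment radii in um.
#'
#' @return A list with class `"vt_kinetics"`.
#' @export
#' @examples
#' kin <- kinetic_config(mode = "gga_null")
#' kin$cargo_exit_rate  # forced to 0
kinetic_config <- function(mode = c("wildtype", "vps10_null", "apl4_null", "gga_null"),
                           cisterna_lifetime = 180,
                           transition_midpoint_frac = 0.5,
                           marker_tau = 8,
                           cargo_exit_rate = 0.02,
                           cargo_overshoot = 1.3,
                           pve_leak_rate = 5e-4,
                           burst_rate = 1 / 300,
                           burst_fraction_mean = 0.375,
                           burst_fraction_sd = 0.15,
                           burst_fraction_range = c(0.16, 0.95),
                           quiescent_prob = 0.3,
                           adaptor_offset_arrival = 30,
                           adaptor_offset_departure = 12,
                           load_time_meanlog = log(720),
                           load_time_sdlog = 0.55,
                           vps8_ar_rho = 0.8,
                           vps8_ar_sd = 0.1,
                           vacuole_radius = 1.2,
                           pve_radius = 0.3,
                           cisterna_radius = 0.25) {
  mode <- match.arg(mode)
  if (cisterna_lifetime <= 0) {
    stop("kinetic_config: `cisterna_lifetime` must be positive", call. = FALSE)
  }
  if (transition_midpoint_frac <= 0 || transition_midpoint_frac >= 1) {
    stop("kinetic_config: `transition_midpoint_frac` must lie in (0, 1)",
         call. = FALSE)
  }
  rates <- c(cargo_exit_rate = cargo_exit_rate, pve_leak_rate = pve_leak_rate,
             burst_rate = burst_rate)
  bad <- names(rates)[!is.finite(rates) | rates < 0]
  if (length(bad)) {
    stop("kinetic_config: rate(s) must be finite and >= 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (burst_fraction_mean - 2 * burst_fraction_sd <= 0 ||
      burst_fraction_mean + 2 * burst_fraction_sd >= 1) {
    stop("kinetic_config: burst_fraction_mean +/- 2*sd must lie within (0, 1)",
         call. = FALSE)
  }
  if (length(burst_fraction_range) != 2L ||
      burst_fraction_range[1] <= 0 || burst_fraction_range[2] >= 1 ||
      diff(burst_fraction_range) <= 0) {
    stop("kinetic_config: `burst_fraction_range` support must lie within (0, 1)",
         call. = FALSE)
  }
  if (quiescent_prob < 0 || quiescent_prob > 1) {
    stop("kinetic_config: `quiescent_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (cargo_overshoot < 1) {
    stop("kinetic_config: `cargo_overshoot` must be >= 1", call. = FALSE)
  }
  if (mode == "gga_null") {
    # GGAs package vacuolar cargo at the Golgi; without them the cargo cannot
    # exit, and marker transitions are shallower.
    cargo_exit_rate <- 0
    marker_tau <- 2 * marker_tau
  }
  structure(list(
    mode = mode,
    cisterna_lifetime = cisterna_lifetime,
    transition_midpoint_frac = transition_midpoint_frac,
    marker_tau = marker_tau,
    cargo_exit_rate = cargo_exit_rate,
    cargo_overshoot = cargo_overshoot,
    pve_leak_rate = pve_leak_rate,
    burst_rate = burst_rate,
    burst_fraction_mean = burst_fraction_mean,
    burst_fraction_sd = burst_fraction_sd,
    burst_fraction_range = burst_fraction_range,
    quiescent_prob = quiescent_prob,
    adaptor_offset_arrival = adaptor_offset_arrival,
    adaptor_offset_departure = adaptor_offset_departure,
    load_time_meanlog = load_time_meanlog,
    load_time_sdlog = load_time_sdlog,
    vps8_ar_rho = vps8_ar_rho,
    vps8_ar_sd = vps8_ar_sd,
    vacuole_radius = vacuole_radius,
    pve_radius = pve_radius,
    cisterna_radius = cisterna_radius
  ), class = "vt_kinetics")
}

#' @export
print.vt_optics <- function(x, ...) {
  cat("<vt_optics> ", x$n_frames, " frames @ ", x$frame_interval, " s; ",
      x$n_z, "x", x$n_y, "x", x$n_x, " voxels (",
      x$voxel_xy, " nm XY, ", x$voxel_z, " um Z)\n", sep = "")
  invisible(x)
}

#' @export
print.vt_kinetics <- function(x, ...) {
  cat("<vt_kinetics> mode=", x$mode,
      "; lifetime=", x$cisterna_lifetime, " s",
      "; cargo_exit_rate=", x$cargo_exit_rate, " /s",
      "; burst_rate=", signif(x$burst_rate, 3), " /s\n", sep = "")
  invisible(x)
}
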