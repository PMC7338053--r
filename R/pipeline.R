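#' @importFrom utils write.csv packageVersion head tail
NULL

default_run_config <- function() {
  list(
    experiment = "bursts",
    seed = 1L,
    optics = list(),
    kinetics = list(),
    analysis = list(interval = 10, threshold = 0.15, floor_frac = 0.02,
                    detect_k = 3, frac = 0.05),
    simulate = list(n_movies = 6, n_pve = 1, n_cells = 40, n_events = 21,
                    render = FALSE, noise_sd = 0.02),
    plots = TRUE
  )
}

validate_run_config <- function(config) {
  def <- default_run_config()
  for (nm in names(def)) {
    if (is.null(config[[nm]])) config[[nm]] <- def[[nm]]
    else if (is.list(def[[nm]])) {
      for (sub in names(def[[nm]])) {
        if (is.null(config[[nm]][[sub]])) config[[nm]][[sub]] <- def[[nm]][[sub]]
      }
    }
  }
  if (!config$experiment %in% c("maturation", "delivery", "bursts", "all")) {
    stop("config field `experiment` must be one of maturation/delivery/bursts/all",
         call. = FALSE)
  }
  if (is.null(config$seed)) stop("config field `seed` is mandatory", call. = FALSE)
  an <- config$analysis
  checks <- c(threshold = an$threshold, floor_frac = an$floor_frac,
              frac = an$frac)
  bad <- names(checks)[checks < 0 | checks > 1]
  if (length(bad)) {
    stop("config field(s) out of range [0, 1]: ",
         paste("analysis$", bad, sep = "", collapse = ", "), call. = FALSE)
  }
  if (an$interval <= 0) stop("config field `analysis$interval` must be positive",
                             call. = FALSE)
  config
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level blocks mirror [run_pipeline()]'s
#'   config: `experiment`, `seed`, `optics`, `kinetics`, `analysis`,
#'   `simulate`.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run a simulate-quantify-analyze pipeline
#'
#' Orchestrates a full run from one configuration: simulates the requested
#' experiment family (maturation movies, whole-cell delivery, or PVE burst
#' movies), runs the corresponding analysis, and writes tidy CSV outputs,
#' plots and a machine-readable JSON summary to `out_dir`. Deterministic
#' given `(config, seed)`; the summary and log record a hash of the config.
#'
#' @param config A config list or path to a YAML file (see
#'   [read_run_config()]). Recognized fields: `experiment` (one of
#'   `"maturation"`, `"delivery"`, `"bursts"`, `"all"`), `seed`, `optics` and
#'   `kinetics` blocks (arguments to [optics_config()] / [kinetic_config()]),
#'   `analysis` (interval, threshold, floor_frac, detect_k, frac) and
#'   `simulate` (n_movies, n_pve, n_cells, n_events, noise_sd).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  } else {
    config <- validate_run_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kin <- do.call(kinetic_config, config$kinetics)
  seed <- as.integer(config$seed)
  an <- config$analysis
  simcfg <- config$simulate
  cfg_hash <- rlang::hash(config)
  log_lines <- c(
    paste0("vactraffic ", as.character(packageVersion("vactraffic"))),
    paste0("config_hash ", cfg_hash),
    paste0("seed ", seed),
    paste0("experiment ", config$experiment)
  )
  summary <- list(config_hash = cfg_hash, seed = seed,
                  experiment = config$experiment)
  stages <- if (config$experiment == "all") {
    c("maturation", "delivery", "bursts")
  } else config$experiment

  run_stage <- function(stage) {
    if (stage == "maturation") {
      ev <- simulate_maturation_events(simcfg$n_events, kin, seed = seed,
                                       noise_sd = simcfg$noise_sd)
      res <- maturation_analysis(ev$traces)
      write.csv(res$midpoints, file.path(out_dir, "maturation_midpoints.csv"),
                row.names = FALSE)
      write.csv(tidy(res$average), file.path(out_dir, "maturation_average.csv"),
                row.names = FALSE)
      if (isTRUE(config$plots)) {
        ggplot2::ggsave(file.path(out_dir, "maturation_average.png"),
                        autoplot(res$average), width = 6, height = 4, dpi = 150)
      }
      cargo45 <- res$average |>
        dplyr::filter(.data$role == "cargo", .data$rel_time_s >= 45) |>
        dplyr::slice_head(n = 1)
      list(n_events = nrow(res$midpoints),
           cargo_mean_at_45s = if (nrow(cargo45)) cargo45$mean else NA_real_)
    } else if (stage == "delivery") {
      cp <- simulate_cell_population(simcfg$n_cells, kin, seed = seed,
                                     noise_sd = simcfg$noise_sd)
      pop <- population_average(cp$traces, frac = an$frac,
                                noise_floor = simcfg$noise_sd * 100)
      write.csv(tidy(pop$records), file.path(out_dir, "delivery_cells.csv"),
                row.names = FALSE)
      write.csv(pop$curve, file.path(out_dir, "delivery_population.csv"),
                row.names = FALSE)
      if (isTRUE(config$plots)) {
        ggplot2::ggsave(file.path(out_dir, "delivery_curves.png"),
                        plot_delivery_curves(cp$traces, pop$curve),
                        width = 6, height = 4, dpi = 150)
      }
      list(n_cells = nrow(pop$records),
           late_fraction = pop$late_fraction)
    } else if (stage == "bursts") {
      bm <- simulate_burst_movies(simcfg$n_movies, kin, seed = seed,
                                  n_pve = simcfg$n_pve,
                                  noise_sd = simcfg$noise_sd)
      ba <- burst_analysis(bm$traces, interval = an$interval,
                           threshold = an$threshold,
                           floor_frac = an$floor_frac)
      write.csv(ba$per_structure, file.path(out_dir, "burst_summaries.csv"),
                row.names = FALSE)
      tables <- dplyr::bind_rows(lapply(names(ba$tables), function(id) {
        dplyr::mutate(tidy(ba$tables[[id]]), structure = id, .before = 1)
      }))
      write.csv(tables, file.path(out_dir, "burst_tables.csv"),
                row.names = FALSE)
      if (isTRUE(config$plots) && length(ba$tables)) {
        ggplot2::ggsave(file.path(out_dir, "burst_timeline.png"),
                        plot_burst_timeline(ba$tables[[1]]),
                        width = 6, height = 4, dpi = 150)
      }
      as.list(ba$pooled)
    }
  }

  for (stage in stages) {
    res <- tryCatch(run_stage(stage), error = function(e) {
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    summary[[stage]] <- res
    log_lines <- c(log_lines, paste0("stage ", stage, " ok"))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(summary)
}

#' Generate the small fixture movies used by the test-suite
#'
#' Builds tiny rendered movies (at most 16 x 48 x 48 voxels and a few tens of
#' frames) with their ground truth: a burst movie with scheduled transfer
#' events and a maturation movie with a recorded transition midpoint. The set
#' regenerates identically from its seed.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, the movies are written there as
#'   TIFF + JSON sidecars.
#' @return A list with `burst` and `maturation`, each holding `timeline` and
#'   `movie`.
#' @export
make_fixtures <- function(seed = 1L, dir = NULL) {
  op_small <- optics_config(n_z = 12, n_y = 48, n_x = 48, frame_interval = 5,
                            n_frames = 25, photon_gain = 50, seed = seed)
  kin_b <- kinetic_config(quiescent_prob = 0, burst_rate = 1 / 60,
                          pve_leak_rate = 1e-3, vacuole_radius = 0.8)
  tl_b <- simulate_timeline(kin_b, op_small, n_cisternae = 0, n_pve = 1,
                            seed = seed)
  mv_b <- render_movie(tl_b, noise = FALSE)

  op_mat <- optics_config(n_z = 12, n_y = 48, n_x = 48, frame_interval = 2,
                          n_frames = 46, photon_gain = 50, seed = seed)
  kin_m <- kinetic_config(vacuole_radius = 0.8)
  tl_m <- simulate_timeline(kin_m, op_mat, n_cisternae = 1, n_pve = 1,
                            seed = seed + 1L)
  mv_m <- render_movie(tl_m, noise = FALSE)

  out <- list(burst = list(timeline = tl_b, movie = mv_b),
              maturation = list(timeline = tl_m, movie = mv_m))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_movie(mv_b, file.path(dir, "fixture_burst.tiff"), truth = tl_b$truth)
    write_movie(mv_m, file.path(dir, "fixture_maturation.tiff"),
                truth = tl_m$truth)
  }
  out
}
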