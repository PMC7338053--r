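test_that("a zero-signal timeline renders to an all-zero movie", {
  kin <- small_kinetics(burst_rate = 0, pve_leak_rate = 0, quiescent_prob = 1)
  tl <- simulate_timeline(kin, small_optics(n_frames = 3), n_cisternae = 0,
                          n_pve = 1, seed = 1, cargo_pve = 0, marker_amp = 0)
  mv <- render_movie(tl, noise = FALSE)
  expect_equal(max(abs(mv$data)), 0)
})

test_that("noiseless rendering integrates to gain times true signal", {
  kin <- small_kinetics(burst_rate = 0, pve_leak_rate = 0, quiescent_prob = 0)
  op <- small_optics(n_frames = 2)
  tl <- simulate_timeline(kin, op, n_cisternae = 0, n_pve = 1, seed = 2,
                          cargo_pve = 50, marker_amp = 0)
  mv <- render_movie(tl, noise = FALSE)
  ci <- match("cargo", mv$roles)
  integrated <- sum(mv$data[1, ci, , , ])
  expect_equal(integrated, op$photon_gain * 50, tolerance = 0.01)

  # linearity: doubling the true signal doubles the integrated intensity
  tl2 <- simulate_timeline(kin, op, n_cisternae = 0, n_pve = 1, seed = 2,
                           cargo_pve = 100, marker_amp = 0)
  mv2 <- render_movie(tl2, noise = FALSE)
  expect_equal(sum(mv2$data[1, ci, , , ]) / integrated, 2, tolerance = 0.01)
})

test_that("Poisson noise preserves the mean integrated intensity", {
  kin <- small_kinetics(burst_rate = 0, pve_leak_rate = 0, quiescent_prob = 0)
  op <- small_optics(n_frames = 1, read_noise_sd = 0)
  tl <- simulate_timeline(kin, op, n_cisternae = 0, n_pve = 1, seed = 2,
                          cargo_pve = 50, marker_amp = 0)
  ci <- NULL
  sums <- vapply(1:200, function(s) {
    mv <- render_movie(tl, noise = TRUE, seed = s)
    if (is.null(ci)) ci <<- match("cargo", mv$roles)
    sum(mv$data[1, ci, , , ])
  }, numeric(1))
  expected <- op$photon_gain * 50
  se <- sd(sums) / sqrt(length(sums))
  expect_lt(abs(mean(sums) - expected), 3 * se)
})

test_that("structures whose PSF support leaves the field raise a geometry error", {
  kin <- kinetic_config(vacuole_radius = 2.0) # too large for a 48-voxel field
  op <- small_optics(n_frames = 2)
  tl <- simulate_timeline(kin, op, n_cisternae = 0, n_pve = 1, seed = 1)
  expect_error(render_movie(tl, noise = FALSE), "exceeds the imaging field")
})

test_that("identical config and seed render bit-identical noisy movies", {
  kin <- small_kinetics(quiescent_prob = 0)
  op <- small_optics(n_frames = 3)
  tl <- simulate_timeline(kin, op, n_cisternae = 0, n_pve = 1, seed = 5)
  a <- render_movie(tl, noise = TRUE, seed = 11)
  b <- render_movie(tl, noise = TRUE, seed = 11)
  expect_identical(a$data, b$data)
})

test_that("movie files round-trip bit-exactly with their metadata", {
  kin <- small_kinetics(quiescent_prob = 0)
  op <- small_optics(n_frames = 3)
  tl <- simulate_timeline(kin, op, n_cisternae = 0, n_pve = 1, seed = 5)
  mv <- render_movie(tl, noise = TRUE, seed = 1)
  path <- file.path(withr::local_tempdir(), "toy.tiff")
  write_movie(mv, path, truth = tl$truth)
  back <- read_movie(path)
  expect_identical(back$data, mv$data)
  expect_identical(back$roles, mv$roles)
  expect_equal(back$times, mv$times)
  expect_equal(back$voxel, mv$voxel)
  expect_false(is.null(attr(back, "ground_truth")))
  # axes declared: T=3 and C = number of channels
  meta <- jsonlite::read_json(sub("\\.tiff$", ".json", path),
                              simplifyVector = TRUE)
  expect_identical(meta$axes, "TCZYX")
  expect_identical(meta$shape[1:2], c(3L, length(mv$roles)))
})

test_that("reading a movie without a channel-role map is a hard error", {
  kin <- small_kinetics(quiescent_prob = 0)
  tl <- simulate_timeline(kin, small_optics(n_frames = 2), n_cisternae = 0,
                          n_pve = 1, seed = 5)
  mv <- render_movie(tl, noise = FALSE)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.tiff")
  write_movie(mv, path)
  # strip the role map from the sidecar
  meta <- jsonlite::read_json(sub("\\.tiff$", ".json", path),
                              simplifyVector = TRUE)
  meta$roles <- NULL
  jsonlite::write_json(meta, sub("\\.tiff$", ".json", path),
                       auto_unbox = TRUE)
  expect_error(read_movie(path), "channel-role map")
  # and a missing sidecar altogether
  file.remove(sub("\\.tiff$", ".json", path))
  expect_error(read_movie(path), "sidecar")
})
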