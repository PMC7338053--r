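make_spot_movie <- function(cargo = 50, marker = 100, gain = 10, seed = 3) {
  kin <- small_kinetics(quiescent_prob = 0, burst_rate = 0, pve_leak_rate = 0,
                        vps8_ar_sd = 0)
  op <- small_optics(n_frames = 2, photon_gain = gain)
  tl <- simulate_timeline(kin, op, n_cisternae = 0, n_pve = 1, seed = seed,
                          cargo_pve = cargo, marker_amp = marker)
  list(tl = tl, mv = render_movie(tl, noise = FALSE), op = op)
}

test_that("measurement inside a mask recovers the rendered intensity", {
  sp <- make_spot_movie(cargo = 50, gain = 10)
  masks <- segment_structures(sp$mv, "pve", 1, dilate = 2)
  expect_length(masks, 1)
  got <- measure_in_mask(sp$mv, "cargo", masks[[1]], all_masks = masks)
  expect_equal(got, 500, tolerance = 0.05)
  # empty mask is an error
  empty <- masks[[1]]
  empty$voxels[] <- FALSE
  expect_error(measure_in_mask(sp$mv, "cargo", empty), "empty")
})

test_that("a uniform image cancels exactly against its own median background", {
  sp <- make_spot_movie()
  mv <- sp$mv
  ci <- match("cargo", mv$roles)
  mv$data[1, ci, , , ] <- 7 # uniform value
  masks <- segment_structures(mv, "pve", 1)
  expect_equal(measure_in_mask(mv, "cargo", masks[[1]], all_masks = masks), 0)
})

test_that("traces scale linearly with image intensity", {
  sp <- make_spot_movie()
  tr1 <- extract_traces(sp$mv, "pve", "cargo", dilate = 2, min_frames = 2)
  mv3 <- sp$mv
  mv3$data <- mv3$data * 3
  tr3 <- extract_traces(mv3, "pve", "cargo", dilate = 2, min_frames = 2)
  expect_equal(tr3$value, 3 * tr1$value, tolerance = 1e-8)
})

test_that("noise-off traces track simulator truth within 5% RMS", {
  kin <- small_kinetics(quiescent_prob = 0, pve_leak_rate = 4e-3,
                        burst_rate = 1 / 120)
  op <- small_optics(n_frames = 30, frame_interval = 10)
  tl <- simulate_timeline(kin, op, n_cisternae = 0, n_pve = 1, seed = 11)
  tl <- apply_photobleach(tl, 1, 1)
  mv <- render_movie(tl, noise = FALSE)
  g <- op$photon_gain
  tru <- timeline_traces(tl)
  tp <- tru[tru$class == "pve" & tru$role == "cargo", ]
  tv <- tru[tru$class == "vacuole" & tru$role == "cargo", ]
  trp <- extract_traces(mv, "pve", "cargo", dilate = 2,
                        exclude_roles = "vacuole", exclude_subtract = TRUE)
  trv <- extract_traces(mv, "vacuole", "cargo", exclude_roles = "pve",
                        exclude_dilate = 4, rescale_excluded = TRUE)
  expect_equal(length(unique(c(trp$structure, trv$structure))), 2)
  rms_p <- sqrt(mean((trp$value / g - tp$value[trp$frame])^2)) / max(tp$value)
  rms_v <- sqrt(mean((trv$value / g - tv$value[trv$frame])^2)) / max(tv$value)
  expect_lt(rms_p, 0.05)
  expect_lt(rms_v, 0.05)
})

test_that("measuring the mask's own channel returns its marker signal", {
  sp <- make_spot_movie(marker = 80, gain = 10)
  tr <- extract_traces(sp$mv, "pve", "pve", dilate = 2, min_frames = 2)
  expect_equal(tr$value / sp$op$photon_gain, rep(80, 2), tolerance = 0.05)
})

test_that("cargo presence scoring hits the all-or-none endpoints", {
  sp <- make_spot_movie(cargo = 80)
  det <- fraction_compartments_with_cargo(sp$mv, "pve", frames = 1)
  expect_equal(det$fraction, 1)
  sp0 <- make_spot_movie(cargo = 0)
  det0 <- fraction_compartments_with_cargo(sp0$mv, "pve", frames = 1)
  expect_equal(det0$fraction, 0)
  # no compartments of the class -> missing, not zero
  empty <- make_spot_movie(marker = 0)
  dete <- fraction_compartments_with_cargo(empty$mv, "pve", frames = 1)
  expect_true(is.na(dete$fraction))
})

test_that("cargo percentages partition to exactly 100", {
  kin <- small_kinetics(quiescent_prob = 0, burst_rate = 0, pve_leak_rate = 0,
                        vps8_ar_sd = 0)
  op <- small_optics(n_frames = 2)
  tl <- simulate_timeline(kin, op, n_cisternae = 1, n_pve = 1, seed = 6,
                          cargo_cisterna = 30, cargo_pve = 70)
  mv <- render_movie(tl, noise = FALSE)
  dist <- cargo_distribution_by_class(mv, c("pve", "early_golgi"), 1,
                                      dilate = 3)
  expect_equal(sum(dist$percent), 100)
  expect_equal(dist$percent[dist$class == "pve"], 70, tolerance = 3)
  expect_equal(dist$percent[dist$class == "early_golgi"], 30, tolerance = 3)
  # all cargo inside one class
  tl2 <- simulate_timeline(kin, op, n_cisternae = 0, n_pve = 1, seed = 6,
                           cargo_pve = 100)
  tl2 <- apply_photobleach(tl2, 1, 1)
  mv2 <- render_movie(tl2, noise = FALSE)
  d2 <- cargo_distribution_by_class(mv2, "pve", 1, dilate = 4)
  expect_gt(d2$percent[d2$class == "pve"], 95)
  # zero cargo -> error
  tl0 <- simulate_timeline(kin, op, n_cisternae = 0, n_pve = 1, seed = 6,
                           cargo_pve = 0)
  tl0 <- apply_photobleach(tl0, 1, 1)
  mv0 <- render_movie(tl0, noise = FALSE)
  expect_error(cargo_distribution_by_class(mv0, "pve", 1), "zero")
})
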