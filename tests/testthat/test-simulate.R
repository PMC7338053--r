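test_that("without transfer channels, PVE and vacuole cargo stay constant", {
  kin <- small_kinetics(burst_rate = 0, pve_leak_rate = 0, quiescent_prob = 0)
  tl <- simulate_timeline(kin, small_optics(), n_cisternae = 0, n_pve = 2,
                          seed = 1)
  sig <- tl$signals[tl$signals$role == "cargo", ]
  for (id in unique(sig$id)) {
    v <- sig$value[sig$id == id]
    expect_equal(v, rep(v[1], length(v)))
  }
})

test_that("summed cargo is conserved frame by frame in vacuole-directed modes", {
  for (mode in c("wildtype", "apl4_null", "gga_null")) {
    kin <- small_kinetics(mode = mode, quiescent_prob = 0.5)
    tl <- simulate_timeline(kin, small_optics(n_frames = 30), n_cisternae = 2,
                            n_pve = 2, seed = 5)
    tot <- cargo_sum_by_frame(tl)
    expect_lt(max(abs(tot - tl$truth$conserved_total_cargo)) /
                tl$truth$conserved_total_cargo, 1e-9)
  }
})

test_that("gga_null cisternae retain cargo through late-marker departure", {
  kin <- small_kinetics(mode = "gga_null", cisterna_lifetime = 60)
  tl <- simulate_timeline(kin, small_optics(n_frames = 40, frame_interval = 4),
                          n_cisternae = 2, n_pve = 1, seed = 2)
  dep <- tl$truth$midpoints
  sig <- tl$signals
  for (i in seq_len(nrow(dep))) {
    cargo <- sig[sig$id == dep$id[i] & sig$role == "cargo", ]
    f_dep <- which.min(abs(tl$times - dep$departure_s[i]))
    expect_gte(cargo$value[cargo$frame == f_dep], 0.9 * cargo$value[1])
  }
})

test_that("burst counts follow the configured Poisson intensity", {
  # rate 1/300 /s over 10 min -> mean 2 events per PVE, checked against an
  # independent tally of the realized schedule over many replicates
  kin <- small_kinetics(burst_rate = 1 / 300, pve_leak_rate = 0,
                        quiescent_prob = 0)
  bm <- simulate_burst_movies(500, kin, seed = 99, n_pve = 1,
                              frame_interval = 10, duration = 600)
  counts <- table(factor(bm$truth$burst_schedule$movie, levels = 1:500))
  m <- mean(as.integer(counts))
  se <- sd(as.integer(counts)) / sqrt(500)
  expect_lt(abs(m - 2), 3 * se + 1e-12)
})

test_that("identical config and seed give identical timelines", {
  kin <- small_kinetics()
  a <- simulate_timeline(kin, small_optics(), n_cisternae = 1, n_pve = 2,
                         seed = 7)
  b <- simulate_timeline(kin, small_optics(), n_cisternae = 1, n_pve = 2,
                         seed = 7)
  expect_identical(a$signals, b$signals)
  expect_identical(a$truth$burst_schedule, b$truth$burst_schedule)
})

test_that("the PVE marker fluctuates but never reaches zero", {
  kin <- small_kinetics(vps8_ar_sd = 0.3, quiescent_prob = 0)
  tl <- simulate_timeline(kin, small_optics(n_frames = 60), n_cisternae = 0,
                          n_pve = 3, seed = 3)
  pve_marker <- tl$signals[tl$signals$role == "pve", ]
  expect_true(all(pve_marker$value > 0))
  expect_gt(sd(pve_marker$value), 0)
})

test_that("photobleach scales non-PVE cargo and spares later arrivals", {
  kin <- small_kinetics(burst_rate = 0, pve_leak_rate = 2e-3,
                        quiescent_prob = 0)
  tl <- simulate_timeline(kin, small_optics(n_frames = 30), n_cisternae = 0,
                          n_pve = 1, seed = 4)
  expect_identical(apply_photobleach(tl, 0, 5)$signals, tl$signals)

  blb <- apply_photobleach(tl, 1, 5)
  vac <- blb$signals[blb$signals$id == "vacuole" &
                       blb$signals$role == "cargo", ]
  expect_equal(vac$value[vac$frame == 5], 0)
  # PVE cargo and markers untouched (compare on a common ordering)
  ord <- function(sig) dplyr::arrange(sig[sig$class == "pve", ],
                                      id, role, frame)
  expect_identical(ord(blb$signals), ord(tl$signals))
  # post-bleach arrivals are unbleached: vacuole gains exactly what the PVE
  # loses after the bleach frame
  pve0 <- tl$signals[tl$signals$class == "pve" & tl$signals$role == "cargo", ]
  gained <- vac$value[vac$frame == 30] - vac$value[vac$frame == 5]
  lost <- pve0$value[pve0$frame == 5] - pve0$value[pve0$frame == 30]
  expect_equal(gained, lost, tolerance = 1e-9)
})

test_that("after a full bleach the vacuole holds exactly what the PVE lost", {
  # conservation bookkeeping: bleach everything outside the PVE at frame 2,
  # then every burst credits the vacuole with precisely the transferred amount
  kin <- small_kinetics(burst_rate = 1 / 50, pve_leak_rate = 0,
                        quiescent_prob = 0)
  tl <- simulate_timeline(kin, small_optics(n_frames = 30), n_cisternae = 0,
                          n_pve = 1, seed = 8, cargo_pve = 100)
  tl <- apply_photobleach(tl, 1, 2)
  sig <- tl$signals
  pve_id <- tl$compartments$id[tl$compartments$class == "pve"]
  pve <- sig[sig$id == pve_id & sig$role == "cargo", ]
  vac <- sig[sig$id == "vacuole" & sig$role == "cargo", ]
  sched <- tl$truth$burst_schedule
  expect_gt(nrow(sched), 0)
  for (f in 2:30) {
    expect_equal(vac$value[vac$frame == f],
                 pve$value[pve$frame == 2] - pve$value[pve$frame == f],
                 tolerance = 1e-9)
  }
  # a single burst of fraction f from remaining R moves R * f to the vacuole
  solo <- sched[!sched$frame %in% sched$frame[duplicated(sched$frame)], ]
  expect_gt(nrow(solo), 0)
  b1 <- solo[1, ]
  vac_inc <- vac$value[vac$frame == b1$frame] -
    vac$value[vac$frame == b1$frame - 1L]
  expect_equal(vac_inc, b1$transferred, tolerance = 1e-9)
  expect_equal(b1$transferred,
               pve$value[pve$frame == b1$frame - 1L] * b1$fraction,
               tolerance = 1e-9)
})

test_that("maturation-event generator matches its declared truth", {
  kin <- small_kinetics()
  ev <- simulate_maturation_events(4, kin, seed = 10)
  expect_setequal(unique(ev$traces$event), 1:4)
  # early marker falls to half its plateau at the true midpoint
  for (e in 1:4) {
    tr <- ev$traces[ev$traces$event == e & ev$traces$role == "early_golgi", ]
    m <- ev$truth$midpoint_s[e]
    at_m <- approx(tr$time_s, tr$value, xout = m)$y
    expect_equal(at_m / max(tr$value), 0.5, tolerance = 0.05)
  }
})

test_that("delivery generator: vps10_null cells accumulate nothing", {
  kin_wt <- small_kinetics(quiescent_prob = 0)
  kin_mut <- small_kinetics(mode = "vps10_null", quiescent_prob = 0)
  wt <- simulate_cell_population(10, kin_wt, seed = 6)
  mut <- simulate_cell_population(10, kin_mut, seed = 6)
  expect_gt(max(wt$traces$value), 0)
  expect_equal(max(mut$traces$value), 0)
})
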