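test_that("top-3 normalization matches hand arithmetic and is idempotent", {
  expect_equal(normalize_top3(c(1, 2, 3, 4, 5)),
               c(0.25, 0.5, 0.75, 1.0, 1.25))
  expect_equal(normalize_top3(c(7, 7, 7, 7)), rep(1, 4))
  x <- c(2, 9, 4, 8, 1, 7)
  expect_equal(normalize_top3(5.3 * x), normalize_top3(x)) # scale-invariant
  expect_equal(normalize_top3(normalize_top3(x)), normalize_top3(x))
  expect_error(normalize_top3(c(0, 0, 0)), "all-zero")
  expect_error(normalize_top3(c(1, 2)), "at least 3")
})

test_that("endpoint-6 normalization divides by the anchor-window mean", {
  expect_equal(normalize_endpoint6(c(rep(10, 6), 20, 30), "head"),
               c(rep(1, 6), 2, 3))
  expect_equal(normalize_endpoint6(c(8, 12, rep(4, 6)), "tail"),
               c(2, 3, rep(1, 6)))
  expect_equal(normalize_endpoint6(1:12, "head"), (1:12) / 3.5)
  expect_error(normalize_endpoint6(c(0, 0, 0, 0, 0, 0, 1), "head"), "positive")
  expect_error(normalize_endpoint6(1:5, "head"), "at least 6")
})

test_that("transition midpoint interpolates the early/late crossing", {
  t <- seq(0, 60, 2)
  early <- tibble::tibble(time_s = t, value = 1 - t / 60)
  late <- tibble::tibble(time_s = t, value = t / 60)
  expect_equal(transition_midpoint(early, late), 30)
  # shift equivariance
  expect_equal(
    transition_midpoint(dplyr::mutate(early, time_s = time_s + 13),
                        dplyr::mutate(late, time_s = time_s + 13)),
    43
  )
  # late always below early: not a maturation event
  low <- dplyr::mutate(late, value = value * 0 - 1)
  expect_error(transition_midpoint(early, low), "not a maturation event")
})

test_that("simulated midpoints are recovered within one frame (noise off)", {
  kin <- small_kinetics()
  ev <- simulate_maturation_events(12, kin, seed = 21)
  ma <- maturation_analysis(ev$traces)
  err <- abs(ma$midpoints$midpoint_s -
               ev$truth$midpoint_s[ma$midpoints$event])
  expect_true(all(err <= 2))
})

test_that("aligned averaging of identical events reproduces the event, SEM 0", {
  t <- seq(-40, 40, 2)
  one <- tibble::tibble(role = "cargo", time_s = t + 100,
                        value = exp(-pmax(0, t) * 0.02))
  events <- dplyr::bind_rows(lapply(1:5, function(e)
    dplyr::mutate(one, event = e)))
  mids <- tibble::tibble(event = 1:5, midpoint_s = 100)
  avg <- align_and_average(events, mids)
  expect_equal(avg$mean, one$value[match(avg$rel_time_s, t)])
  expect_equal(avg$sem, rep(0, nrow(avg)))
  expect_error(align_and_average(events[0, ], mids), "no events")
})

test_that("midpoint estimation error moves the mean crossing, not its shape", {
  # two events whose midpoints are deliberately mis-set by +/- 2 s
  t <- seq(-40, 40, 2)
  mk <- function(e, off) tibble::tibble(
    event = e, role = "cargo", time_s = t + 100,
    value = 1 / (1 + exp((t - off) / 4))
  )
  events <- dplyr::bind_rows(mk(1, -2), mk(2, 2))
  mids <- tibble::tibble(event = 1:2, midpoint_s = c(100, 100))
  avg <- align_and_average(events, mids)
  cross <- avg$rel_time_s[which.min(abs(avg$mean - 0.5))]
  expect_lte(abs(cross - 0), 2)
})

test_that("SEM shrinks as 1/sqrt(n) for replicated events", {
  t <- seq(-40, 40, 2)
  mk_noisy <- function(e) {
    set.seed(e)
    tibble::tibble(event = e, role = "cargo", time_s = t + 100,
                   value = 1 + rnorm(length(t), 0, 0.1))
  }
  mids <- function(n) tibble::tibble(event = 1:n, midpoint_s = 100)
  a5 <- align_and_average(dplyr::bind_rows(lapply(1:5, mk_noisy)), mids(5))
  a45 <- align_and_average(dplyr::bind_rows(lapply(1:45, mk_noisy)), mids(45))
  expect_equal(mean(a45$sem) / mean(a5$sem), sqrt(5 / 45), tolerance = 0.35)
})

test_that("wild-type average cargo declines past the midpoint; gga mode does not", {
  wt <- simulate_maturation_events(20, small_kinetics(), seed = 31,
                                   noise_sd = 0.02)
  ma_wt <- maturation_analysis(wt$traces)
  cargo_wt <- ma_wt$average[ma_wt$average$role == "cargo", ]
  at45 <- cargo_wt$mean[which.min(abs(cargo_wt$rel_time_s - 45))]
  expect_lte(at45, 0.6)

  gga <- simulate_maturation_events(20, small_kinetics(mode = "gga_null"),
                                    seed = 31, noise_sd = 0.02)
  ma_gga <- maturation_analysis(gga$traces)
  cargo_gga <- ma_gga$average[ma_gga$average$role == "cargo", ]
  expect_true(all(cargo_gga$mean >= 0.9))
})

test_that("adaptor timing recovers identical, shifted and offset traces", {
  t <- seq(0, 100, 2)
  ref <- tibble::tibble(time_s = t, value = 1 / (1 + exp(-(t - 30) / 4)) *
                          1 / (1 + exp((t - 80) / 4)))
  ref <- normalize_top3(ref)
  # identical trace: offsets (0, 0)
  same <- adaptor_timing(ref, list(self = ref))
  expect_equal(same$arrival_offset_s, 0, tolerance = 1e-6)
  expect_equal(same$departure_offset_s, 0, tolerance = 1e-6)
  # trace shifted by exactly one frame: offset = 2 s
  shifted <- dplyr::mutate(ref, time_s = time_s + 2)
  sh <- adaptor_timing(ref, list(late = shifted))
  expect_equal(sh$arrival_offset_s, 2, tolerance = 1e-6)
  # a trace never crossing the level reports missing offsets
  flat <- tibble::tibble(time_s = t, value = rep(0.1, length(t)))
  fl <- adaptor_timing(ref, list(flat = flat))
  expect_true(is.na(fl$arrival_offset_s))
})

test_that("simulated adaptor offsets are recovered within 4 s", {
  kin <- small_kinetics(adaptor_offset_arrival = 30,
                        adaptor_offset_departure = 12)
  ev <- simulate_maturation_events(6, kin, seed = 41, adaptors = TRUE,
                                   window = c(-60, 140), noise_sd = 0.02)
  for (e in 1:6) {
    tr <- ev$traces[ev$traces$event == e, ]
    ref <- normalize_top3(tr[tr$role == "late_golgi", c("time_s", "value")])
    apl <- normalize_top3(tr[tr$role == "adaptor_apl2", c("time_s", "value")])
    res <- adaptor_timing(ref, list(adaptor_apl2 = apl))
    expect_lt(abs(res$arrival_offset_s - 30), 4)
    expect_lt(abs(res$departure_offset_s - 12), 4)
  }
})
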