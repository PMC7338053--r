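test_that("remaining series resamples at interval boundaries", {
  tr <- tibble::tibble(time_s = seq(0, 600, 5),
                       value = seq(100, 40, length.out = 121))
  rs <- remaining_series(tr, 10)
  expect_equal(nrow(rs), 61) # 600/10 + 1
  expect_equal(rs$value, tr$value[seq(1, 121, 2)]) # every second frame
  cst <- tibble::tibble(time_s = seq(0, 100, 5), value = rep(3, 21))
  expect_equal(unique(remaining_series(cst, 10)$value), 3)
  coarse <- tibble::tibble(time_s = seq(0, 600, 20), value = 1:31)
  expect_error(remaining_series(coarse, 10), "coarser")
})

test_that("burst calling matches the published interval rule", {
  # 10% drops never qualify
  r10 <- 100 * 0.9^(0:10)
  expect_equal(sum(detect_bursts(r10)$is_burst), 0)
  # the worked example: one burst of fraction 0.60 at interval 2
  tab <- detect_bursts(c(100, 100, 40, 40), interval = 10)
  expect_equal(sum(tab$is_burst), 1)
  expect_equal(tab$fraction[2], 0.6)
  expect_equal(tab$index[tab$is_burst], 2)
  # increases score fraction 0
  tab_up <- detect_bursts(c(50, 60, 70))
  expect_equal(tab_up$fraction, c(0, 0))
  expect_error(detect_bursts(c(0, 10)), "positive")
})

test_that("burst detection equals the brute-force oracle on random series", {
  set.seed(7)
  for (i in 1:300) {
    kind <- i %% 4
    n <- sample(5:40, 1)
    r <- switch(as.character(kind),
      "0" = cumsum(runif(n, 0, 5)),                    # all-increase
      "1" = rep(runif(1, 1, 100), n),                  # all-flat
      "2" = c(runif(1, 50, 100), runif(n - 1, 0, 1)),  # near-empty floor
      "3" = abs(100 * cumprod(c(1, runif(n - 1, 0.5, 1.1))))
    )
    r[1] <- max(r[1], 1e-6)
    tab <- detect_bursts(r, interval = 10)
    oracle <- brute_force_bursts(r, seq_along(r))
    expect_equal(tab$fraction, oracle$fraction)
    expect_identical(tab$is_burst, oracle$is_burst)
  }
})

test_that("burst calls and fractions are scale-invariant", {
  set.seed(8)
  r <- 100 * cumprod(c(1, runif(30, 0.6, 1.05)))
  a <- detect_bursts(r)
  b <- detect_bursts(137.5 * r)
  expect_identical(a$is_burst, b$is_burst)
  expect_equal(a$fraction, b$fraction)
})

test_that("burst summaries report frequency and transfer fractions", {
  # 2 bursts in 10 min -> 0.2 per min
  r <- rep(100, 61)
  r[11:61] <- 70
  r[31:61] <- 40
  tab <- detect_bursts(r, interval = 10)
  s <- summarize_bursts(tab)
  expect_equal(s$n_bursts, 2)
  expect_equal(s$frequency_per_min, 0.2)
  expect_equal(s$mean_fraction_per_burst, mean(c(0.3, 3 / 7)))
  expect_equal(s$total_fraction_in_bursts, 1)
  # zero bursts: frequency 0, fractions missing
  s0 <- summarize_bursts(detect_bursts(rep(10, 61), interval = 10))
  expect_equal(s0$n_bursts, 0)
  expect_equal(s0$frequency_per_min, 0)
  expect_true(is.na(s0$mean_fraction_per_burst))
})

test_that("conservation cross-check never flags bleach-free noiseless movies", {
  kin <- small_kinetics(quiescent_prob = 0, burst_rate = 1 / 100)
  bm <- simulate_burst_movies(4, kin, seed = 5)
  for (mvi in 1:4) {
    pve <- bm$traces[bm$traces$movie == mvi & bm$traces$class == "pve", ]
    vac <- bm$traces[bm$traces$movie == mvi & bm$traces$class == "vacuole", ]
    rem <- remaining_series(pve, 10)
    tab <- detect_bursts(rem)
    s <- summarize_bursts(tab, vac_trace = vac)
    if (s$n_bursts > 0) expect_equal(s$n_unmatched, 0)
  }
})

test_that("active-PVE selection drops quiescent compartments", {
  kin <- small_kinetics(quiescent_prob = 0, burst_rate = 1 / 100)
  act <- simulate_burst_movies(2, kin, seed = 9)$traces
  kin_q <- small_kinetics(quiescent_prob = 1)
  qui <- simulate_burst_movies(2, kin_q, seed = 9)$traces
  qui$structure <- sub("^m", "q", qui$structure)
  pool <- dplyr::bind_rows(act, qui)
  ids <- active_pve(pool[pool$class == "pve", ])
  expect_true(all(grepl("^m", ids)))
  expect_length(ids, 2)
})

test_that("pooled burst statistics recover the generator schedule", {
  kin <- small_kinetics(quiescent_prob = 0)
  bm <- simulate_burst_movies(30, kin, seed = 12, n_pve = 1)
  ba <- burst_analysis(bm$traces)
  sched <- bm$truth$burst_schedule
  expect_lt(abs(ba$pooled$n_bursts - nrow(sched)) / nrow(sched), 0.15)
  expect_lt(abs(ba$pooled$mean_fraction_per_burst - mean(sched$fraction)),
            0.05)
})
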