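test_that("continuous T1 productivity passes through its anchor values", {
  expect_identical(t1_productivity(90), 1)
  expect_equal(t1_productivity(45), 0, tolerance = 1e-15)
  expect_identical(t1_productivity(0), -1)
  # antisymmetric under exchanging the roles of the AP and DV axes
  a <- stats::runif(25, 0, 90)
  expect_equal(t1_productivity(a), -t1_productivity(90 - a))
  # the linear alternative shares the anchors
  expect_equal(t1_productivity(c(0, 45, 90), method = "linear"), c(-1, 0, 1))
  expect_error(t1_productivity(120))
})

test_that("a static movie yields no events and a single scripted swap is
           recovered exactly", {
  m <- generate_tessellation(80, jitter = 0.1, seed = 5)
  static <- simulate_movie(m, seq(0, 8, 0.5), track_noise_um = 0, seed = 1)
  expect_equal(nrow(detect_t1(static)), 0L)

  sw <- schedule_swaps(m, 1, t_range = c(8, 8), seed = 2)
  mv <- simulate_movie(m, seq(0, 14, 0.5), swaps = sw, seed = 3)
  ev <- detect_t1(mv)
  expect_equal(nrow(ev), 1L)
  expect_equal(ukey(ev$lose_a, ev$lose_b), ukey(sw$lose_a, sw$lose_b))
  expect_equal(ukey(ev$gain_a, ev$gain_b), ukey(sw$gain_a, sw$gain_b))
  expect_lte(abs(ev$t_swap_min - sw$t_swap_min), 0.5)
})

test_that("all scheduled swaps in a movie are detected with correct quartets", {
  m <- generate_tessellation(120, jitter = 0.15, seed = 6)
  sw <- schedule_swaps(m, 8, t_range = c(4, 16), seed = 7)
  mv <- simulate_movie(m, seq(0, 20, 0.5), swaps = sw, seed = 8)
  ev <- detect_t1(mv)
  expect_equal(nrow(ev), nrow(sw))
  truth <- mv$ground_truth$swaps
  mt <- match(ukey(ev$lose_a, ev$lose_b), ukey(truth$lose_a, truth$lose_b))
  expect_false(anyNA(mt))
  expect_equal(ukey(ev$gain_a, ev$gain_b),
               ukey(truth$gain_a, truth$gain_b)[mt])
  expect_true(all(abs(ev$t_swap_min - truth$t_swap_min[mt]) <= 0.5))
  # quartet contract: losing pair in contact before, not after; reverse for
  # the gaining pair
  intf <- interfaces_table(mv)
  for (i in seq_len(nrow(ev))) {
    kk <- ukey(intf$cell_a, intf$cell_b)
    lose_frames <- intf$frame[kk == ukey(ev$lose_a[i], ev$lose_b[i])]
    gain_frames <- intf$frame[kk == ukey(ev$gain_a[i], ev$gain_b[i])]
    expect_true(ev$frame_lose[i] %in% lose_frames)
    expect_false(ev$frame_gain[i] %in% lose_frames)
    expect_true(ev$frame_gain[i] %in% gain_frames)
    expect_false(ev$frame_lose[i] %in% gain_frames)
  }
})

test_that("exchange rates normalise by DV-oriented interfaces per minute", {
  m <- generate_tessellation(100, jitter = 0.1, seed = 9)
  mv <- simulate_movie(m, seq(0, 1, 0.5), track_noise_um = 0, seed = 1)
  intf <- interfaces_table(mv)
  n_dv <- sum(intf$orientation_deg[intf$frame == 1] > 45)
  events <- tibble::tibble(
    event = 1:5, t_swap_min = rep(0.5, 5), frame_lose = 1L, frame_gain = 2L,
    lose_a = "x", lose_b = "y", gain_a = "u", gain_b = "v",
    centroid_angle_deg = 90, productivity = t1_productivity(90))
  er <- exchange_rates(events, mv, breaks_min = c(0, 1))
  expect_equal(er$swap_rate, 5 / n_dv / 1)
  expect_equal(er$productive_rate, 5 / n_dv / 1)
  # the same five swaps at 45 degrees are unproductive
  events45 <- events
  events45$centroid_angle_deg <- 45
  events45$productivity <- t1_productivity(45)
  er45 <- exchange_rates(events45, mv, breaks_min = c(0, 1))
  expect_equal(er45$swap_rate, 5 / n_dv / 1)
  expect_equal(er45$productive_rate, 0, tolerance = 1e-15)
  # raw rate dominates |productive| always
  expect_gte(er$swap_rate + 1e-15, abs(er$productive_rate))
  # no events: zero rates
  er0 <- exchange_rates(events[0, ], mv, breaks_min = c(0, 1))
  expect_equal(er0$swap_rate, 0)
})

test_that("swap-aligned trajectories recover scripted shrinkage and growth", {
  m <- generate_tessellation(80, jitter = 0.05, seed = 10)
  sw <- schedule_swaps(m, 1, t_range = c(10, 10), shrink_min = 6,
                       grow_min = 5, new_length_um = 5, seed = 11)
  mv <- simulate_movie(m, seq(0, 18, 0.5), swaps = sw, track_noise_um = 0,
                       seed = 12)
  ev <- detect_t1(mv)
  al <- align_to_swap(ev, mv)
  shr <- al[al$phase == "shrinking", ]
  expect_true(all(shr$time_to_swap_min < 0))
  h0 <- shr$length_um[which.min(shr$time_to_swap_min)]
  # linear scripted shrinkage: constant absolute rate -h0/6 um/min
  ok <- !is.na(shr$abs_rate_um_min) & shr$time_to_swap_min > -5.5
  expect_equal(shr$abs_rate_um_min[ok], rep(-h0 / 6, sum(ok)),
               tolerance = 0.05)
  # proportional rate steepens toward the swap
  pr <- shr$prop_rate_pp_min[ok][order(shr$time_to_swap_min[ok])]
  expect_lt(pr[length(pr)], pr[1])
  gro <- al[al$phase == "growing", ]
  expect_true(all(gro$time_to_swap_min > 0))
  okg <- !is.na(gro$abs_rate_um_min) & gro$time_to_swap_min < 4.5
  expect_true(all(gro$abs_rate_um_min[okg] > 0))
  # ensemble summary has finite mean and se
  ens <- aligned_ensemble(al[al$phase == "shrinking", ],
                          lag_breaks_min = seq(-6, 0, 1),
                          swap_window_min = c(0, 30))
  expect_true(all(is.finite(ens$mean)))
})

test_that("aligned Myosin on shrinking junctions increases toward the swap
           when painted inversely to length", {
  m <- generate_tessellation(80, jitter = 0.05, seed = 13)
  sw <- schedule_swaps(m, 2, t_range = c(9, 12), shrink_min = 6, seed = 14)
  mv <- simulate_movie(m, seq(0, 16, 0.5), swaps = sw, track_noise_um = 0,
                       seed = 15)
  intf <- interfaces_table(mv)
  myos <- tibble::tibble(frame = intf$frame, cell_a = intf$cell_a,
                         cell_b = intf$cell_b,
                         density = 50 / pmax(intf$length_um, 0.1))
  ev <- detect_t1(mv)
  al <- align_to_swap(ev, mv, myosin = myos)
  shr <- al[al$phase == "shrinking" & al$time_to_swap_min > -5.5, ]
  for (e in unique(shr$event)) {
    tr <- shr[shr$event == e, ]
    tr <- tr[order(tr$time_to_swap_min), ]
    expect_true(all(diff(tr$myosin_density) >= -1e-9))
  }
})

test_that("new-neighbour angles track the gaining pair after the swap", {
  m <- generate_tessellation(80, jitter = 0.05, seed = 16)
  sw <- schedule_swaps(m, 1, t_range = c(8, 8), min_orientation_deg = 80,
                       seed = 17)
  mv <- simulate_movie(m, seq(0, 14, 0.5), swaps = sw, track_noise_um = 0,
                       seed = 18)
  ev <- detect_t1(mv)
  ang <- new_neighbour_angle(ev, mv, max_lag_min = 4)
  expect_true(all(ang$angle_deg >= 0 & ang$angle_deg <= 90))
  # DV-oriented losing junction: the new neighbours stack along DV
  expect_true(all(ang$angle_deg > 60))
})
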