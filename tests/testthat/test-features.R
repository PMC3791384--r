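g_def <- arena_geometry()

test_that("per-interval speeds are displacement over dt", {
  still <- make_traj(rep(10, 20), rep(15, 20))
  expect_equal(speeds(still), rep(0, 19))
  line <- make_traj(seq(2, 2 + 9 * 1, by = 1), rep(15, 10))
  expect_equal(speeds(line), rep(12.5, 9))
  hand <- make_traj(c(5, 8, 8, 8), c(10, 10, 14, 14), dt = 1)
  expect_equal(speeds(hand), c(3, 4, 0))
})

test_that("the hysteresis bout detector finds maximal movement episodes", {
  mp0 <- movement_params(start_speed = 1, stop_speed = 0.5, min_bout = 0)
  still <- make_traj(rep(10, 30), rep(15, 30))
  expect_equal(nrow(detect_bouts(still, mp0)), 0)

  # one block of 10 fast steps bracketed by stillness -> a single 10*dt bout
  x <- c(rep(5, 5), 5 + cumsum(rep(0.5, 10)), rep(10, 5))
  tr <- make_traj(x, rep(15, 20))
  b <- detect_bouts(tr, mp0)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration, 10 * 0.08)

  # two fast blocks separated by one slow step -> two bouts
  x2 <- c(5, 5 + cumsum(rep(0.5, 4)), 7 + 0.001, 7.001 + cumsum(rep(0.5, 4)))
  tr2 <- make_traj(x2, rep(15, 10))
  expect_equal(nrow(detect_bouts(tr2, mp0)), 2)

  # dead-band speeds (between stop and start) extend a running bout
  x3 <- c(5, 5.5, 5.56, 5.62, 6.12, 6.12, 6.12)  # fast, slow-ish, fast, stop
  tr3 <- make_traj(x3, rep(15, 7))
  b3 <- detect_bouts(tr3, mp0)
  expect_equal(nrow(b3), 1)
  expect_equal(b3$duration, 4 * 0.08)

  # min_bout removes short bouts
  mp <- movement_params(min_bout = 0.5)
  expect_equal(nrow(detect_bouts(tr2, mp)), 0)
})

test_that("zone episodes follow the start-inside and censoring conventions", {
  n <- 4500  # a full 6-min trial at 12.5 Hz
  inside <- make_traj(rep(3, n), rep(15, n))
  ep <- zone_episodes(inside, g_def, "stimulus")
  expect_equal(ep, list(entries = 1L, first_latency = 0, total_duration = 360))
  opp <- zone_episodes(inside, g_def, "opposite")
  expect_equal(opp, list(entries = 0L, first_latency = 360, total_duration = 0))
  # entering the stimulus strip at the 50th sample and staying
  enter <- make_traj(c(rep(10, 49), rep(3, n - 49)), rep(15, n))
  ep2 <- zone_episodes(enter, g_def, "stimulus")
  expect_equal(ep2$entries, 1L)
  expect_equal(ep2$first_latency, 3.92)
  expect_equal(ep2$total_duration, 356.08)
  expect_error(zone_episodes(inside, g_def, "center"),
               class = "lp_contract_error")
})

test_that("the eleven parameters are populated and deterministic", {
  n <- 4500
  still <- make_traj(rep(12.5, n), rep(15, n))
  f <- extract_features(still, g_def)
  expect_equal(f$TDM, 0); expect_equal(f$FOM, 0); expect_equal(f$TDMV, 0)
  expect_equal(f$AI, 0); expect_equal(f$EFISA, 0); expect_equal(f$LFOISA, 360)
  expect_equal(f$MDTSG, sqrt(12.5^2 + 0^2))

  hand <- make_traj(c(5, 8, 8, 5, 5), c(10, 10, 14, 14, 10), dt = 1)
  expect_equal(extract_features(hand, g_def)$TDM, 14)

  parked <- make_traj(rep(0, n), rep(15, n))
  fp <- extract_features(parked, g_def)
  expect_equal(fp$MDTSG, 0)
  expect_equal(fp$AI, 360)
  expect_identical(names(fp), c("subject_id", "phase", FEATURE_NAMES))
})

test_that("total distance moved is invariant under arena mirror symmetries", {
  set.seed(31)
  tr <- random_traj(80, g_def)
  tdm <- extract_features(tr, g_def)$TDM
  mx <- make_traj(g_def$test_length - tr$x, tr$y)
  my <- make_traj(tr$x, g_def$width - tr$y)
  expect_equal(extract_features(mx, g_def)$TDM, tdm, tolerance = 1e-12)
  expect_equal(extract_features(my, g_def)$TDM, tdm, tolerance = 1e-12)
})

test_that("mirroring the stimulus axis negates AI and swaps the zone features", {
  set.seed(17)
  for (i in 1:10) {
    tr <- random_traj(60, g_def)
    f <- extract_features(tr, g_def)
    fm <- extract_features(make_traj(g_def$test_length - tr$x, tr$y), g_def)
    expect_equal(fm$AI, -f$AI)
    expect_equal(fm$EFISA, f$EFIOSA); expect_equal(fm$LFOISA, f$LFOIOSA)
    expect_equal(fm$EFIOSA, f$EFISA); expect_equal(fm$LFOIOSA, f$LFOISA)
  }
})

test_that("2x upsampling preserves TDM and moves zone durations by at most dt per crossing", {
  set.seed(23)
  for (i in 1:5) {
    tr <- random_traj(60, g_def)
    xs <- approx(tr$t, tr$x, n = 2 * length(tr$t) - 1)$y
    ys <- approx(tr$t, tr$y, n = 2 * length(tr$t) - 1)$y
    up <- make_traj(xs, ys, dt = tr$dt / 2)
    expect_equal(extract_features(up, g_def)$TDM,
                 extract_features(tr, g_def)$TDM, tolerance = 1e-9)
    for (z in c("stimulus", "opposite", "wall")) {
      a <- zone_episodes(tr, g_def, z); b <- zone_episodes(up, g_def, z)
      expect_lte(abs(a$total_duration - b$total_duration),
                 tr$dt * (max(a$entries, b$entries) + 1))
    }
  }
})

test_that("a zone with positive occupancy has at least one entry", {
  set.seed(5)
  for (i in 1:20) {
    tr <- random_traj(40, g_def)
    for (z in c("stimulus", "opposite", "wall")) {
      ep <- zone_episodes(tr, g_def, z)
      if (ep$total_duration > 0) expect_gte(ep$entries, 1)
      expect_identical(ep$entries == 0L, ep$total_duration == 0)
    }
  }
})

test_that("all parameters match an independent brute-force recomputation", {
  set.seed(99)
  mp <- movement_params(start_speed = 1, stop_speed = 0.5, min_bout = 0.16)
  for (i in 1:10) {
    tr <- random_traj(sample(5:20, 1), g_def, step_sd = runif(1, 0.01, 3))
    f <- extract_features(tr, g_def, mp)
    o <- brute_features(tr, g_def, mp)
    expect_equal(unlist(f[FEATURE_NAMES]), o[FEATURE_NAMES],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})
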