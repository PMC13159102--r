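drift_track <- function(v = 0.087, n = 10, x0 = 8, dt = 5, noise = 0,
                        fl = 10) {
  tt <- (seq_len(n) - 1) * dt
  as_track(data.frame(t = tt, x = x0 - v * tt + rnorm(n, 0, noise)),
           filament_length = fl)
}

test_that("track construction enforces ordering and uniform spacing", {
  expect_error(as_track(data.frame(t = c(0, 5, 5), x = 1:3)),
               "strictly increasing")
  expect_error(as_track(data.frame(t = c(0, 5, 11), x = 1:3)),
               "uniformly spaced")
  tr <- as_track(data.frame(t_s = c(0, 5, 10), x_um = c(1, 2, 3)))
  expect_equal(tr$frame_interval, 5)
})

test_that("pure drift yields a single processive event with the right velocity", {
  tr <- drift_track(v = 0.087, n = 10)
  ev <- segment_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$class, "processive")
  expect_equal(ev$start, 1L)
  expect_equal(ev$end, 10L)
  expect_equal(ev$velocity, 0.087, tolerance = 1e-12)
})

test_that("pure jitter above the floor is one diffusive event", {
  x <- 5 + rep(c(0.3, -0.3), 4)     # 8 frames alternating +-0.3 um
  tr <- as_track(data.frame(t = (0:7) * 5, x = x))
  ev <- segment_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$class, "diffusive")
})

test_that("localization noise alone stays static", {
  set.seed(21)
  tr <- as_track(data.frame(t = (0:29) * 5, x = 5 + rnorm(30, 0, 0.05)))
  ev <- segment_events(tr)
  expect_equal(ev$class, "static")
})

test_that("changepoints are recovered within one frame on noisy tracks", {
  set.seed(99)
  hits <- 0L
  for (i in 1:200) {
    xc <- c(rep(5, 5), 5 - 0.3 * (1:10))
    x <- xc + rnorm(15, 0, 0.05)
    tr <- as_track(data.frame(t = (0:14) * 5, x = x))
    ev <- segment_events(tr)
    proc <- ev[ev$class == "processive", , drop = FALSE]
    if (nrow(proc) >= 1 && abs(proc$start[1] - 5L) <= 1L) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("event velocity follows least squares with minus-end sign convention", {
  tr <- drift_track(v = 0.087, n = 8)
  ev <- segment_events(tr)
  expect_equal(event_velocity(ev[1, ], tr), 0.087, tolerance = 1e-12)

  two <- data.frame(class = "processive", start = 1L, end = 2L)
  expect_equal(event_velocity(two, tr), (tr$x[1] - tr$x[2]) / 5,
               tolerance = 1e-12)

  diffev <- data.frame(class = "diffusive", start = 1L, end = 5L)
  expect_error(event_velocity(diffev, tr), "processive")

  set.seed(31)
  est <- replicate(200, {
    tr <- drift_track(v = 0.055, n = 12, noise = 0.05)
    ev <- segment_events(tr)
    ev$velocity[which(ev$class == "processive")[1]]
  })
  expect_equal(mean(est, na.rm = TRUE), 0.055, tolerance = 0.05)
})

test_that("run distance and run/length ratio follow their definitions", {
  tr <- as_track(data.frame(t = (0:4) * 5, x = c(9, 7.2, 5.4, 3.2, 1.6)),
                 filament_length = 10)
  ev <- data.frame(class = "processive", start = 1L, end = 5L)
  expect_equal(run_distance(ev, tr), 7.4)
  expect_equal(run_ratio(ev, tr), 0.74)

  tr_nolen <- as_track(data.frame(t = (0:4) * 5, x = c(9, 7, 5, 3, 1.6)))
  expect_error(run_ratio(ev, tr_nolen), "filament_length")

  tr_over <- as_track(data.frame(t = (0:4) * 5, x = c(10.5, 8, 6, 3, -0.4)),
                      filament_length = 10)
  expect_warning(r <- run_ratio(ev, tr_over), "capped")
  expect_equal(r, 1)
})

test_that("event rates normalize to microtubule length times minutes", {
  er <- event_rate(4L, mt_length = 10, duration = 20)
  expect_equal(er$rate[1], 0.02)
  expect_equal(event_rate(0L, 10, 20)$rate[1], 0)
  expect_error(event_rate(4L, 0, 20), "mt_length")
  expect_error(event_rate(4L, 10, 0), "duration")

  set.seed(12)
  fx <- gen_tracks(n = 12, kind = "mixture", seed = 12)
  pooled <- do.call(rbind, lapply(fx$tracks, segment_events))
  er2 <- event_rate(pooled, mt_length = 10, duration = 20)
  for (cl in c("processive", "diffusive")) {
    n_brute <- sum(pooled$class == cl)
    expect_equal(er2$rate[er2$class == cl], n_brute / (10 * 20))
  }
})

test_that("track summaries satisfy their definitions and inequality", {
  tr <- as_track(data.frame(t = (0:4) * 5, x = seq(0, 2, length.out = 5)))
  s <- track_summary(tr)
  expect_equal(s$track_length, s$displacement)
  expect_equal(s$mean_velocity, 2 / 20)

  loop <- as_track(data.frame(t = (0:4) * 5, x = c(0, 1, 1, 0, 0),
                              y = c(0, 0, 1, 1, 0)))
  sl <- track_summary(loop)
  expect_equal(sl$displacement, 0)
  expect_gt(sl$track_length, 0)

  set.seed(77)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    tr <- as_track(data.frame(t = (0:(n - 1)) * 5, x = cumsum(rnorm(n)),
                              y = cumsum(rnorm(n))))
    s <- track_summary(tr)
    expect_gte(s$track_length + 1e-12, s$displacement)
    o <- oracle_track_summary(tr$t, tr$x, tr$y)
    expect_equal(s$track_length, o$track_length, tolerance = 1e-12)
    expect_equal(s$displacement, o$displacement, tolerance = 1e-12)
  }
})

test_that("event segments partition every track", {
  set.seed(55)
  fx <- gen_tracks(n = 20, kind = "mixture", seed = 55)
  for (tr in fx$tracks) {
    ev <- segment_events(tr)
    # steps covered exactly once: event over frames [start, end] owns
    # steps start..end-1
    covered <- unlist(mapply(function(s, e) s:(e - 1), ev$start, ev$end,
                             SIMPLIFY = FALSE))
    expect_identical(sort(covered), seq_len(length(tr$x) - 1L))
    expect_identical(ev$start[-1], ev$end[-nrow(ev)])
  }
})

test_that("statistics are scale covariant", {
  set.seed(13)
  tr <- drift_track(v = 0.06, n = 12, noise = 0.03)
  ev <- segment_events(tr, noise_floor = 0.1)
  c_ <- 2.5
  tr2 <- as_track(data.frame(t = tr$t, x = c_ * tr$x),
                  filament_length = 10 * c_)
  ev2 <- segment_events(tr2, noise_floor = 0.1 * c_)
  expect_identical(ev2$class, ev$class)
  expect_equal(ev2$velocity, c_ * ev$velocity, tolerance = 1e-9)
  expect_equal(ev2$run_distance, c_ * ev$run_distance, tolerance = 1e-9)
  s1 <- track_summary(tr); s2 <- track_summary(tr2)
  expect_equal(s2$track_length, c_ * s1$track_length, tolerance = 1e-9)
})
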