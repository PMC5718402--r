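straight_track <- function(v_ms = 1, length_km = 1000, step_km = 5) {
  n <- length_km / step_km
  data.frame(time = as.POSIXct("2008-01-01", tz = "UTC") +
               (0:n) * step_km * 1000 / v_ms,
             lon = 0, lat = 55 + (0:n) * step_km / 111.195)
}

test_that("equidistant resampling preserves spacing, count and path length", {
  tr <- straight_track(length_km = 100)
  rs <- resample_track_equidistant(tr, 5)
  expect_equal(nrow(rs), 21)  # 100/5 + 1
  n <- nrow(rs)
  seg <- gc_dist_km(rs$lon[-n], rs$lat[-n], rs$lon[-1], rs$lat[-1])
  expect_true(all(abs(seg - 5) < 0.005))
  expect_lt(abs(sum(seg) - 100) / 100, 0.001)
  # constant speed -> equally spaced timestamps
  expect_equal(diff(range(diff(as.numeric(rs$time)))), 0, tolerance = 1)
  # oracle path-length preservation on a wiggly random track
  wt <- random_track(40, seed = 9)
  rw <- resample_track_equidistant(wt, 5)
  nw <- nrow(wt)
  len_orig <- sum(gc_dist_km(wt$lon[-nw], wt$lat[-nw], wt$lon[-1], wt$lat[-1]))
  expect_lt(abs(max(rw$cumdist_km) - len_orig), 5)  # within one spacing
})

test_that("FPT on a straight constant-speed track equals 2r/v", {
  rs <- resample_track_equidistant(straight_track(v_ms = 1), 5)
  for (r in c(10, 30, 55)) {
    f <- fpt_at_radius(rs, r)
    expected_hr <- 2 * r * 1000 / 1 / 3600
    interior <- which(!is.na(f))
    expect_lt(max(abs(f[interior] - expected_hr)) / expected_hr, 0.02)
  }
  expect_error(fpt_at_radius(rs, -1), "positive")
})

test_that("doubling back inside the circle increases FPT beyond 2r/v", {
  # approach, wiggle (out 20 km, back 10, out again), depart: the point at
  # the wiggle's start dwells inside its 15-km circle longer than a straight
  # pass would
  km <- c(seq(-50, -2.5, by = 2.5), seq(0, 12.5, by = 2.5),
          seq(10, 5, by = -2.5), seq(7.5, 60, by = 2.5))
  tr <- data.frame(time = as.POSIXct("2008-01-01", tz = "UTC") +
                     seq_along(km) * 2500, lon = 0, lat = 55 + km / 111.195)
  f <- fpt_at_radius(tr, 15)
  i0 <- which(abs(km) < 1e-9)  # the wiggle's origin
  v_kmh <- 2.5 / (2500 / 3600)
  expect_gt(f[i0], 2 * 15 / v_kmh)
})

test_that("FPT matches the brute-force crossing-search oracle", {
  for (seed in 1:3) {
    tr <- random_track(50, seed)
    for (r in c(5, 15, 40))
      expect_equal(fpt_at_radius(tr, r), oracle_fpt(tr, r), tolerance = 1e-9)
  }
})

test_that("FPT is non-decreasing in radius and invariant to track reversal", {
  tr <- random_track(60, seed = 2)
  f10 <- fpt_at_radius(tr, 10)
  f20 <- fpt_at_radius(tr, 20)
  both <- !is.na(f10) & !is.na(f20)
  expect_true(all(f20[both] >= f10[both] - 1e-9))
  tt <- as.numeric(tr$time)
  rev_tr <- data.frame(time = as.POSIXct(max(tt) - rev(tt) + min(tt),
                                         origin = "1970-01-01", tz = "UTC"),
                       lon = rev(tr$lon), lat = rev(tr$lat))
  expect_equal(rev(fpt_at_radius(rev_tr, 20)), f20, tolerance = 1e-6)
})

test_that("ARS-scale selection is permutation invariant and flags flat curves", {
  sim <- simulate_track(noise_free_config(seed = 4, n_animals = 1,
                                          duration_days = 20))
  trips <- latent_trips(sim)
  a <- select_ars_scale(trips, seq(10, 60, by = 5))
  b <- select_ars_scale(rev(trips), seq(10, 60, by = 5))
  expect_equal(a$selected_radius_km, b$selected_radius_km)
  expect_true(a$informative)
  st <- resample_track_equidistant(straight_track(length_km = 400), 5)
  expect_message(flat <- select_ars_scale(st, c(10, 20, 30)), "flat")
  expect_false(flat$informative)
})

test_that("FPT is higher inside simulated patches than outside", {
  sim <- simulate_track(noise_free_config(seed = 12, n_animals = 1,
                                          duration_days = 25))
  trips <- latent_trips(sim)
  fpt <- unlist(lapply(trips, fpt_at_radius, r_km = 30))
  pts <- do.call(rbind, trips)
  pat <- sim$truth$patches
  d_pat <- do.call(pmin, lapply(seq_len(nrow(pat)), function(k)
    gc_dist_km(pts$lon, pts$lat, pat$lon[k], pat$lat[k])))
  inside <- d_pat < pat$radius_km[1]
  expect_gt(mean(fpt[inside], na.rm = TRUE), mean(fpt[!inside], na.rm = TRUE))
})

test_that("haul-out exclusion matches a brute-force distance scan", {
  pts <- random_track(50, seed = 6)
  pts$animal_id <- "a"; pts$fpt_hr <- 1
  ho <- data.frame(lon = pts$lon[c(10, 40)], lat = pts$lat[c(10, 40)])
  out <- exclude_haulout_fpt(pts, ho, 25)
  keep_oracle <- sapply(seq_len(nrow(pts)), function(i)
    all(gc_dist_km(pts$lon[i], pts$lat[i], ho$lon, ho$lat) >= 25))
  expect_equal(nrow(out), sum(keep_oracle))
  expect_identical(exclude_haulout_fpt(pts, ho[0, ], 25), pts)
  expect_equal(nrow(exclude_haulout_fpt(pts[10, ], ho, 25)), 0)
})

test_that("daily FPT aggregation matches the group-by oracle", {
  pts <- data.frame(animal_id = "a",
                    time = as.POSIXct("2008-04-01", tz = "UTC") + (0:23) * 3600,
                    fpt_hr = 6)
  expect_equal(daily_fpt(pts)$mean_fpt_hr, 6)
  set.seed(11)
  pts <- data.frame(animal_id = sample(c("a", "b"), 80, TRUE),
                    time = as.POSIXct("2008-04-01", tz = "UTC") +
                      runif(80, 0, 6 * 86400),
                    fpt_hr = c(runif(70, 1, 40), rep(NA, 10)))
  got <- daily_fpt(pts)
  keep <- !is.na(pts$fpt_hr)
  want <- oracle_daily_mean(pts$animal_id[keep],
                            as.Date(pts$time[keep], tz = "UTC"),
                            pts$fpt_hr[keep])
  expect_equal(got$mean_fpt_hr, want$mean)
})

test_that("foraging-day flagging uses a strict type-7 quantile threshold", {
  d <- data.frame(animal_id = "a", day = as.Date("2008-04-01") + 0:99,
                  mean_fpt_hr = 1:100)
  f <- foraging_days(d, 0.75)
  expect_equal(sum(f$foraging), 25)
  expect_equal(which(f$foraging), 76:100)
  same <- data.frame(animal_id = "a", day = as.Date("2008-04-01") + 0:9,
                     mean_fpt_hr = rep(7, 10))
  expect_equal(sum(foraging_days(same)$foraging), 0)
  expect_error(foraging_days(d[1:3, ]), "at least 4")
  set.seed(3)
  r <- data.frame(animal_id = "a", day = as.Date("2008-04-01") + 0:49,
                  mean_fpt_hr = rnorm(50))
  fr <- foraging_days(r, 0.75)
  s <- sort(r$mean_fpt_hr)
  h <- (50 - 1) * 0.75 + 1                  # type-7 interpolation index
  thr <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  expect_equal(fr$foraging, r$mean_fpt_hr > thr)
})
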