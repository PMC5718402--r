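mk_fixes <- function(lon, lat, dt_hr = 1, lc = "3", id = "s1") {
  data.frame(animal_id = id,
             time = as.POSIXct("2008-04-01", tz = "UTC") +
               (seq_along(lon) - 1) * dt_hr * 3600,
             lon = lon, lat = lat, lc = lc)
}

test_that("a slow straight track passes the SDA filter untouched", {
  fx <- mk_fixes(lon = c(0, 0, 0), lat = 70 + (0:2) / 111.2)  # 1 km/hr steps
  expect_equal(nrow(sda_filter(fx)), 3)
})

test_that("a fix requiring >2 m/s to both neighbours is removed", {
  # neighbours 1 hr apart; displace the middle fix so both legs need ~3 m/s
  lat0 <- 70
  off_km <- 3 * 3.6  # 3 m/s for 1 hr
  fx <- mk_fixes(lon = c(0, off_km / (111.2 * cos(lat0 * pi / 180)), 0),
                 lat = c(lat0, lat0, lat0 + 2 / 111.2))
  out <- sda_filter(fx)
  expect_equal(nrow(out), 2)
  expect_equal(out$time, fx$time[c(1, 3)])
})

test_that("all LC Z fixes are removed and filtering is idempotent", {
  sim <- shared_sim()$sim
  f1 <- sda_filter(sim$fixes)
  expect_false(any(f1$lc == "Z"))
  expect_gt(sum(sim$fixes$lc == "Z"), 0)
  expect_identical(sda_filter(f1), f1)
})

test_that("spike rule removes sharp-angle long-leg artifacts", {
  # out-and-back spike: 6 km out at a ~5 degree internal angle
  fx <- mk_fixes(lon = c(0, 0.01, 0.19, 0.02, 0.03),
                 lat = c(70, 70, 70.002, 70, 70), dt_hr = 5)
  out <- sda_filter(fx)
  expect_false(70.002 %in% out$lat)
})

test_that("fewer than 3 fixes are returned unchanged with a warning", {
  fx <- mk_fixes(lon = c(0, 0.01), lat = c(70, 70))
  expect_warning(out <- sda_filter(fx), "fewer than 3")
  expect_equal(nrow(out), 2)
})

test_that("state-space smoothing reduces position error on noisy tracks", {
  cfg <- sim_config(n_animals = 1, duration_days = 12, seed = 31)
  sim <- simulate_track(cfg)
  fx <- sda_filter(sim$fixes)
  tr <- smooth_track(fx, sim$truth$haulouts, interval_hr = 1)
  la <- sim$truth$latent
  m <- match(as.numeric(tr$time), as.numeric(la$time))
  ok <- !is.na(m)
  rmse_s <- sqrt(mean(gc_dist_km(tr$lon[ok], tr$lat[ok],
                                 la$lon[m[ok]], la$lat[m[ok]])^2))
  mr <- match(as.numeric(fx$time), as.numeric(la$time))
  rmse_r <- sqrt(mean(gc_dist_km(fx$lon, fx$lat, la$lon[mr], la$lat[mr])^2))
  expect_lt(rmse_s, rmse_r)
  expect_true(all(tr$position_se >= 0))
  expect_equal(unique(diff(as.numeric(tr$time))), 3600)
})

test_that("identical fixes smooth to the same position", {
  fx <- mk_fixes(lon = rep(5, 10), lat = rep(70, 10))
  tr <- smooth_track(fx, NULL, interval_hr = 1)
  expect_equal(tr$lon, rep(5, nrow(tr)), tolerance = 1e-6)
  expect_equal(tr$lat, rep(70, nrow(tr)), tolerance = 1e-6)
})

test_that("a displaced fix during a haul-out does not move the track", {
  n <- 30
  lon <- rep(10, n); lat <- rep(75, n)
  lon[1:10] <- seq(9.5, 10, length.out = 10)     # approach, then haul out
  fx <- mk_fixes(lon = lon, lat = lat)
  ho <- data.frame(animal_id = "s1", start = fx$time[11], end = fx$time[n])
  fx$lon[20] <- 10 + 5 / (111.2 * cos(75 * pi / 180))  # 5 km off, mid haul-out
  tr <- smooth_track(fx, ho, interval_hr = 1)
  during <- tr$time >= ho$start & tr$time <= ho$end
  drift_km <- gc_dist_km(tr$lon[during], tr$lat[during], 10, 75)
  expect_lt(max(drift_km), 0.5)
})

test_that("season labelling follows the haul-out rules per class", {
  tp <- data.frame(animal_id = "s1",
                   time = seq(as.POSIXct("2008-03-20", tz = "UTC"),
                              as.POSIXct("2008-08-15", tz = "UTC"), by = "day"),
                   lon = 0, lat = 70)
  ho <- data.frame(animal_id = "s1",
                   start = as.POSIXct(c("2008-05-01", "2008-06-20", "2008-07-10"),
                                      tz = "UTC"),
                   end = as.POSIXct(c("2008-05-02", "2008-06-21", "2008-07-11"),
                                    tz = "UTC"))
  pup <- segment_seasons(tp, "pup", ho)
  expect_equal(attr(pup, "season_boundaries")[["post_breeding_end"]],
               as.POSIXct("2008-06-20", tz = "UTC"))
  adult <- segment_seasons(tp, "female", ho)
  expect_equal(attr(adult, "season_boundaries")[["post_breeding_end"]],
               as.POSIXct("2008-07-10", tz = "UTC"))
  # adult track ending before the molt is entirely post-breeding
  short <- tp[tp$time < as.POSIXct("2008-07-01", tz = "UTC"), ]
  lab <- segment_seasons(short, "female", ho[1, ])
  expect_true(all(lab$season == "post_breeding"))
  expect_match(attr(lab, "season_flags")[1], "record end")
})

test_that("trip segmentation counts loops and flags incomplete trips", {
  ctr <- c(lon = 13.5, lat = 73.86)
  mk_loop <- function(n_loops, die_offshore = FALSE) {
    lat_seq <- c()
    for (k in seq_len(n_loops))
      lat_seq <- c(lat_seq, seq(73.86, 68, length.out = 40),
                   seq(68, 73.86, length.out = 40))
    if (die_offshore) lat_seq <- c(lat_seq, seq(73.86, 69, length.out = 30))
    tp <- data.frame(animal_id = "m1",
                     time = as.POSIXct("2008-03-20", tz = "UTC") +
                       seq_along(lat_seq) * 3600,
                     lon = 13.5, lat = lat_seq, season = "post_breeding")
    tp
  }
  five <- segment_trips(mk_loop(5), "male", ctr)
  expect_equal(nrow(five$trips), 5)
  expect_true(all(five$trips$complete))
  died <- segment_trips(mk_loop(1, die_offshore = TRUE), "male", ctr)
  expect_equal(nrow(died$trips), 2)
  expect_equal(died$trips$complete, c(TRUE, FALSE))
  # every outside point belongs to exactly one trip
  pts <- five$points
  d <- gc_dist_km(pts$lon, pts$lat, ctr["lon"], ctr["lat"])
  expect_true(all(!is.na(pts$trip_id[d > 250])))
})

test_that("pup trips are delimited by season boundaries, not the disc", {
  tp <- data.frame(animal_id = "p1",
                   time = seq(as.POSIXct("2008-03-20", tz = "UTC"),
                              by = "day", length.out = 100),
                   lon = 13.5, lat = seq(73.86, 60, length.out = 100))
  tp$season <- rep(c("post_breeding", "post_molting"), each = 50)
  sg <- segment_trips(tp, "pup")
  expect_equal(nrow(sg$trips), 2)
  expect_equal(sg$trips$season, c("post_breeding", "post_molting"))
})
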