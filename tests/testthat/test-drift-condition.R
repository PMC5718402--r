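mk_profile <- function(ts, dd, id = "d1", animal = "s1",
                       start = as.POSIXct("2008-04-10 03:00:00", tz = "UTC")) {
  df <- data.frame(dive_id = id, animal_id = animal, start_time = start,
                   duration_s = ts[6], max_depth = max(dd))
  df[paste0("t", 0:5, "_s")] <- as.list(ts)
  df[paste0("d", 0:5, "_m")] <- as.list(dd)
  df
}

test_that("candidate extraction honours segment, duration and rate rules", {
  # V-shaped dive: two steep legs, no interior segment long enough
  v <- mk_profile(c(0, 250, 290, 310, 350, 600), c(0, 250, 260, 258, 250, 0))
  expect_equal(nrow(extract_drift_candidates(v)), 0)
  # 40%-duration mid-segment sinking at 0.30 m/s
  d <- mk_profile(c(0, 72, 84, 324, 336, 600), c(0, 150, 152, 224, 222, 0))
  cand <- extract_drift_candidates(d)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$seg, 3)
  expect_equal(cand$drift_rate, -0.30)
  expect_equal(cand$mean_depth, 188)
  # the same segment fails if its duration fraction is below threshold
  expect_equal(nrow(extract_drift_candidates(d, min_frac = 0.45)), 0)
})

test_that("candidate counts equal a brute-force segment scan", {
  dv <- shared_sim()$dv$dives
  cand <- extract_drift_candidates(dv)
  n_oracle <- 0
  for (i in seq_len(nrow(dv))) {
    ts <- as.numeric(dv[i, paste0("t", 0:5, "_s")])
    dd <- as.numeric(dv[i, paste0("d", 0:5, "_m")])
    for (s in 2:4) {
      dur <- ts[s + 1] - ts[s]
      rate <- abs((dd[s + 1] - dd[s]) / dur)
      if (dur >= 0.30 * dv$duration_s[i] && rate >= 0.01 && rate <= 1.2)
        n_oracle <- n_oracle + 1
    }
  }
  expect_equal(nrow(cand), n_oracle)
})

test_that("positive-drift screening keeps clustered and drops isolated events", {
  seg <- data.frame(animal_id = "a",
                    day = as.Date("2008-04-01") + c(0, 1, 2, 4, 30),
                    drift_rate = c(0.1, 0.12, 0.08, 0.09, 0.11))
  out <- screen_positive_drifts(seg)
  expect_true(all(out$flagged_positive))
  expect_equal(out$excluded, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # a single isolated positive among negatives is excluded
  seg2 <- data.frame(animal_id = "a", day = as.Date("2008-04-01") + 0:4,
                     drift_rate = c(-0.3, -0.28, 0.05, -0.31, -0.29))
  out2 <- screen_positive_drifts(seg2)
  expect_equal(which(out2$excluded), 3L)
  # oracle neighbourhood scan
  set.seed(7)
  seg3 <- data.frame(animal_id = sample(c("a", "b"), 40, TRUE),
                     day = as.Date("2008-04-01") + sample(0:20, 40, TRUE),
                     drift_rate = rnorm(40, 0, 0.2))
  out3 <- screen_positive_drifts(seg3, k = 2, window_days = 5)
  for (i in which(out3$flagged_positive)) {
    others <- sum(seg3$drift_rate > 0 & seg3$animal_id == seg3$animal_id[i] &
                    abs(as.numeric(seg3$day - seg3$day[i])) <= 5) - 1
    expect_equal(out3$excluded[i], others < 2)
  }
})

test_that("trip inclusion requires one segment per two days", {
  expect_true(trip_inclusion(10, 5))    # boundary
  expect_false(trip_inclusion(10, 4))
  set.seed(8)
  days <- runif(20, 2, 60); n <- rpois(20, 15)
  expect_equal(trip_inclusion(days, n), n >= days / 2)
})

test_that("drift classifier separates drift from active dives (held out)", {
  s <- shared_sim()
  dv <- s$dv$dives
  cand <- extract_drift_candidates(dv)
  feats <- drift_features(dv, cand)
  lab <- s$dv$labels$is_drift[match(feats$dive_id, dv$dive_id)]
  set.seed(42)
  tr_idx <- sample(nrow(feats), floor(0.6 * nrow(feats)))
  clf <- train_drift_classifier(feats[tr_idx, ], lab[tr_idx])
  pr <- classify_drift_dive(clf, dv, cand)
  p_te <- pr$probability[match(feats$dive_id[-tr_idx], pr$dive_id)]
  auc <- as.numeric(pROC::auc(pROC::roc(lab[-tr_idx], p_te, quiet = TRUE)))
  expect_gte(auc, 0.90)
  # no-candidate dives have probability 0 by definition
  no_cand <- setdiff(dv$dive_id, cand$dive_id)
  expect_true(all(pr$probability[match(no_cand, pr$dive_id)] == 0))
  expect_error(classify_drift_dive(NULL, dv, cand), "train_drift_classifier")
})

test_that("the drift spline recovers a constant rate with zero daily change", {
  tt <- as.POSIXct("2008-04-01", tz = "UTC") + seq(0, 20 * 86400, by = 86400 / 2)
  seg <- data.frame(time = tt, drift_rate = -0.30,
                    weight = runif(length(tt), 0.3, 1))
  fit <- fit_drift_spline(seg)
  expect_equal(fit$daily$rate, rep(-0.30, nrow(fit$daily)), tolerance = 1e-6)
  expect_equal(fit$daily$change, rep(0, nrow(fit$daily)), tolerance = 1e-6)
})

test_that("zero-weight segments have no influence on the spline", {
  set.seed(9)
  tt <- as.POSIXct("2008-04-01", tz = "UTC") + sort(runif(40, 0, 25 * 86400))
  seg <- data.frame(time = tt, drift_rate = -0.3 + 0.004 * (1:40) + rnorm(40, 0, 0.01),
                    weight = runif(40, 0.5, 1))
  junk <- data.frame(time = tt[1:5] + 3600, drift_rate = 5, weight = 0)
  a <- fit_drift_spline(seg)
  b <- fit_drift_spline(rbind(seg, junk))
  expect_equal(a$daily$rate, b$daily$rate, tolerance = 1e-9)
})

test_that("duplicating a segment while halving its weight leaves the fit unchanged", {
  set.seed(10)
  tt <- as.POSIXct("2008-04-01", tz = "UTC") + sort(runif(30, 0, 20 * 86400))
  seg <- data.frame(time = tt, drift_rate = rnorm(30, -0.3, 0.05),
                    weight = runif(30, 0.4, 1))
  dup <- rbind(transform(seg[1:10, ], weight = weight / 2),
               transform(seg[1:10, ], weight = weight / 2), seg[11:30, ])
  a <- fit_drift_spline(seg)
  b <- fit_drift_spline(dup)
  expect_equal(a$daily$rate, b$daily$rate, tolerance = 1e-6)
})

test_that("daily change telescopes back to the endpoint difference", {
  set.seed(11)
  tt <- as.POSIXct("2008-04-01", tz = "UTC") + sort(runif(50, 0, 30 * 86400))
  seg <- data.frame(time = tt,
                    drift_rate = -0.35 + 0.005 * as.numeric(tt - tt[1]) / 86400 +
                      rnorm(50, 0, 0.01),
                    weight = 1)
  fit <- fit_drift_spline(seg)
  d <- fit$daily
  n <- nrow(d)
  # central differences telescope pairwise; the sum equals the endpoint
  # change up to the half-step end corrections
  expect_equal(sum(d$change[2:(n - 1)]),
               (d$rate[n] + d$rate[n - 1]) / 2 - (d$rate[1] + d$rate[2]) / 2,
               tolerance = 1e-9)
  # predictions stay within the observed envelope + tolerance
  expect_true(all(d$rate >= min(seg$drift_rate) - 0.05 &
                  d$rate <= max(seg$drift_rate) + 0.05))
})

test_that("the spline needs at least 4 positively weighted segments", {
  tt <- as.POSIXct("2008-04-01", tz = "UTC") + (0:4) * 86400
  seg <- data.frame(time = tt, drift_rate = -0.3, weight = c(1, 1, 1, 0, 0))
  expect_error(fit_drift_spline(seg), "at least 4")
})
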