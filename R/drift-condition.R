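# Drift-dive body-condition index. Passive drift segments are extracted from
# compressed dive profiles; a random forest scores each candidate dive's
# probability of being a true drift dive; rare positive (floating) drifts
# are screened; and per trip a weighted, range-constrained penalized B-spline
# reconstructs the daily drift-rate series, whose first derivative is the
# daily body-condition change index (positive = fattening).
#
# Sign convention throughout: drift_rate < 0 = sinking (lean animal),
# drift_rate > 0 = floating (fat animal). Depth is positive-down, so a
# sinking drift has increasing depth.

#' Extract candidate drift segments from compressed dive profiles
#'
#' A profile segment is a candidate when it is one of the three interior
#' segments (never the initial descent or final ascent leg), spans at least
#' `min_frac` of the dive duration, and its vertical rate magnitude lies in
#' `rate_window` (too slow = flat bottom; too fast = active swimming).
#'
#' @param dives dive table with wide profile columns
#' @param min_frac minimum segment duration as a fraction of dive duration
#' @param rate_window `c(min, max)` absolute vertical rate bounds, m/s
#' @return data.frame of candidate segments: dive_id, animal_id, seg (2-4),
#'   time (segment midpoint), day, duration_s, dur_frac, drift_rate (m/s,
#'   negative = sinking), mean_depth, depth_span
#' @export
extract_drift_candidates <- function(dives, min_frac = 0.30,
                                     rate_window = c(0.01, 1.2)) {
  out <- list()
  for (s in 2:4) {
    ta <- dives[[paste0("t", s - 1, "_s")]]; tb <- dives[[paste0("t", s, "_s")]]
    da <- dives[[paste0("d", s - 1, "_m")]]; db <- dives[[paste0("d", s, "_m")]]
    dur <- tb - ta
    slope <- (db - da) / pmax(dur, 1e-9)        # positive = deepening
    rate <- -slope                               # negative = sinking
    keep <- dur >= min_frac * dives$duration_s &
      abs(rate) >= rate_window[1] & abs(rate) <= rate_window[2]
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      dive_id = dives$dive_id[keep], animal_id = dives$animal_id[keep],
      seg = s,
      time = dives$start_time[keep] + (ta[keep] + tb[keep]) / 2,
      duration_s = dur[keep], dur_frac = dur[keep] / dives$duration_s[keep],
      drift_rate = rate[keep], mean_depth = (da[keep] + db[keep]) / 2,
      depth_span = abs(db[keep] - da[keep]))
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else NULL
  if (is.null(res))
    return(data.frame(dive_id = character(), animal_id = character(),
                      seg = integer(), time = as.POSIXct(character()),
                      duration_s = numeric(), dur_frac = numeric(),
                      drift_rate = numeric(), mean_depth = numeric(),
                      depth_span = numeric(), day = as.Date(character())))
  res$day <- as.Date(res$time, tz = "UTC")
  res[order(res$animal_id, res$time), ]
}

#' Per-dive feature vector for drift classification
#'
#' Uses each dive's best candidate (longest duration fraction). Dives with no
#' candidate are absent (their drift probability is 0 by definition).
#'
#' @param dives dive table
#' @param candidates from [extract_drift_candidates()]
#' @return data.frame: dive_id + numeric features
#' @export
drift_features <- function(dives, candidates) {
  if (!nrow(candidates)) return(data.frame(dive_id = character()))
  best <- candidates[order(candidates$dive_id, -candidates$dur_frac), ]
  best <- best[!duplicated(best$dive_id), ]
  m <- match(best$dive_id, dives$dive_id)
  # variance of interior-segment rates: a clean drift has one dominant
  # smooth segment, active dives wiggle
  slopes <- cbind((dives$d2_m - dives$d1_m) / pmax(dives$t2_s - dives$t1_s, 1e-9),
                  (dives$d3_m - dives$d2_m) / pmax(dives$t3_s - dives$t2_s, 1e-9),
                  (dives$d4_m - dives$d3_m) / pmax(dives$t4_s - dives$t3_s, 1e-9))
  data.frame(dive_id = best$dive_id,
             dur_frac = best$dur_frac,
             abs_rate = abs(best$drift_rate),
             rate_var = apply(slopes[m, , drop = FALSE], 1, stats::sd),
             depth_span = best$depth_span,
             duration_s = dives$duration_s[m],
             max_depth = dives$max_depth[m])
}

#' Train the random-forest drift-dive classifier
#'
#' Semi-supervised in the sense that labels come from the simulator's ground
#' truth (plus any user-supplied labelled examples appended to the training
#' set).
#'
#' @param features from [drift_features()]
#' @param labels logical vector (TRUE = drift dive), aligned with `features`
#' @param ntree forest size
#' @return object of class `drift_classifier`
#' @export
train_drift_classifier <- function(features, labels, ntree = 300) {
  x <- features[, setdiff(names(features), "dive_id"), drop = FALSE]
  rf <- randomForest::randomForest(x, factor(labels, levels = c(FALSE, TRUE)),
                                   ntree = ntree)
  structure(list(rf = rf, feature_names = names(x)), class = "drift_classifier")
}

#' Drift-dive probability for each dive
#'
#' @param model a `drift_classifier` (error if missing/unfitted)
#' @param dives dive table
#' @param candidates from [extract_drift_candidates()]
#' @return data.frame dive_id, probability (0 for dives with no candidate)
#' @export
classify_drift_dive <- function(model, dives, candidates) {
  if (!inherits(model, "drift_classifier"))
    stop("no fitted classifier; call train_drift_classifier() first")
  feats <- drift_features(dives, candidates)
  prob <- rep(0, nrow(dives))
  if (nrow(feats)) {
    p <- stats::predict(model$rf,
                        feats[, model$feature_names, drop = FALSE],
                        type = "prob")[, "TRUE"]
    prob[match(feats$dive_id, dives$dive_id)] <- p
  }
  data.frame(dive_id = dives$dive_id, probability = prob)
}

#' Screen rare positive (floating) drift segments
#'
#' Positive drift rates are rare and influential, so an isolated positive
#' segment is excluded unless at least `k` other positive segments from the
#' same animal occur within `window_days`. All positives are flagged for
#' review regardless, so a manual override table can be applied.
#'
#' @param segments candidate segments with animal_id, day, drift_rate
#' @param k minimum number of corroborating positive segments
#' @param window_days corroboration window, days
#' @return `segments` with logical columns `flagged_positive` and `excluded`
#' @export
screen_positive_drifts <- function(segments, k = 2, window_days = 5) {
  segments$flagged_positive <- segments$drift_rate > 0
  segments$excluded <- FALSE
  pos <- which(segments$flagged_positive)
  for (i in pos) {
    same <- pos[pos != i &
                segments$animal_id[pos] == segments$animal_id[i] &
                abs(as.numeric(segments$day[pos] - segments$day[i])) <= window_days]
    if (length(same) < k) segments$excluded[i] <- TRUE
  }
  segments
}

#' Trip inclusion rule for drift-spline fitting
#'
#' A trip is included only if it has at least one identified drift segment
#' per 2 days of trip duration.
#'
#' @param trip_duration_days trip duration, days
#' @param n_segments number of retained drift segments on the trip
#' @return logical
#' @export
trip_inclusion <- function(trip_duration_days, n_segments) {
  n_segments >= trip_duration_days / 2
}

#' Fit the weighted, constrained penalized B-spline to a trip's drift rates
#'
#' A cubic P-spline (knot spacing ~`knot_days`) is fitted to (time,
#' drift_rate) with per-segment weights (depth weight x classification
#' probability), smoothing parameter by generalized cross-validation. The
#' fitted curve is range-constrained to the observed drift-rate envelope
#' +/- `envelope_tol`. Daily rates are predicted at UTC-day midpoints and
#' the daily change is their first derivative by central finite differences.
#'
#' @param segments data.frame with time (POSIXct), drift_rate, weight
#' @param trip_id identifier carried through
#' @param knot_days target knot spacing, days
#' @param envelope_tol range-constraint tolerance, m/s
#' @param constraint "range" (default) or "none"
#' @return object of class `drift_spline_fit`: daily data.frame (day,
#'   rate, change), the mgcv fit, and the envelope
#' @export
fit_drift_spline <- function(segments, trip_id = NA_character_, knot_days = 5,
                             envelope_tol = 0.05,
                             constraint = c("range", "none")) {
  constraint <- match.arg(constraint)
  segments <- segments[segments$weight > 0, ]
  if (nrow(segments) < 4) stop("need at least 4 positively weighted drift segments")
  x <- as.numeric(segments$time) / 86400            # days
  x0 <- min(x)
  x <- x - x0
  y <- segments$drift_rate
  w <- segments$weight / mean(segments$weight)
  span <- max(x) - min(x)
  k <- max(4, min(round(span / knot_days) + 3, sum(!duplicated(x)) - 1, 20))
  fit <- NULL
  while (is.null(fit) && k >= 4) {
    fit <- tryCatch(
      mgcv::gam(y ~ s(x, bs = "ps", k = k), weights = w, method = "GCV.Cp"),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("spline basis singular at k = ", k, "; reducing knots")
      k <- k - 2
    }
  }
  if (is.null(fit)) stop("could not fit drift spline")
  day0 <- as.Date(as.POSIXct(x0 * 86400, origin = "1970-01-01", tz = "UTC"),
                  tz = "UTC")
  days <- seq(day0, as.Date(as.POSIXct((x0 + max(x)) * 86400,
                                       origin = "1970-01-01", tz = "UTC"),
                            tz = "UTC"), by = "day")
  xd <- as.numeric(as.POSIXct(paste(days, "12:00:00"), tz = "UTC")) / 86400 - x0
  pred <- as.numeric(stats::predict(fit, data.frame(x = xd)))
  env <- range(y)
  if (constraint == "range")
    pred <- pmin(pmax(pred, env[1] - envelope_tol), env[2] + envelope_tol)
  n <- length(pred)
  change <- numeric(n)
  if (n >= 2) {
    change[1] <- pred[2] - pred[1]
    change[n] <- pred[n] - pred[n - 1]
    if (n > 2) change[2:(n - 1)] <- (pred[3:n] - pred[1:(n - 2)]) / 2
  }
  structure(list(trip_id = trip_id, model = fit, k = k,
                 envelope = env,
                 daily = data.frame(day = days, rate = pred, change = change)),
            class = "drift_spline_fit")
}
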