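# Trip-level movement descriptors, circular statistics for trip headings,
# nonparametric class/season comparisons, and dive behaviour inside
# high-FPT foraging areas.

#' Movement summary for one trip
#'
#' The overall azimuth is the initial great-circle bearing from the trip's
#' first point to its most distant point (clockwise from north; ties in
#' distance broken by the earliest time). Maximum distance and duration are
#' reported for complete trips only, azimuth for all trips.
#'
#' @param trip data.frame with time, lon, lat (time-ordered)
#' @param complete logical; whether the trip returned to the deployment disc
#' @return data.frame: azimuth_deg, cos_azimuth, sin_azimuth,
#'   max_distance_km, duration_days (NA when incomplete), complete
#' @export
trip_summary <- function(trip, complete = TRUE) {
  if (nrow(trip) < 2) stop("degenerate trip: fewer than 2 points")
  trip <- trip[order(trip$time), ]
  d <- gc_dist_km(trip$lon[1], trip$lat[1], trip$lon, trip$lat)
  far <- which(d == max(d))[1]
  az <- gc_bearing_deg(trip$lon[1], trip$lat[1], trip$lon[far], trip$lat[far])
  data.frame(azimuth_deg = az,
             cos_azimuth = cos(az * pi / 180),
             sin_azimuth = sin(az * pi / 180),
             max_distance_km = if (complete) max(d) else NA_real_,
             duration_days = if (complete)
               as.numeric(difftime(trip$time[nrow(trip)], trip$time[1],
                                   units = "days")) else NA_real_,
             complete = complete)
}

#' Rayleigh test of circular uniformity for trip azimuths
#'
#' Mean resultant length R-bar and the standard large-sample approximation
#' p = exp(sqrt(1 + 4n + 4(n^2 - n R^2)) - (1 + 2n)) with R = n * R-bar.
#'
#' @param azimuth_deg vector of azimuths in degrees
#' @return list: r_bar, p_value, n
#' @export
rayleigh_test <- function(azimuth_deg) {
  n <- length(azimuth_deg)
  if (n < 3) stop("need at least 3 azimuths")
  a <- azimuth_deg * pi / 180
  r_bar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  R <- n * r_bar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(r_bar = r_bar, p_value = min(p, 1), n = n)
}

#' Wilcoxon-Mann-Whitney comparison of two groups
#'
#' Exact two-sided test for small untied samples (total n <= 20), normal
#' approximation with tie correction otherwise.
#'
#' @param values_a,values_b numeric vectors
#' @return list: statistic (U), p_value, method
#' @export
group_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  ties <- any(duplicated(c(values_a, values_b)))
  if (ties && length(unique(c(values_a, values_b))) == 1) {
    warning("all values tied across both groups")
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1, method = "degenerate"))
  }
  exact <- (length(values_a) + length(values_b)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Dive behaviour on flagged foraging days
#'
#' For days flagged as important foraging days (high FPT), reports the daily
#' mean maximum dive depth and its ratio to the daily mean bathymetry (a
#' benthic-vs-pelagic indicator; ratios > 1 are flagged as inconsistent and
#' reported capped). Days with missing or non-positive bathymetry are
#' skipped.
#'
#' @param daily_depth from [daily_mean_max_depth()]
#' @param daily_environment from [daily_env()]
#' @param flags data.frame with animal_id, day, foraging (from
#'   [foraging_days()])
#' @return data.frame: animal_id, day, mean_max_depth, bathymetry_m,
#'   depth_over_bathymetry, inconsistent
#' @export
foraging_dive_behavior <- function(daily_depth, daily_environment, flags) {
  f <- flags[flags$foraging, c("animal_id", "day")]
  x <- merge(f, daily_depth, by = c("animal_id", "day"))
  x <- merge(x, daily_environment[, c("animal_id", "day", "bathymetry_m")],
             by = c("animal_id", "day"))
  bad <- !is.finite(x$bathymetry_m) | x$bathymetry_m <= 0
  if (any(bad)) message(sum(bad), " foraging day(s) skipped: missing bathymetry")
  x <- x[!bad, ]
  ratio <- x$mean_max_depth / x$bathymetry_m
  x$depth_over_bathymetry <- pmin(ratio, 1)
  x$inconsistent <- ratio > 1
  x[, c("animal_id", "day", "mean_max_depth", "bathymetry_m",
        "depth_over_bathymetry", "inconsistent")]
}
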