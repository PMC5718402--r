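# Per-dive processing of compressed 6-point time-depth profiles: descent and
# ascent transit rates, dive geolocation along the smoothed track, and the
# daily mean maximum dive depth.

# extract the 6-point profile of one dive row as a (time_s, depth_m) matrix
.dive_profile <- function(dive) {
  cbind(t = as.numeric(dive[paste0("t", 0:5, "_s")]),
        d = as.numeric(dive[paste0("d", 0:5, "_m")]))
}

#' Descent/ascent transit rates and mean transit depth per dive
#'
#' The descent rate is the depth/time ratio over the first profile leg (start
#' point to first at-depth point); the ascent rate likewise over the last leg,
#' sign-flipped so that positive means upward. The mean transit depth is the
#' mean of the depth where the descent ended and the depth where the ascent
#' began; it drives the shallow-dive weighting of the foraging index. Dives
#' with a zero-duration leg or with a descent leg that goes upward are
#' excluded with a message.
#'
#' @param dives dive table with profile columns `t0_s..t5_s`, `d0_m..d5_m`
#' @return data.frame: dive_id, descent_rate, ascent_rate (m/s, both
#'   positive), mean_transit_depth (m)
#' @export
compute_transit_rates <- function(dives) {
  t1 <- dives$t1_s - dives$t0_s
  t5 <- dives$t5_s - dives$t4_s
  desc <- (dives$d1_m - dives$d0_m) / t1
  asc <- -(dives$d5_m - dives$d4_m) / t5
  ok <- t1 > 0 & t5 > 0 & desc >= 0 & asc >= 0
  if (any(!ok))
    message(sum(!ok), " dive(s) excluded (zero-duration or inverted transit leg)")
  data.frame(dive_id = dives$dive_id[ok],
             descent_rate = desc[ok], ascent_rate = asc[ok],
             mean_transit_depth = (dives$d1_m[ok] + dives$d4_m[ok]) / 2)
}

#' Geolocate dives by linear interpolation along the smoothed track
#'
#' The dive position is anchored at the dive start time, interpolated along
#' the great circle between the bracketing track points. Dives outside the
#' track's time span are dropped with a message.
#'
#' @param dives dive table with start_time
#' @param track TrackPoints (animal_id, time, lon, lat)
#' @return dives with lon/lat replaced by interpolated positions
#' @export
geolocate_dives <- function(dives, track) {
  if (is.null(track) || nrow(track) == 0) stop("empty track")
  out <- list()
  for (id in unique(dives$animal_id)) {
    dv <- dives[dives$animal_id == id, ]
    tr <- track[track$animal_id == id, ]
    tr <- tr[order(tr$time), ]
    tt <- as.numeric(tr$time)
    ts <- as.numeric(dv$start_time)
    inside <- ts >= tt[1] & ts <= tt[length(tt)]
    if (any(!inside))
      message(sum(!inside), " dive(s) for ", id, " outside track span; dropped")
    dv <- dv[inside, ]
    if (!nrow(dv)) next
    ts <- as.numeric(dv$start_time)
    i <- pmin(pmax(findInterval(ts, tt), 1), length(tt) - 1)
    f <- (ts - tt[i]) / pmax(tt[i + 1] - tt[i], 1e-9)
    p <- gc_interpolate(tr$lon[i], tr$lat[i], tr$lon[i + 1], tr$lat[i + 1],
                        pmin(pmax(f, 0), 1))
    dv$lon <- norm_lon(p[, "lon"]); dv$lat <- p[, "lat"]
    out[[id]] <- dv
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Daily mean maximum dive depth per animal UTC day
#'
#' @param dives dive table with animal_id, start_time, max_depth
#' @return data.frame: animal_id, day (Date), mean_max_depth (m), n_dives
#' @export
daily_mean_max_depth <- function(dives) {
  day <- as.Date(dives$start_time, tz = "UTC")
  agg <- stats::aggregate(dives$max_depth,
                          by = list(animal_id = dives$animal_id, day = day),
                          FUN = mean)
  names(agg)[3] <- "mean_max_depth"
  cnt <- stats::aggregate(dives$max_depth,
                          by = list(animal_id = dives$animal_id, day = day),
                          FUN = length)
  agg$n_dives <- cnt$x
  agg[order(agg$animal_id, agg$day), ]
}
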