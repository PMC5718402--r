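# First passage time (FPT) analysis: the time an animal takes to cross a
# circle of radius r centred on each track point. Slow, tortuous movement
# (area-restricted search) yields large FPT. Tracks are first resampled to
# equidistant points along the path so that FPT is not biased by the higher
# fix density in slow-moving areas; the ARS scale is the radius maximizing
# the across-track FPT variance.

#' Resample a track to equidistant points along the path
#'
#' Points are placed at cumulative great-circle distance multiples of
#' `spacing_km` along the track-line; timestamps are interpolated linearly
#' within each original segment.
#'
#' @param trip data.frame with time, lon, lat (one animal/trip, time-ordered)
#' @param spacing_km spacing along the path, km
#' @return data.frame: time, lon, lat, cumdist_km
#' @export
resample_track_equidistant <- function(trip, spacing_km = 5) {
  if (nrow(trip) < 2) stop("trip needs at least 2 points")
  trip <- trip[order(trip$time), ]
  n <- nrow(trip)
  seg <- gc_dist_km(trip$lon[-n], trip$lat[-n], trip$lon[-1], trip$lat[-1])
  cum <- c(0, cumsum(seg))
  total <- cum[n]
  if (total < spacing_km) {
    message("trip shorter than one spacing interval; single point returned")
    return(data.frame(time = trip$time[1], lon = trip$lon[1],
                      lat = trip$lat[1], cumdist_km = 0))
  }
  targets <- seq(0, total, by = spacing_km)
  i <- pmin(pmax(findInterval(targets, cum, rightmost.closed = TRUE), 1), n - 1)
  f <- (targets - cum[i]) / pmax(seg[i], 1e-12)
  f <- pmin(pmax(f, 0), 1)
  p <- gc_interpolate(trip$lon[i], trip$lat[i], trip$lon[i + 1], trip$lat[i + 1], f)
  tt <- as.numeric(trip$time)
  data.frame(time = as.POSIXct(tt[i] + f * (tt[i + 1] - tt[i]),
                               origin = "1970-01-01", tz = "UTC"),
             lon = norm_lon(p[, "lon"]), lat = p[, "lat"], cumdist_km = targets)
}

# pairwise great-circle distance matrix (km) for resampled points
.dist_matrix <- function(points) {
  n <- nrow(points)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- gc_dist_km(points$lon[i], points$lat[i], points$lon[j], points$lat[j])
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

# FPT at each point for one radius given the distance matrix and times (hr).
# Crossing instants are linearly interpolated on the crossing segment; points
# where the circle is never exited forward or backward get NA.
.fpt_radius <- function(D, t_hr, r) {
  n <- length(t_hr)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    di <- D[i, ]
    fwd <- which(di[i:n] > r)
    bwd <- which(di[1:i] > r)
    if (!length(fwd) || !length(bwd)) next
    j <- i + fwd[1] - 1                         # first point beyond r forward
    k <- bwd[length(bwd)]                       # last point beyond r backward
    fj <- (r - di[j - 1]) / (di[j] - di[j - 1])
    t_exit <- t_hr[j - 1] + fj * (t_hr[j] - t_hr[j - 1])
    fk <- (r - di[k + 1]) / (di[k] - di[k + 1])
    t_entry <- t_hr[k + 1] - fk * (t_hr[k + 1] - t_hr[k])
    out[i] <- t_exit - t_entry
  }
  out
}

#' First passage time at one radius
#'
#' @param points equidistant points from [resample_track_equidistant()]
#' @param r_km circle radius, km
#' @return numeric vector of FPT in hours (NA where undefined at track ends)
#' @export
fpt_at_radius <- function(points, r_km) {
  if (r_km <= 0) stop("radius must be positive")
  .fpt_radius(.dist_matrix(points), as.numeric(points$time) / 3600, r_km)
}

#' FPT profiles over a set of radii (shared distance matrix)
#'
#' @param points equidistant points
#' @param radii_km vector of radii, km
#' @return matrix `length(radii) x nrow(points)` of FPT hours
#' @export
fpt_profile <- function(points, radii_km) {
  D <- .dist_matrix(points)
  t_hr <- as.numeric(points$time) / 3600
  t(vapply(radii_km, function(r) .fpt_radius(D, t_hr, r),
           numeric(nrow(points))))
}

#' Select the area-restricted-search scale by FPT variance maximization
#'
#' Computes the variance of FPT (and of log FPT) across all points of all
#' supplied trips at each tested radius and selects the radius maximizing the
#' chosen variance. The default maximizes the variance of log FPT, the form
#' used by the method's originators: raw FPT variance grows monotonically
#' with radius on directed tracks (both curves are always reported, and the
#' raw basis is available as a switch). A flat variance curve (straight-line
#' movement) is flagged as non-informative.
#'
#' @param trips list of equidistant point data.frames (one per trip)
#' @param radii_km candidate radii, km
#' @param on "log" (default) to maximize var(log FPT), "raw" for var(FPT)
#' @return list: selected_radius_km, variance_curve (data.frame radius,
#'   var_fpt, var_log_fpt, n), informative (logical)
#' @export
select_ars_scale <- function(trips, radii_km = 5:100, on = c("log", "raw")) {
  on <- match.arg(on)
  if (is.data.frame(trips)) trips <- list(trips)
  if (!length(trips)) stop("at least one trip required")
  mats <- lapply(trips, function(tr) fpt_profile(tr, radii_km))
  all_fpt <- do.call(cbind, mats)
  var_fpt <- apply(all_fpt, 1, stats::var, na.rm = TRUE)
  var_log <- apply(log(all_fpt), 1, stats::var, na.rm = TRUE)
  nn <- apply(all_fpt, 1, function(x) sum(!is.na(x)))
  curve <- data.frame(radius_km = radii_km, var_fpt = var_fpt,
                      var_log_fpt = var_log, n = nn)
  usable <- which(nn >= 2 & is.finite(if (on == "raw") var_fpt else var_log))
  if (!length(usable)) stop("no radius had enough defined FPT values")
  v <- if (on == "raw") var_fpt else var_log
  sel <- usable[which.max(v[usable])]
  vr <- range(v[usable])
  informative <- (vr[2] - vr[1]) > 1e-8 * max(vr[2], 1)
  if (!informative)
    message("FPT variance curve is flat; scale selection is non-informative")
  list(selected_radius_km = radii_km[sel], variance_curve = curve,
       informative = informative)
}

#' Remove FPT points biased by haul-out proximity
#'
#' Points closer than the ARS scale to any haul-out position are removed:
#' their large FPT reflects time on the ice, not search effort.
#'
#' @param fpt_points data.frame with lon, lat (+ fpt columns)
#' @param haulout_positions data.frame with lon, lat (may be empty)
#' @param scale_km exclusion radius, km
#' @return filtered fpt_points
#' @export
exclude_haulout_fpt <- function(fpt_points, haulout_positions, scale_km) {
  if (is.null(haulout_positions) || nrow(haulout_positions) == 0)
    return(fpt_points)
  keep <- rep(TRUE, nrow(fpt_points))
  for (k in seq_len(nrow(haulout_positions)))
    keep <- keep & gc_dist_km(fpt_points$lon, fpt_points$lat,
                              haulout_positions$lon[k],
                              haulout_positions$lat[k]) >= scale_km
  fpt_points[keep, ]
}

#' Daily mean FPT per animal UTC day
#'
#' @param fpt_points data.frame with animal_id, time, fpt_hr
#' @return data.frame: animal_id, day, mean_fpt_hr, n_points
#' @export
daily_fpt <- function(fpt_points) {
  pts <- fpt_points[!is.na(fpt_points$fpt_hr), ]
  day <- as.Date(pts$time, tz = "UTC")
  agg <- stats::aggregate(pts$fpt_hr,
                          by = list(animal_id = pts$animal_id, day = day),
                          FUN = mean)
  names(agg)[3] <- "mean_fpt_hr"
  cnt <- stats::aggregate(pts$fpt_hr,
                          by = list(animal_id = pts$animal_id, day = day),
                          FUN = length)
  agg$n_points <- cnt$x
  agg[order(agg$animal_id, agg$day), ]
}

#' Flag high-FPT foraging days
#'
#' A day is flagged as an important foraging day when its mean FPT strictly
#' exceeds the empirical `q` quantile (type 7) over the supplied pooling
#' scope.
#'
#' @param daily data.frame from [daily_fpt()]
#' @param q quantile level
#' @return `daily` with a logical `foraging` column; attribute `threshold`
#' @export
foraging_days <- function(daily, q = 0.75) {
  if (nrow(daily) < 4) stop("need at least 4 daily FPT values")
  thr <- stats::quantile(daily$mean_fpt_hr, q, type = 7, names = FALSE)
  daily$foraging <- daily$mean_fpt_hr > thr
  attr(daily, "threshold") <- thr
  daily
}
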