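# Season and trip segmentation. Records start in the breeding period (tags
# are deployed at breeding): the post-breeding season runs from record start
# until the onset of the molt (adults: the first haul-out after the molt rule
# date; pups, which do not molt in their first year, switch at the first
# haul-out after June 15), and the post-molting season runs from then until
# the first haul-out after February 15 of the following year.

#' Label track points with a season
#'
#' @param track TrackPoints for one animal (animal_id, time, ...)
#' @param class "pup", "female" or "male"
#' @param haulouts data.frame (animal_id, start, end)
#' @param molt_date month-day string for the adult molt rule date
#' @param pup_date month-day string for the pup season switch rule date
#' @param breeding_date month-day string ending the post-molting season
#' @return `track` with a `season` column; attribute `season_flags` lists
#'   boundaries that fell back to the record end because no qualifying
#'   haul-out existed.
#' @export
segment_seasons <- function(track, class, haulouts,
                            molt_date = "07-01", pup_date = "06-15",
                            breeding_date = "02-15") {
  stopifnot(length(unique(track$animal_id)) == 1)
  id <- track$animal_id[1]
  ho <- haulouts[haulouts$animal_id == id, ]
  ho <- ho[order(ho$start), ]
  t0 <- min(track$time); t_end <- max(track$time)
  yr <- as.integer(format(t0, "%Y"))
  rule1 <- as.POSIXct(paste0(yr, "-", if (class == "pup") pup_date else molt_date),
                      tz = "UTC")
  if (rule1 < t0) rule1 <- as.POSIXct(paste0(yr + 1, "-", if (class == "pup") pup_date else molt_date), tz = "UTC")
  flags <- character()
  first_ho_after <- function(when) {
    cand <- ho$start[ho$start > when]
    if (length(cand)) cand[1] else NA
  }
  b1 <- first_ho_after(rule1)
  if (is.na(b1) || b1 > t_end) {
    b1 <- t_end
    flags <- c(flags, "post_breeding end fell back to record end")
  }
  rule2 <- as.POSIXct(paste0(yr + 1, "-", breeding_date), tz = "UTC")
  b2 <- first_ho_after(rule2)
  if (is.na(b2) || b2 > t_end) {
    b2 <- t_end
    if (b1 < t_end) flags <- c(flags, "post_molting end fell back to record end")
  }
  season <- ifelse(track$time <= b1, "post_breeding",
                   ifelse(track$time <= b2, "post_molting", "post_breeding"))
  track$season <- season
  attr(track, "season_flags") <- flags
  attr(track, "season_boundaries") <- c(post_breeding_end = b1,
                                        post_molting_end = b2)
  track
}

#' Segment a season-labelled track into foraging trips
#'
#' Adult trips are maximal excursions beyond `threshold_km` of the deployment
#' centre: a trip starts at the last exit from the disc and ends at the next
#' re-entry (complete) or at the record end (incomplete). Pup trips are
#' delimited by the season boundaries regardless of the disc, since pups need
#' not return to the traditional breeding/molting areas.
#'
#' @param track season-labelled TrackPoints for one animal
#' @param class "pup", "female" or "male"
#' @param center lon/lat of the mean deployment point
#' @param threshold_km trip disc radius, km
#' @return list with `points` (track plus `trip_id`, NA off-trip) and
#'   `trips` (trip_id, animal_id, class, season, complete, start_time,
#'   end_time, n_points)
#' @export
segment_trips <- function(track, class, center = c(lon = 13.50, lat = 73.86),
                          threshold_km = 250) {
  stopifnot(length(unique(track$animal_id)) == 1)
  id <- track$animal_id[1]
  track <- track[order(track$time), ]
  n <- nrow(track)
  trip_id <- rep(NA_character_, n)
  trips <- list()
  if (class == "pup") {
    key <- track$season
    brk <- c(1, which(key[-1] != key[-n]) + 1, n + 1)
    k <- 0
    for (j in seq_len(length(brk) - 1)) {
      i <- brk[j]:(brk[j + 1] - 1)
      if (length(i) < 2) next
      k <- k + 1
      tid <- sprintf("%s_t%02d", id, k)
      trip_id[i] <- tid
      trips[[k]] <- data.frame(trip_id = tid, animal_id = id, class = class,
                               season = key[i[1]],
                               complete = brk[j + 1] <= n,
                               start_time = track$time[i[1]],
                               end_time = track$time[i[length(i)]],
                               n_points = length(i))
    }
  } else {
    d <- gc_dist_km(track$lon, track$lat, center[["lon"]], center[["lat"]])
    outside <- d > threshold_km
    if (!any(outside)) {
      message("animal ", id, " never left the ", threshold_km, " km disc; no trips")
      return(list(points = cbind(track, trip_id = trip_id),
                  trips = data.frame()))
    }
    r <- rle(outside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    k <- 0
    for (j in which(r$values)) {
      i <- starts[j]:ends[j]
      if (length(i) < 2) next
      k <- k + 1
      tid <- sprintf("%s_t%02d", id, k)
      trip_id[i] <- tid
      season <- names(which.max(table(track$season[i])))
      trips[[k]] <- data.frame(trip_id = tid, animal_id = id, class = class,
                               season = season,
                               complete = ends[j] < n,
                               start_time = track$time[i[1]],
                               end_time = track$time[i[length(i)]],
                               n_points = length(i))
    }
  }
  list(points = cbind(track, trip_id = trip_id),
       trips = do.call(rbind, c(trips, list(make.row.names = FALSE))))
}
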