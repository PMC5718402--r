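# Per-dive environmental covariates: gridded bathymetry and ice at the dive
# position, SST from the shallowest CTD point (nominally 6 m) with time-
# linear interpolation between casts when a dive has no nearby cast, and
# daily means of everything.

#' Assign an SST value to every dive from CTD casts
#'
#' Dives within `window_hr` of a cast take that cast's shallowest-point
#' temperature directly (`sst_source = "ctd"`); other dives take a
#' time-linear interpolation between the bracketing casts' shallowest-point
#' temperatures (`"interpolated"`); dives beyond the first/last cast take the
#' nearest cast's value (`"extrapolated"`). Animals with no casts get NA with
#' a warning.
#'
#' @param dives dive table (dive_id, animal_id, start_time)
#' @param ctd long CTD table from [simulate_ctd()] or equivalent
#'   (profile_id, animal_id, time, depth_m, temp_C)
#' @param window_hr direct-assignment window, hours
#' @return data.frame: dive_id, sst_C, sst_source
#' @export
sst_per_dive <- function(dives, ctd, window_hr = 3) {
  out <- data.frame(dive_id = dives$dive_id, sst_C = NA_real_,
                    sst_source = NA_character_)
  for (id in unique(dives$animal_id)) {
    di <- which(dives$animal_id == id)
    pr <- ctd[ctd$animal_id == id, ]
    if (!nrow(pr)) {
      warning("no CTD casts for ", id, "; SST missing")
      out$sst_source[di] <- "missing"
      next
    }
    shal <- do.call(rbind, lapply(split(pr, pr$profile_id), function(p)
      p[which.min(p$depth_m), c("time", "temp_C")]))
    shal <- shal[order(shal$time), ]
    pt <- as.numeric(shal$time)
    dt <- as.numeric(dives$start_time[di])
    near_i <- vapply(dt, function(t) which.min(abs(pt - t)), integer(1))
    near_gap <- abs(pt[near_i] - dt) / 3600
    direct <- near_gap <= window_hr
    sst <- rep(NA_real_, length(dt))
    src <- rep(NA_character_, length(dt))
    sst[direct] <- shal$temp_C[near_i[direct]]
    src[direct] <- "ctd"
    todo <- which(!direct)
    if (length(todo)) {
      inside <- dt[todo] >= pt[1] & dt[todo] <= pt[length(pt)]
      ii <- todo[inside]
      if (length(ii)) {
        sst[ii] <- stats::approx(pt, shal$temp_C, dt[ii])$y
        src[ii] <- "interpolated"
      }
      oo <- todo[!inside]
      if (length(oo)) {
        sst[oo] <- shal$temp_C[near_i[oo]]
        src[oo] <- "extrapolated"
      }
    }
    out$sst_C[di] <- sst
    out$sst_source[di] <- src
  }
  out
}

#' Assemble per-dive environmental covariates
#'
#' @param dives geolocated dive table (dive_id, animal_id, start_time, lon,
#'   lat)
#' @param env list of [env_grid()]s with `bathymetry`, `ice` (others ignored)
#' @param ctd long CTD table
#' @param window_hr passed to [sst_per_dive()]
#' @return data.frame: dive_id, animal_id, day, bathymetry_m, ice_fraction,
#'   sst_C, sst_source
#' @export
dive_env <- function(dives, env, ctd, window_hr = 3) {
  date <- as.Date(dives$start_time, tz = "UTC")
  sst <- sst_per_dive(dives, ctd, window_hr = window_hr)
  data.frame(dive_id = dives$dive_id, animal_id = dives$animal_id, day = date,
             bathymetry_m = env_lookup(env$bathymetry, dives$lon, dives$lat),
             ice_fraction = env_lookup(env$ice, dives$lon, dives$lat,
                                       date = date),
             sst_C = sst$sst_C, sst_source = sst$sst_source)
}

#' Daily means of the per-dive environmental covariates
#'
#' @param denv from [dive_env()]
#' @return data.frame: animal_id, day, bathymetry_m, ice_fraction, sst_C
#' @export
daily_env <- function(denv) {
  agg <- function(v) {
    a <- stats::aggregate(denv[[v]],
                          by = list(animal_id = denv$animal_id, day = denv$day),
                          FUN = mean, na.rm = TRUE)
    names(a)[3] <- v
    a
  }
  out <- Reduce(function(a, b) merge(a, b, by = c("animal_id", "day")),
                lapply(c("bathymetry_m", "ice_fraction", "sst_C"), agg))
  out$sst_C[is.nan(out$sst_C)] <- NA
  out[order(out$animal_id, out$day), ]
}
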