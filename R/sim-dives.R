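# Simulated compressed dive records and CTD casts. Each dive is transmitted
# as a 6-point time-depth profile (start and end at the surface plus four
# at-depth inflection points) with maximum depth, duration and post-dive
# surface time, mirroring on-board SRDL compression. A configurable fraction
# of dives contain a passive drift segment whose vertical rate follows the
# animal's true body-condition trajectory.

# class-conditional dive envelopes (median / log-IQR spread on a lognormal),
# spanning typical pup vs adult dive depth and duration distributions
.dive_pars <- list(
  pup    = list(depth = c(mlog = log(75),  slog = 0.80), dur = c(mlog = log(4.5 * 60), slog = 0.70), surf = 62),
  female = list(depth = c(mlog = log(231), slog = 0.55), dur = c(mlog = log(12 * 60),  slog = 0.38), surf = 100),
  male   = list(depth = c(mlog = log(251), slog = 0.60), dur = c(mlog = log(13 * 60),  slog = 0.40), surf = 95))

#' Simulate compressed dive records along simulated tracks
#'
#' @param sim result of [simulate_track()]
#' @param env environmental fields from [make_synthetic_env()] (bathymetry
#'   caps dive depth)
#' @param config a [sim_config()]; defaults to the one stored in `sim`
#' @return list with `dives` (one row per dive: 6-point profile in wide
#'   columns `t0_s..t5_s` / `d0_m..d5_m`, summary metrics, true position) and
#'   `labels` (ground truth per dive: `is_drift`, `true_rate`, `in_patch`).
#' @export
simulate_dives <- function(sim, env = make_synthetic_env(), config = sim$config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 1000003L) %% .Machine$integer.max)
  out <- list(); labs <- list(); n_rejected <- 0L
  for (id in unique(sim$truth$latent$animal_id)) {
    lat_path <- sim$truth$latent[sim$truth$latent$animal_id == id, ]
    cls <- sim$truth$classes[[id]]
    pars <- .dive_pars[[cls]]
    cond <- sim$truth$condition[sim$truth$condition$animal_id == id, ]
    tt <- as.numeric(lat_path$time)
    starts <- seq(tt[1], tt[length(tt)] - 3600, by = config$dive_interval_min * 60)
    # no diving while hauled out
    ho <- sim$truth$haulouts[sim$truth$haulouts$animal_id == id, ]
    at_sea <- rep(TRUE, length(starts))
    if (nrow(ho))
      for (k in seq_len(nrow(ho)))
        at_sea <- at_sea & !(starts >= as.numeric(ho$start[k]) &
                             starts <= as.numeric(ho$end[k]))
    starts <- starts[at_sea]
    if (!length(starts)) next
    lon <- stats::approx(tt, lat_path$lon, starts)$y
    lat <- stats::approx(tt, lat_path$lat, starts)$y
    idx <- findInterval(starts, tt)
    in_patch <- lat_path$mode[pmax(idx, 1)] == "ars"
    bathy <- env_lookup(env$bathymetry, lon, lat)
    day <- as.Date(as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
                   tz = "UTC")
    rate_day <- cond$rate[match(day, cond$day)]

    n <- length(starts)
    rec <- vector("list", n)
    for (k in seq_len(n)) {
      blim <- max(config$min_depth_m + 10, bathy[k] - 5)
      D <- stats::rlnorm(1, pars$depth["mlog"], pars$depth["slog"])
      if (D > blim) { D <- stats::rlnorm(1, pars$depth["mlog"], pars$depth["slog"]); n_rejected <- n_rejected + 1L }
      D <- min(max(D, config$min_depth_m), blim)
      T_s <- max(90, stats::rlnorm(1, pars$dur["mlog"], pars$dur["slog"]))
      surf <- max(20, stats::rnorm(1, pars$surf, pars$surf / 5))
      boost <- if (in_patch[k]) 1 else 0  # 1-SD transit-rate elevation in ARS
      rd <- stats::rlnorm(1, log(0.9) + boost * 0.25, 0.25)
      ra <- stats::rlnorm(1, log(0.85) + boost * 0.25, 0.25)
      u <- stats::runif(1)
      is_drift <- FALSE; true_rate <- NA_real_
      if (u < config$drift_dive_prob && !is.na(rate_day[k])) {
        rate <- rate_day[k] + stats::rnorm(1, 0, config$drift_noise_sd)
        T_s <- max(T_s, 600)
        gf <- stats::runif(1, 0.35, 0.45)
        need <- abs(rate) * gf * T_s
        if (blim > config$min_depth_m + need + 30) {
          is_drift <- TRUE; true_rate <- rate
          Dd <- min(max(D, config$min_depth_m + need + 30), blim)
          if (rate <= 0) { ds <- Dd - need } else { ds <- Dd }
          ts <- c(0, 0.12, 0.14, 0.14 + gf, 0.16 + gf, 1) * T_s
          dd <- c(0, ds, ds, 0, 0, 0)
          # drift moves depth opposite to the signed rate (negative = sinking
          # = depth increasing)
          dd[4] <- ds - rate * gf * T_s
          dd[5] <- dd[4] * stats::runif(1, 0.95, 1)
          rec[[k]] <- list(ts = ts, dd = dd, D = max(dd) + stats::runif(1, 0, 3),
                           T_s = T_s, surf = surf)
        }
      }
      if (!is_drift && u < config$drift_dive_prob + config$glide_prob) {
        # hard negative: active glide with a long, gently sloped mid-segment
        gf <- stats::runif(1, 0.32, 0.42)
        s <- stats::runif(1, 0.05, 0.45) * sample(c(-1, 1), 1)
        d2 <- D * stats::runif(1, 0.9, 1)
        d3 <- min(max(d2 - s * gf * T_s, config$min_depth_m), blim)
        ts <- c(0, 0.10, 0.18, 0.18 + gf, 0.88, 1) * T_s
        dd <- c(0, D * stats::runif(1, 0.9, 1), d2, d3,
                d3 * stats::runif(1, 0.75, 0.95), 0)
        rec[[k]] <- list(ts = ts, dd = dd, D = max(dd) + stats::runif(1, 0, 3),
                         T_s = T_s, surf = surf, glide = TRUE)
      } else if (!is_drift) {
        # U-shaped dive; transit legs set by descent/ascent rates
        d1 <- D * stats::runif(1, 0.92, 1)
        d4 <- D * stats::runif(1, 0.88, 1)
        t1 <- min(d1 / rd, 0.33 * T_s)
        t_asc <- min(d4 / ra, 0.33 * T_s)
        t4 <- T_s - t_asc
        ts <- c(0, t1, t1 + (t4 - t1) / 3, t1 + 2 * (t4 - t1) / 3, t4, T_s)
        dd <- c(0, d1, D * stats::runif(1, 0.9, 1), D * stats::runif(1, 0.9, 1),
                d4, 0)
        rec[[k]] <- list(ts = ts, dd = dd, D = max(dd) + stats::runif(1, 0, 3),
                         T_s = T_s, surf = surf)
      }
      rec[[k]]$is_drift <- is_drift
      rec[[k]]$true_rate <- true_rate
    }
    keep <- !vapply(rec, is.null, logical(1))
    rec <- rec[keep]
    if (!length(rec)) next
    ts <- t(vapply(rec, function(r) r$ts, numeric(6)))
    dd <- t(vapply(rec, function(r) r$dd, numeric(6)))
    df <- data.frame(animal_id = id, class = cls,
                     start_time = as.POSIXct(starts[keep],
                                             origin = "1970-01-01", tz = "UTC"),
                     duration_s = vapply(rec, function(r) r$T_s, numeric(1)),
                     surface_s = vapply(rec, function(r) r$surf, numeric(1)),
                     max_depth = vapply(rec, function(r) r$D, numeric(1)),
                     lon = lon[keep], lat = lat[keep])
    df$end_time <- df$start_time + df$duration_s
    colnames(ts) <- paste0("t", 0:5, "_s"); colnames(dd) <- paste0("d", 0:5, "_m")
    df <- cbind(df, ts, dd)
    lab <- data.frame(animal_id = id,
                      is_drift = vapply(rec, function(r) r$is_drift, logical(1)),
                      true_rate = vapply(rec, function(r) r$true_rate, numeric(1)),
                      in_patch = in_patch[keep])
    out[[id]] <- df; labs[[id]] <- lab
  }
  if (n_rejected > 0)
    warning(n_rejected, " dive depth draw(s) exceeded local bathymetry and were resampled")
  dives <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  labels <- do.call(rbind, c(labs, list(make.row.names = FALSE)))
  dives$dive_id <- sprintf("%s_d%05d", dives$animal_id,
                           stats::ave(seq_len(nrow(dives)), dives$animal_id,
                                      FUN = seq_along))
  labels$dive_id <- dives$dive_id
  list(dives = dives, labels = labels)
}

#' Simulate CTD casts (one 17-point profile per 6-hour window)
#'
#' The shallowest point sits at 6 m and carries the SST field value at the
#' cast position/date plus observation noise; temperature relaxes toward a
#' deep-water value with depth.
#'
#' @param sim result of [simulate_track()]
#' @param env fields from [make_synthetic_env()]
#' @param config a [sim_config()]
#' @param noise_sd SD of the 6 m temperature noise, degrees C
#' @return data.frame with one row per (profile, depth point): profile_id,
#'   animal_id, time, lon, lat, depth_m, temp_C, cond_mS
#' @export
simulate_ctd <- function(sim, env = make_synthetic_env(), config = sim$config,
                         noise_sd = 0.1) {
  set.seed((config$seed + 2000003L) %% .Machine$integer.max)
  out <- list()
  for (id in unique(sim$truth$latent$animal_id)) {
    lat_path <- sim$truth$latent[sim$truth$latent$animal_id == id, ]
    tt <- as.numeric(lat_path$time)
    span <- tt[length(tt)] - tt[1]
    n_win <- floor(span / (6 * 3600))
    if (n_win < 1) next
    wt <- tt[1] + (seq_len(n_win) - 1) * 6 * 3600 + 3 * 3600
    lon <- stats::approx(tt, lat_path$lon, wt)$y
    lat <- stats::approx(tt, lat_path$lat, wt)$y
    when <- as.POSIXct(wt, origin = "1970-01-01", tz = "UTC")
    bathy <- env_lookup(env$bathymetry, lon, lat)
    sst <- env_lookup(env$sst, lon, lat, date = as.Date(when, tz = "UTC"))
    for (k in seq_len(n_win)) {
      zmax <- max(20, min(bathy[k] - 2, 500))
      z <- seq(6, zmax, length.out = 17)
      t6 <- sst[k] + stats::rnorm(1, 0, noise_sd)
      temp <- -0.5 + (t6 + 0.5) * exp(-(z - 6) / 150)
      out[[length(out) + 1]] <- data.frame(
        profile_id = sprintf("%s_c%04d", id, k), animal_id = id,
        time = when[k], lon = lon[k], lat = lat[k], depth_m = z,
        temp_C = temp, cond_mS = 28 + 0.01 * z + stats::rnorm(17, 0, 0.05))
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
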