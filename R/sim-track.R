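# Mechanistic track simulator: a correlated random walk that alternates
# directed transit with slow, tortuous area-restricted search (ARS) inside
# prey patches, returning to haul out at the colony between trips. Behaviour
# is simulated mechanistically (speed / turning-angle switch), so downstream
# ARS detection is a genuine inference problem rather than a label lookup.

#' Simulate Argos tracks with known ground truth
#'
#' @param config a [sim_config()]
#' @return list with `fixes` (data.frame: animal_id, time, lon, lat, lc) and
#'   `truth` (latent path with behavioural mode, haul-out intervals, patch
#'   geometry, per-fix artifact labels, per-animal class, and the true daily
#'   drift-rate trajectory used by [simulate_dives()]).
#' @export
simulate_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_steps <- floor(config$duration_days * 24 / config$fix_interval_hr)
  if (n_steps < 2) stop("invalid config: requested track has fewer than 2 fixes")
  set.seed(config$seed)

  classes <- rep(names(config$class_mix),
                 diff(round(cumsum(c(0, config$class_mix)) * config$n_animals)))
  classes <- rep_len(c(classes, names(config$class_mix)[1]), config$n_animals)
  ids <- sprintf("seal%02d", seq_len(config$n_animals))
  names(classes) <- ids

  dt_hr <- config$fix_interval_hr
  step_transit <- config$transit_speed_ms * 3.6 * dt_hr       # km per step
  step_ars <- step_transit * 0.6   # extra dwell comes from tortuosity + time
  crossing_days <- 2 * config$patch_radius_km /
    (config$transit_speed_ms * 3.6 * 24)
  ars_days <- config$patch_dwell_factor * crossing_days
  ctr <- config$deployment_center
  patches <- config$patch_centers
  lc_names <- names(config$lc_probs)
  lc_p <- config$lc_probs / sum(config$lc_probs)

  fixes <- list(); latent <- list(); haulouts <- list(); condition <- list()
  for (a in seq_along(ids)) {
    id <- ids[a]
    times <- config$t0 + (seq_len(n_steps) - 1) * dt_hr * 3600
    lon <- lat <- numeric(n_steps)
    mode <- character(n_steps); patch_idx <- rep(NA_integer_, n_steps)
    lon[1] <- ctr[["lon"]] + stats::rnorm(1, 0, 0.05)
    lat[1] <- ctr[["lat"]] + stats::rnorm(1, 0, 0.02)
    heading <- stats::runif(1, 90, 200)  # southeasterly departure bias
    state <- "haulout"
    state_until <- config$t0 + config$haulout_days * 86400 * stats::runif(1, 0.3, 1)
    target <- 1 + (a - 1) %% nrow(patches)
    mode[1] <- state
    rate <- -0.25  # body-condition trajectory state (m/s, negative = sinking)
    rate_step <- numeric(n_steps); rate_step[1] <- rate
    for (i in 2:n_steps) {
      d_home <- gc_dist_km(lon[i - 1], lat[i - 1], ctr[["lon"]], ctr[["lat"]])
      d_patch <- gc_dist_km(lon[i - 1], lat[i - 1],
                            patches$lon[target], patches$lat[target])
      if (state == "haulout" && times[i] >= state_until) state <- "transit_out"
      if (state == "transit_out" && d_patch < config$patch_radius_km * 0.5) {
        state <- "ars"
        state_until <- times[i] + ars_days * 86400 * stats::runif(1, 0.7, 1.3)
      }
      if (state == "ars" && times[i] >= state_until) state <- "transit_home"
      if (state == "transit_home" && d_home < 30) {
        state <- "haulout"
        state_until <- times[i] + config$haulout_days * 86400 * stats::runif(1, 0.6, 1.4)
        target <- 1 + target %% nrow(patches)
      }
      if (state == "haulout") {
        step <- 0
      } else if (state == "ars") {
        # search covers the whole patch: a moderately tortuous walk reflected
        # at the patch boundary, so time per unit patch area (not realized
        # range) carries the dwell signal
        step <- step_ars * stats::rlnorm(1, 0, 0.2)
        heading <- heading + stats::rnorm(1, 0, 60)
        if (d_patch > config$patch_radius_km * 0.95)
          heading <- gc_bearing_deg(lon[i - 1], lat[i - 1],
                                    patches$lon[target], patches$lat[target]) +
            stats::rnorm(1, 0, 30)
      } else {
        step <- step_transit * stats::rlnorm(1, 0, 0.1)
        goal <- if (state == "transit_out")
          gc_bearing_deg(lon[i - 1], lat[i - 1],
                         patches$lon[target], patches$lat[target])
        else gc_bearing_deg(lon[i - 1], lat[i - 1], ctr[["lon"]], ctr[["lat"]])
        heading <- goal + stats::rnorm(1, 0, 15)
      }
      p <- gc_destination(lon[i - 1], lat[i - 1], heading, step)
      lon[i] <- norm_lon(p[1, "lon"]); lat[i] <- p[1, "lat"]
      mode[i] <- state
      if (state == "ars") patch_idx[i] <- target
      # condition declines slowly while transiting / hauled out, improves
      # while feeding inside a patch; clamped to a plausible envelope
      slope_day <- if (state == "ars") 0.006 else -0.004
      rate <- min(0.3, max(-1.2, rate + slope_day * dt_hr / 24))
      rate_step[i] <- rate
    }

    day <- as.Date(times, tz = "UTC")
    if (is.null(config$condition_trajectory)) {
      cond <- tapply(rate_step, day, mean)
    } else {
      d0 <- as.numeric(day - day[1])
      cond <- tapply(config$condition_trajectory(d0), day, mean)
    }
    condition[[id]] <- data.frame(animal_id = id,
                                  day = as.Date(names(cond)),
                                  rate = as.numeric(cond),
                                  row.names = NULL)

    # haul-out intervals from contiguous runs of the haulout state
    r <- rle(mode == "haulout")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    ho <- which(r$values)
    if (length(ho))
      haulouts[[id]] <- data.frame(animal_id = id,
                                   start = times[starts[ho]],
                                   end = times[ends[ho]])

    # Argos observation model
    lc <- sample(lc_names, n_steps, replace = TRUE, prob = lc_p)
    artifact <- rep("none", n_steps)
    is_z <- stats::runif(n_steps) < config$p_lc_z
    lc[is_z] <- "Z"; artifact[is_z] <- "z"
    sd_km <- ifelse(lc == "Z", 60, config$argos_error_sd_km[lc])
    err_b <- stats::runif(n_steps, 0, 360)
    err_d <- abs(stats::rnorm(n_steps, 0, sd_km))
    obs <- gc_destination(lon, lat, err_b, err_d)
    spike <- stats::runif(n_steps) < config$p_spike & !is_z
    spike[c(1, n_steps)] <- FALSE
    if (any(spike)) {
      sp <- gc_destination(lon[spike], lat[spike],
                           stats::runif(sum(spike), 0, 360), config$spike_km)
      obs[spike, ] <- sp
      artifact[spike] <- "spike"
    }

    fixes[[id]] <- data.frame(animal_id = id, time = times,
                              lon = norm_lon(obs[, "lon"]), lat = obs[, "lat"],
                              lc = lc)
    latent[[id]] <- data.frame(animal_id = id, time = times, lon = lon,
                               lat = lat, mode = mode, patch = patch_idx,
                               artifact = artifact)
  }

  list(fixes = do.call(rbind, c(fixes, list(make.row.names = FALSE))),
       truth = list(
         latent = do.call(rbind, c(latent, list(make.row.names = FALSE))),
         classes = classes,
         haulouts = if (length(haulouts))
           do.call(rbind, c(haulouts, list(make.row.names = FALSE)))
           else data.frame(animal_id = character(), start = config$t0[0],
                           end = config$t0[0]),
         patches = cbind(config$patch_centers,
                         radius_km = config$patch_radius_km,
                         dwell_factor = config$patch_dwell_factor),
         condition = do.call(rbind, c(condition, list(make.row.names = FALSE)))),
       config = config)
}
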