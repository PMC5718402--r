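# End-to-end pipeline: simulate (or ingest) -> filter & smooth -> segment ->
# dive processing -> the three foraging indexes -> environmental covariates
# -> the daily modelling table joining everything on (animal, UTC day).

#' Run the full foraging-inference pipeline on simulated data
#'
#' Executes every stage in dependency order on a freshly simulated SRDL
#' bundle and assembles the daily modelling table (one row per animal-day)
#' joining the three foraging indexes with the daily environmental means and
#' the daily mean maximum dive depth. The join for modelling is inner on
#' (animal, day); a full outer audit table with per-index availability is
#' also returned, along with a manifest of row counts and drop accounting.
#'
#' @param config a [sim_config()]
#' @param env environmental fields ([make_synthetic_env()] by default)
#' @param ars_radii_km radii tested for the ARS scale
#' @param spacing_km along-track resampling interval for FPT
#' @param smooth logical; state-space smooth the filtered fixes (slower) or
#'   use the filtered fixes directly on the regular simulation grid
#' @return list: sim, tracks, trips, dives, rates, pca, ars, daily
#'   (modelling table), audit, drift (per-trip spline fits), manifest
#' @export
run_pipeline <- function(config = sim_config(), env = make_synthetic_env(),
                         ars_radii_km = 5:100, spacing_km = 5,
                         smooth = TRUE) {
  sim <- simulate_track(config)
  fixes <- sda_filter(sim$fixes)
  track <- if (smooth) smooth_track(fixes, sim$truth$haulouts,
                                    interval_hr = config$fix_interval_hr)
           else cbind(fixes[, c("animal_id", "time", "lon", "lat")],
                      position_se = 0, hauled_out = FALSE)
  # season + trip segmentation per animal
  pts <- list(); trips <- list()
  for (id in unique(track$animal_id)) {
    tr <- track[track$animal_id == id, ]
    cls <- sim$truth$classes[[id]]
    tr <- segment_seasons(tr, cls, sim$truth$haulouts)
    sg <- segment_trips(tr, cls, config$deployment_center)
    pts[[id]] <- sg$points
    if (nrow(sg$trips)) trips[[id]] <- sg$trips
  }
  points <- do.call(rbind, c(pts, list(make.row.names = FALSE)))
  trips <- do.call(rbind, c(trips, list(make.row.names = FALSE)))

  # dives
  dv <- simulate_dives(sim, env, config)
  dives <- geolocate_dives(dv$dives, track)
  labels <- dv$labels[match(dives$dive_id, dv$labels$dive_id), ]
  rates <- compute_transit_rates(dives)

  # --- FPT index ---------------------------------------------------------
  trip_pts <- split(points[!is.na(points$trip_id), ],
                    points$trip_id[!is.na(points$trip_id)])
  trip_pts <- Filter(function(p) nrow(p) >= 2, trip_pts)
  resampled <- lapply(trip_pts, resample_track_equidistant,
                      spacing_km = spacing_km)
  resampled <- Filter(function(p) nrow(p) >= 3, resampled)
  ars <- select_ars_scale(unname(resampled), ars_radii_km)
  ho_pos <- NULL
  if (nrow(sim$truth$haulouts)) {
    hp <- list()
    for (k in seq_len(nrow(sim$truth$haulouts))) {
      h <- sim$truth$haulouts[k, ]
      tk <- track[track$animal_id == h$animal_id &
                  track$time >= h$start & track$time <= h$end, ]
      if (nrow(tk)) hp[[k]] <- data.frame(lon = mean(tk$lon), lat = mean(tk$lat))
    }
    ho_pos <- do.call(rbind, hp)
  }
  fpt_pts <- list()
  for (tid in names(resampled)) {
    p <- resampled[[tid]]
    p$fpt_hr <- fpt_at_radius(p, ars$selected_radius_km)
    p$animal_id <- sub("_t[0-9]+$", "", tid)
    p$trip_id <- tid
    fpt_pts[[tid]] <- exclude_haulout_fpt(p, ho_pos, ars$selected_radius_km)
  }
  fpt_pts <- do.call(rbind, c(fpt_pts, list(make.row.names = FALSE)))
  d_fpt <- daily_fpt(fpt_pts)

  # --- transit index -----------------------------------------------------
  pca <- fit_transit_pca(rates)
  scored <- data.frame(dive_id = rates$dive_id,
                       score = transit_score(pca, rates),
                       weight = depth_weight(rates$mean_transit_depth))
  scored$animal_id <- dives$animal_id[match(scored$dive_id, dives$dive_id)]
  scored$start_time <- dives$start_time[match(scored$dive_id, dives$dive_id)]
  d_transit <- daily_transit_index(scored)

  # --- drift-rate change index ------------------------------------------
  cand <- extract_drift_candidates(dives)
  feats <- drift_features(dives, cand)
  lab <- labels$is_drift[match(feats$dive_id, dives$dive_id)]
  clf <- train_drift_classifier(feats, lab)
  prob <- classify_drift_dive(clf, dives, cand)
  seg <- cand
  seg$probability <- prob$probability[match(seg$dive_id, prob$dive_id)]
  seg$depth_weight <- depth_weight(seg$mean_depth)
  seg$weight <- seg$depth_weight * seg$probability
  seg <- screen_positive_drifts(seg)
  seg <- seg[!seg$excluded & seg$probability >= 0.5, ]
  # keep each dive's best candidate as its drift segment
  seg <- seg[order(seg$dive_id, -seg$dur_frac), ]
  seg <- seg[!duplicated(seg$dive_id), ]
  drift_fits <- list(); d_drift <- list()
  if (!is.null(trips) && nrow(trips))
    for (k in seq_len(nrow(trips))) {
      ti <- trips[k, ]
      s <- seg[seg$animal_id == ti$animal_id &
               seg$time >= ti$start_time & seg$time <= ti$end_time, ]
      dur_days <- as.numeric(difftime(ti$end_time, ti$start_time, units = "days"))
      if (!trip_inclusion(dur_days, nrow(s)) || nrow(s) < 4) next
      fit <- tryCatch(fit_drift_spline(s, trip_id = ti$trip_id),
                      error = function(e) NULL)
      if (is.null(fit)) next
      drift_fits[[ti$trip_id]] <- fit
      d_drift[[ti$trip_id]] <- cbind(animal_id = ti$animal_id, fit$daily)
    }
  d_drift <- if (length(d_drift))
    do.call(rbind, c(d_drift, list(make.row.names = FALSE)))
    else data.frame(animal_id = character(), day = as.Date(character()),
                    rate = numeric(), change = numeric())

  # --- environment + daily join -----------------------------------------
  denv <- dive_env(dives, env, simulate_ctd(sim, env, config))
  d_env <- daily_env(denv)
  d_depth <- daily_mean_max_depth(dives)

  names(d_drift)[names(d_drift) == "rate"] <- "drift_rate"
  names(d_drift)[names(d_drift) == "change"] <- "drift_change"
  tabs <- list(fpt = d_fpt[, c("animal_id", "day", "mean_fpt_hr")],
               transit = d_transit[, c("animal_id", "day", "transit_index")],
               drift = d_drift[, c("animal_id", "day", "drift_rate",
                                   "drift_change")],
               env = d_env,
               depth = d_depth[, c("animal_id", "day", "mean_max_depth")])
  audit <- Reduce(function(a, b) merge(a, b, by = c("animal_id", "day"),
                                       all = TRUE), tabs)
  daily <- stats::na.omit(audit)
  daily$class <- unname(sim$truth$classes[daily$animal_id])
  tid <- points$trip_id[!is.na(points$trip_id)]
  pd <- data.frame(animal_id = points$animal_id[!is.na(points$trip_id)],
                   day = as.Date(points$time[!is.na(points$trip_id)], tz = "UTC"),
                   trip_id = tid)
  pd <- pd[!duplicated(pd[, c("animal_id", "day")]), ]
  daily <- merge(daily, pd, by = c("animal_id", "day"), all.x = TRUE)
  daily$trip_id[is.na(daily$trip_id)] <- "none"

  manifest <- list(seed = config$seed, n_animals = config$n_animals,
                   n_fixes_raw = nrow(sim$fixes), n_fixes_filtered = nrow(fixes),
                   n_dives = nrow(dives), n_trips = if (is.null(trips)) 0 else nrow(trips),
                   ars_radius_km = ars$selected_radius_km,
                   n_drift_segments = nrow(seg),
                   n_trips_with_spline = length(drift_fits),
                   n_daily_rows = nrow(daily),
                   n_audit_rows = nrow(audit),
                   rows_dropped_by_join = nrow(audit) - nrow(daily))

  list(sim = sim, tracks = points, trips = trips, dives = dives,
       labels = labels, rates = rates, pca = pca, ars = ars,
       fpt_points = fpt_pts, daily_fpt = d_fpt, daily_transit = d_transit,
       drift = drift_fits, daily_drift = d_drift, daily_env = d_env,
       daily = daily, audit = audit, classifier = clf, manifest = manifest)
}

#' Write a small deterministic fixture bundle
#'
#' Three animals over 30 days, written as CSV/JSON/text rasters under `dir`.
#'
#' @param dir output directory
#' @param seed integer seed
#' @return invisibly, the list of written paths
#' @export
make_fixtures <- function(dir, seed = 42) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(n_animals = 3, duration_days = 30, fix_interval_hr = 2,
                    dive_interval_min = 60, seed = seed)
  env <- make_synthetic_env(res = 1)
  sim <- simulate_track(cfg)
  dv <- suppressWarnings(simulate_dives(sim, env, cfg))
  ctd <- simulate_ctd(sim, env, cfg)
  paths <- c(
    write_srdl_csv(sim$fixes, file.path(dir, "fixes.csv")),
    write_srdl_csv(dv$dives, file.path(dir, "dives.csv")),
    write_srdl_csv(ctd, file.path(dir, "ctd.csv")),
    write_srdl_csv(sim$truth$haulouts, file.path(dir, "haulouts.csv")),
    write_truth_json(sim$truth, file.path(dir, "truth.json")),
    write_env_grid(env$bathymetry, file.path(dir, "bathymetry.txt")))
  invisible(paths)
}
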