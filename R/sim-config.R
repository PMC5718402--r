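# Simulation configuration for the synthetic SRDL generator.

#' Configuration for the synthetic SRDL data generator
#'
#' Builds a validated configuration describing a simulated deployment of
#' CTD-SRDL-tagged seals: a colony (deployment centre) on the pack ice,
#' offshore foraging patches where animals switch to area-restricted search,
#' Argos observation error by location class, compressed dive records with
#' occasional passive drift segments, and a body-condition (drift-rate)
#' trajectory.
#'
#' @param n_animals number of simulated animals
#' @param class_mix named proportions for `pup`, `female`, `male`
#'   (must sum to 1); defaults reflect a typical deployment mix.
#' @param deployment_center lon/lat of the colony; default 13.50 E, 73.86 N
#'   (pack ice northwest of Jan Mayen).
#' @param duration_days record length per animal
#' @param fix_interval_hr Argos fix interval, hours
#' @param dive_interval_min spacing between successive dive starts, minutes
#' @param patch_centers matrix/data.frame with columns lon, lat of foraging
#'   patches; default two patches southeast of the colony.
#' @param patch_radius_km patch radius, km (5-100)
#' @param patch_dwell_factor >1; multiplier on the time spent per unit area
#'   inside a patch relative to transit (implemented mechanistically via a
#'   slower, more tortuous walk).
#' @param transit_speed_ms mean horizontal transit speed, m/s
#' @param argos_error_sd_km named per-LC isotropic error SD in km for classes
#'   `3,2,1,0,A,B`.
#' @param lc_probs named sampling probabilities for classes `3,2,1,0,A,B`
#'   (renormalized); invalid class Z is governed by `p_lc_z`.
#' @param p_lc_z probability a fix is reported as LC Z (large error,
#'   removed by filtering)
#' @param p_spike probability of injecting a spike artifact (large
#'   displacement at a good LC) for filter testing
#' @param spike_km displacement of injected spikes, km
#' @param haulout_days days hauled out at the colony between trips
#' @param trip_days nominal trip length, days (outbound + search + return)
#' @param drift_dive_prob probability a dive is a passive drift dive
#' @param condition_trajectory `NULL` (default) to derive the true drift-rate
#'   trajectory mechanistically from behaviour (condition declines slowly in
#'   transit, improves inside patches), or a function `day -> rate (m/s)`
#'   (negative = sinking) applied to all animals.
#' @param drift_noise_sd SD of per-segment noise around the true drift rate,
#'   m/s
#' @param glide_prob probability a non-drift dive contains a slow gliding
#'   mid-segment (hard negatives for the drift classifier)
#' @param min_depth_m shallow-dive cutoff, m
#' @param t0 deployment timestamp (UTC)
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_animals = 6,
                       class_mix = c(pup = 0.40, female = 0.45, male = 0.15),
                       deployment_center = c(lon = 13.50, lat = 73.86),
                       duration_days = 60,
                       fix_interval_hr = 1,
                       dive_interval_min = 25,
                       patch_centers = NULL,
                       patch_radius_km = 30,
                       patch_dwell_factor = 5,
                       transit_speed_ms = 1.1,
                       argos_error_sd_km = c(`3` = 0.25, `2` = 0.5, `1` = 1.5,
                                             `0` = 5, A = 8, B = 15),
                       lc_probs = c(`3` = 0.15, `2` = 0.2, `1` = 0.25,
                                    `0` = 0.15, A = 0.15, B = 0.10),
                       p_lc_z = 0.02,
                       p_spike = 0.01,
                       spike_km = 40,
                       haulout_days = 2,
                       trip_days = 25,
                       drift_dive_prob = 0.12,
                       condition_trajectory = NULL,
                       drift_noise_sd = 0.02,
                       glide_prob = 0.08,
                       min_depth_m = 10,
                       t0 = as.POSIXct("2008-03-20 00:00:00", tz = "UTC"),
                       seed = 1L) {
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (duration_days <= 0) stop("duration_days must be positive")
  if (fix_interval_hr <= 0) stop("fix_interval_hr must be positive")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (patch_radius_km < 5 || patch_radius_km > 100)
    stop("patch_radius_km must lie in [5, 100]")
  if (patch_dwell_factor <= 1) stop("patch_dwell_factor must exceed 1")
  if (drift_dive_prob < 0 || drift_dive_prob > 1)
    stop("drift_dive_prob must lie in [0, 1]")
  if (is.null(patch_centers)) {
    # two offshore patches southeast of the colony (the dominant migration
    # direction), ~500-800 km out
    patch_centers <- data.frame(lon = c(19.5, 8.0), lat = c(69.5, 67.5))
  }
  patch_centers <- as.data.frame(patch_centers)
  names(patch_centers) <- c("lon", "lat")
  structure(list(
    n_animals = as.integer(n_animals), class_mix = class_mix,
    deployment_center = deployment_center, duration_days = duration_days,
    fix_interval_hr = fix_interval_hr, dive_interval_min = dive_interval_min,
    patch_centers = patch_centers, patch_radius_km = patch_radius_km,
    patch_dwell_factor = patch_dwell_factor,
    transit_speed_ms = transit_speed_ms,
    argos_error_sd_km = argos_error_sd_km, lc_probs = lc_probs,
    p_lc_z = p_lc_z, p_spike = p_spike, spike_km = spike_km,
    haulout_days = haulout_days, trip_days = trip_days,
    drift_dive_prob = drift_dive_prob,
    condition_trajectory = condition_trajectory,
    drift_noise_sd = drift_noise_sd, glide_prob = glide_prob,
    min_depth_m = min_depth_m, t0 = t0, seed = as.integer(seed)),
    class = "sim_config")
}
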