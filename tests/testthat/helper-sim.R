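# Shared small simulated datasets, built once per test run.

noise_free_config <- function(seed = 1, ...) {
  sim_config(argos_error_sd_km = c(`3` = 0, `2` = 0, `1` = 0, `0` = 0,
                                   A = 0, B = 0),
             p_lc_z = 0, p_spike = 0, seed = seed, ...)
}

# one small shared environment and simulation reused across test files
shared_env <- local({
  e <- NULL
  function() {
    if (is.null(e)) e <<- make_synthetic_env(res = 1)
    e
  }
})

shared_sim <- local({
  s <- NULL
  function() {
    if (is.null(s)) {
      cfg <- sim_config(n_animals = 2, duration_days = 20,
                        dive_interval_min = 40, seed = 99)
      s <<- list(cfg = cfg, sim = simulate_track(cfg))
      s$dv <<- suppressWarnings(simulate_dives(s$sim, shared_env(), cfg))
    }
    s
  }
})

# split a latent path into per-trip (non-haulout) segments and resample
latent_trips <- function(sim, spacing_km = 5, min_pts = 20) {
  lat <- sim$truth$latent
  out <- list()
  for (id in unique(lat$animal_id)) {
    la <- lat[lat$animal_id == id, ]
    r <- rle(la$mode != "haulout")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      i <- starts[j]:ends[j]
      if (length(i) < min_pts) next
      out[[length(out) + 1]] <-
        resample_track_equidistant(la[i, c("time", "lon", "lat")], spacing_km)
    }
  }
  out
}
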