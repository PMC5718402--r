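# Speed-distance-angle filtering of raw Argos fixes: drop invalid location
# class Z, then iterate a McConnell-style both-neighbour speed test and
# angle/leg-length spike rules to a fixed point (which makes the filter
# idempotent by construction).

#' Speed-distance-angle (SDA) filter for Argos fixes
#'
#' Removes all LC Z fixes, then repeatedly removes (a) fixes whose implied
#' swimming speed to *both* neighbours exceeds `vmax_ms` (worst offender per
#' pass) and (b) spike fixes whose internal turning angle is below a rule's
#' angle with both legs longer than the rule's length, until no fix violates
#' any rule. Fix order is preserved; duplicate timestamps are dropped.
#'
#' @param fixes data.frame with animal_id, time, lon, lat, lc
#' @param vmax_ms swimming speed threshold, m/s
#' @param spike_rules list of `c(angle_deg, min_leg_km)` pairs; a fix is a
#'   spike under a rule if its internal angle is smaller than `angle_deg`
#'   and both adjacent legs are longer than `min_leg_km`.
#' @return filtered fixes (same columns)
#' @export
sda_filter <- function(fixes, vmax_ms = 2.0,
                       spike_rules = list(c(15, 2.5), c(25, 5))) {
  do.call(rbind, c(lapply(split(fixes, fixes$animal_id), .sda_one,
                          vmax_ms = vmax_ms, spike_rules = spike_rules),
                   list(make.row.names = FALSE)))
}

.sda_one <- function(fx, vmax_ms, spike_rules) {
  fx <- fx[order(fx$time), ]
  fx <- fx[!duplicated(fx$time), ]
  if (nrow(fx) < 3) {
    warning("fewer than 3 fixes for ", fx$animal_id[1], "; returned unfiltered")
    return(fx)
  }
  fx <- fx[fx$lc != "Z", ]
  repeat {
    n <- nrow(fx)
    if (n < 3) break
    dt <- diff(as.numeric(fx$time))
    leg <- gc_dist_km(fx$lon[-n], fx$lat[-n], fx$lon[-1], fx$lat[-1])
    v <- leg * 1000 / pmax(dt, 1)               # m/s per leg
    v_in <- c(NA, v); v_out <- c(v, NA)
    bad_speed <- which(v_in > vmax_ms & v_out > vmax_ms)
    if (length(bad_speed)) {
      worst <- bad_speed[which.max(pmin(v_in[bad_speed], v_out[bad_speed]))]
      fx <- fx[-worst, ]
      next
    }
    # internal angle at each interior fix
    b_back <- gc_bearing_deg(fx$lon[2:(n - 1)], fx$lat[2:(n - 1)],
                             fx$lon[1:(n - 2)], fx$lat[1:(n - 2)])
    b_fwd <- gc_bearing_deg(fx$lon[2:(n - 1)], fx$lat[2:(n - 1)],
                            fx$lon[3:n], fx$lat[3:n])
    ang <- abs(((b_back - b_fwd + 180) %% 360) - 180)
    leg_in <- leg[1:(n - 2)]; leg_out <- leg[2:(n - 1)]
    spike <- rep(FALSE, n - 2)
    for (rule in spike_rules)
      spike <- spike | (ang < rule[1] & leg_in > rule[2] & leg_out > rule[2])
    if (!any(spike)) break
    worst <- which(spike)[which.min(ang[spike])] + 1L
    fx <- fx[-worst, ]
  }
  fx
}
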