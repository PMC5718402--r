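# Continuous-time correlated random walk (CTCRW) state-space smoothing of
# SDA-filtered Argos fixes. The state is (position, velocity) per axis in a
# local azimuthal-equidistant projection; measurement error is isotropic with
# a per-location-class SD; velocity is pinned to zero across haul-out
# intervals so the track stops on the ice. Velocity autocorrelation (beta)
# and diffusion (sigma) are estimated per animal by maximum likelihood on the
# Kalman innovations.

#' Per-location-class measurement SDs (km) used by default
#' @export
DEFAULT_LC_SD_KM <- c(`3` = 0.25, `2` = 0.5, `1` = 1.5, `0` = 5, A = 8, B = 15)

# exact discrete-time transition/noise of the CTCRW over dt (time in hours,
# distance in km): dv = -beta v dt + sigma dW
.ctcrw_mats <- function(dt, beta, sig2) {
  phi <- exp(-beta * dt)
  F <- matrix(c(1, 0, (1 - phi) / beta, phi), 2, 2)
  q11 <- sig2 / beta^2 * (dt - 2 * (1 - phi) / beta + (1 - phi^2) / (2 * beta))
  q12 <- sig2 * (1 - phi)^2 / (2 * beta^2)
  q22 <- sig2 * (1 - phi^2) / (2 * beta)
  list(F = F, Q = matrix(c(q11, q12, q12, q22), 2, 2))
}

# Kalman filter (+ optional RTS smoother) for one axis. t in hours; z has NA
# at prediction-only times; r_var measurement variance (km^2); ho[i] TRUE if
# the interval (i-1, i] lies inside a haul-out.
.ctcrw_kalman <- function(t, z, r_var, ho, beta, sig2, smooth = FALSE) {
  n <- length(t)
  m_p <- m_f <- matrix(0, n, 2)
  P_p <- P_f <- array(0, c(n, 2, 2))
  Fs <- array(0, c(n, 2, 2))
  i0 <- which(!is.na(z))[1]
  m_f[i0, ] <- c(z[i0], 0)
  P_f[i0, , ] <- diag(c(r_var[i0], sig2 / (2 * beta)))
  m_p[i0, ] <- m_f[i0, ]; P_p[i0, , ] <- P_f[i0, , ]
  ll <- 0
  for (i in seq_len(n)) {
    if (i < i0) { m_f[i, ] <- m_f[i0, ]; next }
    if (i > i0) {
      dt <- t[i] - t[i - 1]
      if (ho[i]) {
        F <- matrix(c(1, 0, 0, 0), 2, 2)
        Q <- diag(c(1e-8, 1e-8))
      } else {
        mats <- .ctcrw_mats(max(dt, 1e-6), beta, sig2)
        F <- mats$F; Q <- mats$Q
      }
      Fs[i, , ] <- F
      m_p[i, ] <- F %*% m_f[i - 1, ]
      P_p[i, , ] <- F %*% P_f[i - 1, , ] %*% t(F) + Q
      m_f[i, ] <- m_p[i, ]; P_f[i, , ] <- P_p[i, , ]
    }
    if (!is.na(z[i]) && i > i0) {
      S <- P_p[i, 1, 1] + r_var[i]
      K <- P_p[i, , 1] / S
      innov <- z[i] - m_p[i, 1]
      ll <- ll - 0.5 * (log(2 * pi * S) + innov^2 / S)
      m_f[i, ] <- m_p[i, ] + K * innov
      P_f[i, , ] <- P_p[i, , ] - outer(K, K) * S
    }
  }
  if (!smooth) return(list(loglik = ll))
  m_s <- m_f; P_s <- P_f
  for (i in (n - 1):1) {
    if (i < i0) { m_s[i, ] <- m_s[i0, ]; P_s[i, , ] <- P_s[i0, , ]; next }
    Pp1 <- P_p[i + 1, , ]
    C <- P_f[i, , ] %*% t(Fs[i + 1, , ]) %*% solve(Pp1 + diag(1e-10, 2))
    m_s[i, ] <- m_f[i, ] + C %*% (m_s[i + 1, ] - m_p[i + 1, ])
    P_s[i, , ] <- P_f[i, , ] + C %*% (P_s[i + 1, , ] - Pp1) %*% t(C)
  }
  list(loglik = ll, mean = m_s, var_pos = pmax(P_s[, 1, 1], 0))
}

#' Smooth an SDA-filtered track to a regular time grid
#'
#' @param fixes SDA-filtered fixes (animal_id, time, lon, lat, lc)
#' @param haulouts data.frame (animal_id, start, end) or NULL
#' @param interval_hr regular output interval, hours
#' @param lc_sd_km named per-LC measurement SDs in km; unknown classes get
#'   the largest listed SD
#' @param max_gap_hr data gaps longer than this split the track into
#'   independently smoothed segments
#' @return data.frame of TrackPoints: animal_id, time, lon, lat,
#'   position_se (km), hauled_out
#' @export
smooth_track <- function(fixes, haulouts = NULL, interval_hr = 1,
                         lc_sd_km = DEFAULT_LC_SD_KM, max_gap_hr = 48) {
  do.call(rbind, c(lapply(split(fixes, fixes$animal_id), .smooth_one,
                          haulouts = haulouts, interval_hr = interval_hr,
                          lc_sd_km = lc_sd_km, max_gap_hr = max_gap_hr),
                   list(make.row.names = FALSE)))
}

.smooth_one <- function(fx, haulouts, interval_hr, lc_sd_km, max_gap_hr) {
  fx <- fx[order(fx$time), ]
  id <- fx$animal_id[1]
  ho <- if (!is.null(haulouts)) haulouts[haulouts$animal_id == id, ] else NULL
  lon0 <- mean(fx$lon); lat0 <- mean(fx$lat)
  xy <- project_aeq(fx$lon, fx$lat, lon0, lat0)
  t_obs <- as.numeric(fx$time) / 3600
  sd_obs <- lc_sd_km[as.character(fx$lc)]
  sd_obs[is.na(sd_obs)] <- max(lc_sd_km)
  sd_obs <- pmax(sd_obs, 0.05)  # measurement floor keeps filter well-posed
  seg <- cumsum(c(0, diff(t_obs) > max_gap_hr))
  if (max(seg) > 0)
    message("track ", id, " split into ", max(seg) + 1,
            " segments at gaps > ", max_gap_hr, " hr")
  out <- list()
  for (s in unique(seg)) {
    i <- which(seg == s)
    if (length(i) < 3) next
    to <- t_obs[i]
    grid <- seq(ceiling(to[1] / interval_hr) * interval_hr, to[length(to)],
                by = interval_hr)
    t_all <- sort(unique(round(c(to, grid), 8)))
    oi <- match(round(to, 8), t_all)
    zx <- zy <- rv <- rep(NA_real_, length(t_all))
    zx[oi] <- xy[i, "x"]; zy[oi] <- xy[i, "y"]; rv[oi] <- sd_obs[i]^2
    mid <- (t_all[-1] + t_all[-length(t_all)]) / 2
    in_ho <- rep(FALSE, length(t_all))
    if (!is.null(ho) && nrow(ho))
      for (k in seq_len(nrow(ho)))
        in_ho[-1][mid >= as.numeric(ho$start[k]) / 3600 &
                  mid <= as.numeric(ho$end[k]) / 3600] <- TRUE
    # MLE of (beta, sigma^2) on the observation-time likelihood
    obs_only <- list(t = to, zx = xy[i, "x"], zy = xy[i, "y"], r = sd_obs[i]^2)
    ho_obs <- rep(FALSE, length(to))
    if (!is.null(ho) && nrow(ho)) {
      mo <- (to[-1] + to[-length(to)]) / 2
      for (k in seq_len(nrow(ho)))
        ho_obs[-1][mo >= as.numeric(ho$start[k]) / 3600 &
                   mo <= as.numeric(ho$end[k]) / 3600] <- TRUE
    }
    nll <- function(p) {
      b <- exp(p[1]); s2 <- exp(p[2])
      if (!is.finite(b) || b < 1e-4 || b > 100) return(1e10)
      -(.ctcrw_kalman(obs_only$t, obs_only$zx, obs_only$r, ho_obs, b, s2)$loglik +
        .ctcrw_kalman(obs_only$t, obs_only$zy, obs_only$r, ho_obs, b, s2)$loglik)
    }
    v_emp <- stats::var(c(diff(obs_only$zx), diff(obs_only$zy)) /
                          rep(pmax(diff(to), 0.1), 2))
    p0 <- c(log(0.5), log(max(v_emp, 0.5)))
    opt <- try(stats::optim(p0, nll, method = "Nelder-Mead",
                            control = list(maxit = 120, reltol = 1e-6)),
               silent = TRUE)
    par <- if (inherits(opt, "try-error") || !is.finite(opt$value)) p0 else opt$par
    beta <- exp(par[1]); sig2 <- exp(par[2])
    kx <- .ctcrw_kalman(t_all, zx, rv, in_ho, beta, sig2, smooth = TRUE)
    ky <- .ctcrw_kalman(t_all, zy, rv, in_ho, beta, sig2, smooth = TRUE)
    gi <- match(round(grid, 8), t_all)
    ll <- unproject_aeq(kx$mean[gi, 1], ky$mean[gi, 1], lon0, lat0)
    gt <- as.POSIXct(grid * 3600, origin = "1970-01-01", tz = "UTC")
    ho_pt <- rep(FALSE, length(grid))
    if (!is.null(ho) && nrow(ho))
      for (k in seq_len(nrow(ho)))
        ho_pt[gt >= ho$start[k] & gt <= ho$end[k]] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      animal_id = id, time = gt, lon = norm_lon(ll[, "lon"]), lat = ll[, "lat"],
      position_se = sqrt((kx$var_pos[gi] + ky$var_pos[gi]) / 2),
      hauled_out = ho_pt)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
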